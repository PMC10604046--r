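#' @importFrom S4Vectors isSingleString isSingleNumber
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges NumericList
NULL

## ---------------------------------------------------------------------------
## BPEVocabulary
## ---------------------------------------------------------------------------

#' Byte-pair-encoding vocabulary over the nucleotide alphabet
#'
#' An ordered token set built by iterative most-frequent-pair merging, together
#' with the merge rules that produced it. Single-base tokens of the training
#' alphabet always come first; every multi-base token is the concatenation of
#' the two tokens of its merge rule.
#'
#' @slot tokens character vector of unique, non-empty tokens.
#' @slot merges character matrix with columns \code{left}, \code{right}; row
#'   \code{i} is the i-th merge performed during training.
#' @slot k integer(1), the target vocabulary size requested at training time.
#' @slot alphabet character vector of single-character base tokens.
#'
#' @seealso [trainBPE()], [bpeTokenize()]
#' @export
setClass("BPEVocabulary",
  representation(
    tokens = "character",
    merges = "matrix",
    k = "integer",
    alphabet = "character"
  )
)

setValidity("BPEVocabulary", function(object) {
  msg <- NULL
  tok <- object@tokens
  if (anyDuplicated(tok)) msg <- c(msg, "tokens must be unique")
  if (any(!nzchar(tok))) msg <- c(msg, "tokens must be non-empty")
  if (!all(object@alphabet %in% tok))
    msg <- c(msg, "every single-character base token must be present")
  if (length(tok) > object@k)
    msg <- c(msg, "|tokens| must not exceed k")
  m <- object@merges
  if (nrow(m) > 0L) {
    merged <- paste0(m[, 1L], m[, 2L])
    if (!all(merged %in% tok))
      msg <- c(msg, "each merge rule must yield a vocabulary token")
    multi <- tok[nchar(tok) > 1L]
    if (!all(multi %in% merged))
      msg <- c(msg, "every multi-character token needs a merge rule")
    if (!all(m[, 1L] %in% tok) || !all(m[, 2L] %in% tok))
      msg <- c(msg, "merge rule parts must themselves be tokens")
  } else if (any(nchar(tok) > 1L)) {
    msg <- c(msg, "multi-character tokens without merge rules")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn BPEVocabulary ordered tokens
#' @param x a \code{BPEVocabulary}
#' @export
setMethod("vocabTokens", "BPEVocabulary", function(x) x@tokens)

#' @describeIn BPEVocabulary merge rules as a two-column character matrix
#' @export
setMethod("vocabMerges", "BPEVocabulary", function(x) x@merges)

#' @describeIn BPEVocabulary number of tokens actually in the vocabulary
#' @export
setMethod("vocabSize", "BPEVocabulary", function(x) length(x@tokens))

setMethod("show", "BPEVocabulary", function(object) {
  cat("BPEVocabulary: ", length(object@tokens), " tokens (k = ", object@k,
      "), alphabet {", paste(object@alphabet, collapse = ","), "}\n", sep = "")
  cat("  longest token: ", max(nchar(object@tokens)), " nt\n", sep = "")
})

## ---------------------------------------------------------------------------
## RBPSampleSet
## ---------------------------------------------------------------------------

#' A set of candidate binding sites with aligned per-base features
#'
#' Container for one protein's (or a merged baseline's) samples: genomic
#' intervals, nucleotide sequences, dot-bracket secondary structure,
#' per-base conservation, binary labels, protein ids and a train/eval split
#' tag. Sequence, structure and conservation, where populated, have exactly
#' one symbol/score per base of the interval, ordered 5'->3' along the
#' transcribed strand.
#'
#' @slot intervals a \code{GRanges} (1-based, closed; converted from/to the
#'   0-based half-open convention at BED/header boundaries).
#' @slot sequence character; \code{NA} when not yet extracted.
#' @slot structure character dot-bracket strings; \code{NA} when absent.
#' @slot conservation a \code{NumericList}; zero-length elements mean absent.
#' @slot label integer 0/1.
#' @slot protein character protein identifier per sample.
#' @slot split character, one of \code{"train"} or \code{"eval"} per sample.
#' @slot dialect single string tagging the source flavour
#'   (\code{"rbp24-style"}, \code{"rbp31-style"} or \code{"synthetic"}).
#'
#' @export
setClass("RBPSampleSet",
  representation(
    intervals = "GRanges",
    sequence = "character",
    structure = "character",
    conservation = "NumericList",
    label = "integer",
    protein = "character",
    split = "character",
    dialect = "character"
  )
)

setValidity("RBPSampleSet", function(object) {
  n <- length(object@intervals)
  msg <- NULL
  for (nm in c("sequence", "structure", "label", "protein", "split")) {
    if (length(slot(object, nm)) != n)
      msg <- c(msg, sprintf("slot '%s' must have length %d", nm, n))
  }
  if (length(object@conservation) != n)
    msg <- c(msg, sprintf("slot 'conservation' must have length %d", n))
  if (length(object@dialect) != 1L)
    msg <- c(msg, "dialect must be a single string")
  if (n > 0L) {
    w <- GenomicRanges::width(object@intervals)
    ok <- is.na(object@sequence) | nchar(object@sequence) == w
    if (!all(ok)) msg <- c(msg, "sequence length must equal interval width")
    ok <- is.na(object@structure) | nchar(object@structure) == w
    if (!all(ok)) msg <- c(msg, "structure length must equal interval width")
    cl <- lengths(object@conservation)
    if (!all(cl == 0L | cl == w))
      msg <- c(msg, "conservation length must equal interval width (or 0)")
    if (!all(object@label %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1")
    if (!all(object@split %in% c("train", "eval")))
      msg <- c(msg, "split must be 'train' or 'eval'")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an RBPSampleSet
#'
#' @param intervals GRanges of the sample intervals.
#' @param sequence,structure character vectors (may be NA).
#' @param conservation NumericList or list of numeric vectors.
#' @param label integer 0/1 vector.
#' @param protein character vector of protein ids.
#' @param split character vector, "train"/"eval".
#' @param dialect source dialect tag.
#' @return an \code{RBPSampleSet}
#' @export
RBPSampleSet <- function(intervals,
                         sequence = rep(NA_character_, length(intervals)),
                         structure = rep(NA_character_, length(intervals)),
                         conservation = NULL,
                         label = integer(length(intervals)),
                         protein = rep("protein", length(intervals)),
                         split = rep("train", length(intervals)),
                         dialect = "synthetic") {
  n <- length(intervals)
  if (is.null(conservation)) {
    conservation <- IRanges::NumericList(rep(list(numeric(0)), n))
  } else if (!is(conservation, "NumericList")) {
    conservation <- IRanges::NumericList(conservation)
  }
  new("RBPSampleSet",
      intervals = intervals,
      sequence = as.character(sequence),
      structure = as.character(structure),
      conservation = conservation,
      label = as.integer(label),
      protein = as.character(protein),
      split = as.character(split),
      dialect = dialect)
}

#' @describeIn RBPSampleSet number of samples
#' @param x an \code{RBPSampleSet}
#' @export
setMethod("length", "RBPSampleSet", function(x) length(x@intervals))

#' @describeIn RBPSampleSet the sample intervals as GRanges
#' @export
setMethod("sampleIntervals", "RBPSampleSet", function(x) x@intervals)

#' @describeIn RBPSampleSet nucleotide sequences
#' @export
setMethod("sampleSequences", "RBPSampleSet", function(x) x@sequence)

#' @describeIn RBPSampleSet dot-bracket structure strings
#' @export
setMethod("sampleStructures", "RBPSampleSet", function(x) x@structure)

#' @describeIn RBPSampleSet per-base conservation vectors
#' @export
setMethod("sampleConservation", "RBPSampleSet", function(x) x@conservation)

#' @describeIn RBPSampleSet 0/1 labels
#' @export
setMethod("sampleLabels", "RBPSampleSet", function(x) x@label)

#' @describeIn RBPSampleSet protein ids
#' @export
setMethod("sampleProteins", "RBPSampleSet", function(x) x@protein)

#' @describeIn RBPSampleSet train/eval split tags
#' @export
setMethod("sampleSplit", "RBPSampleSet", function(x) x@split)

#' @describeIn RBPSampleSet subset of samples tagged "train"
#' @export
setMethod("trainingSet", "RBPSampleSet", function(x) x[x@split == "train"])

#' @describeIn RBPSampleSet subset of samples tagged "eval"
#' @export
setMethod("evaluationSet", "RBPSampleSet", function(x) x[x@split == "eval"])

#' @export
setMethod("[", "RBPSampleSet", function(x, i, j, ..., drop = TRUE) {
  if (is.logical(i)) i <- which(i)
  new("RBPSampleSet",
      intervals = x@intervals[i],
      sequence = x@sequence[i],
      structure = x@structure[i],
      conservation = x@conservation[i],
      label = x@label[i],
      protein = x@protein[i],
      split = x@split[i],
      dialect = x@dialect)
})

#' Concatenate sample sets
#'
#' @param x,... \code{RBPSampleSet} objects to combine; the dialect of the
#'   first is kept.
#' @return an \code{RBPSampleSet}
#' @export
setMethod("c", "RBPSampleSet", function(x, ...) {
  args <- c(list(x), list(...))
  new("RBPSampleSet",
      intervals = do.call(c, lapply(args, function(a) a@intervals)),
      sequence = unlist(lapply(args, function(a) a@sequence)),
      structure = unlist(lapply(args, function(a) a@structure)),
      conservation = do.call(c, lapply(args, function(a) a@conservation)),
      label = unlist(lapply(args, function(a) a@label)),
      protein = unlist(lapply(args, function(a) a@protein)),
      split = unlist(lapply(args, function(a) a@split)),
      dialect = x@dialect)
})

setMethod("show", "RBPSampleSet", function(object) {
  n <- length(object)
  cat("RBPSampleSet with ", n, " samples (", object@dialect, ")\n", sep = "")
  if (n > 0L) {
    cat("  proteins: ", paste(unique(object@protein), collapse = ", "), "\n",
        sep = "")
    cat("  labels: ", sum(object@label == 1L), " positive / ",
        sum(object@label == 0L), " negative\n", sep = "")
    cat("  split: ", sum(object@split == "train"), " train / ",
        sum(object@split == "eval"), " eval\n", sep = "")
  }
})

## ---------------------------------------------------------------------------
## ModelConfig
## ---------------------------------------------------------------------------

.table1_space <- list(
  bigruUnits = c(64L, 128L, 256L, 512L),
  embeddingDim = c(16L, 32L, 64L, 128L),
  tokenizerK = c(16L, 32L, 64L),
  cnnFilters = c(32L, 64L, 128L),
  resnetBlocks = c(2L, 3L),
  denseLayers = c(2L, 3L)
)

.interval_sweep <- c(100L, 150L, 200L, 250L, 300L)

#' Hyperparameter configuration of the three-branch classifier
#'
#' Tunable fields span the staged-search space (BiGRU units, embedding
#' dimension, tokenizer size, convolution filters, ResNet block count,
#' fully-connected layer count); the remaining architecture constants
#' (kernel sizes, attention width, head width, dropout) are fixed and
#' centralised in [nnConstants()].
#'
#' @slot bigruUnits integer, GRU hidden units per direction.
#' @slot embeddingDim integer, token embedding dimension.
#' @slot tokenizerK integer, BPE vocabulary size the sequence branch expects.
#' @slot cnnFilters integer, filters of all convolutional layers.
#' @slot resnetBlocks integer, residual blocks in the SS and EC branches.
#' @slot denseLayers integer, fully connected layers in the head.
#' @slot branches character subset of \code{c("S","SS","EC")}.
#' @slot intervalLength integer, recentred interval length in nt.
#' @slot outOfSpace logical; allow values outside the staged search space.
#' @export
setClass("ModelConfig",
  representation(
    bigruUnits = "integer",
    embeddingDim = "integer",
    tokenizerK = "integer",
    cnnFilters = "integer",
    resnetBlocks = "integer",
    denseLayers = "integer",
    branches = "character",
    intervalLength = "integer",
    outOfSpace = "logical"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- NULL
  if (length(object@branches) == 0L ||
      !all(object@branches %in% c("S", "SS", "EC")))
    msg <- c(msg, "branches must be a non-empty subset of {S, SS, EC}")
  if (!isTRUE(object@outOfSpace)) {
    for (nm in names(.table1_space)) {
      if (!slot(object, nm) %in% .table1_space[[nm]])
        msg <- c(msg, sprintf(
          "%s = %d is outside the search space {%s}; set outOfSpace = TRUE to allow",
          nm, slot(object, nm), paste(.table1_space[[nm]], collapse = ", ")))
    }
    if (!object@intervalLength %in% .interval_sweep)
      msg <- c(msg, "intervalLength outside {100,150,200,250,300}; set outOfSpace = TRUE")
  }
  if (object@intervalLength < 1L) msg <- c(msg, "intervalLength must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Create a model configuration
#'
#' Defaults are the smallest option of every tuned dimension with all three
#' branches enabled at the standard 150 nt interval.
#'
#' @param bigruUnits,embeddingDim,tokenizerK,cnnFilters,resnetBlocks,denseLayers
#'   tunable hyperparameters; see \linkS4class{ModelConfig}.
#' @param branches character subset of \code{c("S","SS","EC")}.
#' @param intervalLength recentred interval length (nt).
#' @param outOfSpace allow values outside the staged search space.
#' @return a \code{ModelConfig}
#' @examples
#' modelConfig(branches = "S")
#' @export
modelConfig <- function(bigruUnits = 64, embeddingDim = 16, tokenizerK = 16,
                        cnnFilters = 32, resnetBlocks = 2, denseLayers = 2,
                        branches = c("S", "SS", "EC"), intervalLength = 150,
                        outOfSpace = FALSE) {
  new("ModelConfig",
      bigruUnits = as.integer(bigruUnits),
      embeddingDim = as.integer(embeddingDim),
      tokenizerK = as.integer(tokenizerK),
      cnnFilters = as.integer(cnnFilters),
      resnetBlocks = as.integer(resnetBlocks),
      denseLayers = as.integer(denseLayers),
      branches = branches,
      intervalLength = as.integer(intervalLength),
      outOfSpace = outOfSpace)
}

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig [", paste(object@branches, collapse = "+"), "] ",
      "L=", object@intervalLength, " nt\n", sep = "")
  cat("  BiGRU ", object@bigruUnits, " | emb ", object@embeddingDim,
      " | k ", object@tokenizerK, " | filters ", object@cnnFilters,
      " | ResNet blocks ", object@resnetBlocks,
      " | dense layers ", object@denseLayers, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## TrainSpec
## ---------------------------------------------------------------------------

#' Training regime specification
#'
#' Captures the protocol (BS base-model pretraining, SCR training from
#' scratch, TL fine-tuning from a base checkpoint), optimiser settings and
#' stopping rule. TL requires \code{initFrom}; BS/SCR forbid it.
#'
#' @slot protocol one of "BS", "SCR", "TL".
#' @slot initFrom character checkpoint directory (length 0 unless TL).
#' @slot learningRate numeric Adam step size.
#' @slot maxEpochs,patience integer stopping controls (early stopping
#'   monitors validation AUC).
#' @slot batchSize integer.
#' @slot seed integer RNG seed for init, shuffling and dropout.
#' @slot freeze character vector of parameter-name prefixes kept fixed
#'   during fine-tuning (empty = update all layers).
#' @slot classWeights logical; inverse-frequency loss weights.
#' @export
setClass("TrainSpec",
  representation(
    protocol = "character",
    initFrom = "character",
    learningRate = "numeric",
    maxEpochs = "integer",
    patience = "integer",
    batchSize = "integer",
    seed = "integer",
    freeze = "character",
    classWeights = "logical"
  )
)

setValidity("TrainSpec", function(object) {
  msg <- NULL
  if (!object@protocol %in% c("BS", "SCR", "TL"))
    msg <- c(msg, "protocol must be BS, SCR or TL")
  if (object@protocol == "TL" && length(object@initFrom) != 1L)
    msg <- c(msg, "TL requires initFrom (a checkpoint directory)")
  if (object@protocol %in% c("BS", "SCR") && length(object@initFrom) != 0L)
    msg <- c(msg, "initFrom is only valid for protocol TL")
  if (object@maxEpochs < 0L) msg <- c(msg, "maxEpochs must be >= 0")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Create a training specification
#'
#' Defaults: Adam with learning rate 1e-3 for BS/SCR and 1e-4 for TL
#' fine-tuning, early stopping on validation AUC with patience 5, at most
#' 100 epochs, batch size 64. Fine-tuning updates all layers unless
#' \code{freeze} names parameter prefixes to hold fixed.
#'
#' @param protocol "BS", "SCR" or "TL".
#' @param initFrom checkpoint directory (TL only).
#' @param learningRate Adam step size; default depends on protocol.
#' @param maxEpochs,patience,batchSize,seed training controls.
#' @param freeze character vector of parameter-name prefixes to freeze.
#' @param classWeights use inverse-frequency loss weights.
#' @return a \code{TrainSpec}
#' @export
trainSpec <- function(protocol = c("SCR", "BS", "TL"), initFrom = character(0),
                      learningRate = NULL, maxEpochs = 100, patience = 5,
                      batchSize = 64, seed = 1, freeze = character(0),
                      classWeights = FALSE) {
  protocol <- match.arg(protocol)
  if (is.null(learningRate))
    learningRate <- if (protocol == "TL") 1e-4 else 1e-3
  new("TrainSpec",
      protocol = protocol,
      initFrom = initFrom,
      learningRate = learningRate,
      maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience),
      batchSize = as.integer(batchSize),
      seed = as.integer(seed),
      freeze = freeze,
      classWeights = classWeights)
}

setMethod("show", "TrainSpec", function(object) {
  cat("TrainSpec <", object@protocol, "> lr=", object@learningRate,
      " epochs<=", object@maxEpochs, " patience=", object@patience,
      " batch=", object@batchSize, " seed=", object@seed, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## RBPModel
## ---------------------------------------------------------------------------

#' A (possibly trained) three-branch classifier
#'
#' Holds the configuration, the parameter store (a named list of numeric
#' matrices/vectors, including batch-normalisation running statistics) and
#' the vocabulary used by the sequence branch. Predictions in inference mode
#' are deterministic for fixed parameters and inputs.
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot params named list of numeric arrays.
#' @slot vocab a \linkS4class{BPEVocabulary} (may be an empty vocabulary when
#'   the S branch is disabled).
#' @export
setClass("RBPModel",
  representation(
    config = "ModelConfig",
    params = "list",
    vocab = "BPEVocabulary"
  )
)

setMethod("show", "RBPModel", function(object) {
  np <- sum(vapply(object@params[!grepl("^bn_run", names(object@params))],
                   length, integer(1)))
  cat("RBPModel [", paste(object@config@branches, collapse = "+"), "] ",
      np, " parameters\n", sep = "")
  show(object@config)
})

#' Total trainable parameter count of a model
#'
#' Counts every optimised weight (batch-normalisation running statistics are
#' excluded: they are maintained, not optimised).
#'
#' @param model an \code{RBPModel}
#' @return integer parameter count
#' @export
parameterCount <- function(model) {
  stopifnot(is(model, "RBPModel"))
  sum(vapply(model@params[!grepl("^bn_run", names(model@params))],
             length, integer(1)))
}

## ---------------------------------------------------------------------------
## SyntheticSpec
## ---------------------------------------------------------------------------

#' Specification of a synthetic CLIP-like benchmark collection
#'
#' Describes a family of "proteins" whose positives carry a planted motif
#' (a shared transferable core plus a protein-specific flank), negatives
#' drawn from the same background composition, conservation elevated over
#' the motif, and deterministic stub secondary structure. Two dialects are
#' emulated: variable-length balanced collections (\code{"rbp24-style"}) and
#' fixed 101-nt collections at a 1:4 positive:negative ratio
#' (\code{"rbp31-style"}).
#'
#' @slot nProteins integer number of proteins.
#' @slot coreMotif shared core motif (nucleotides).
#' @slot flankMotifs per-protein flank motifs (character; may be empty
#'   strings to disable flanks).
#' @slot motifMutationRate per-base substitution probability in [0,1).
#' @slot nPos,nNeg integer samples per protein.
#' @slot intervalLengthRange integer(2), native interval length range (nt).
#' @slot negPerPosRatio numeric, negatives per positive.
#' @slot conservation numeric(4): background mean/sd, motif mean/sd.
#' @slot dialect "rbp24-style" or "rbp31-style".
#' @slot markovBackground logical; first-order Markov background instead of
#'   i.i.d. uniform.
#' @slot plantHairpins logical; place complementary arms around the motif so
#'   the structure branch has learnable signal.
#' @slot seed integer generator seed.
#' @export
setClass("SyntheticSpec",
  representation(
    nProteins = "integer",
    coreMotif = "character",
    flankMotifs = "character",
    motifMutationRate = "numeric",
    nPos = "integer",
    nNeg = "integer",
    intervalLengthRange = "integer",
    negPerPosRatio = "numeric",
    conservation = "numeric",
    dialect = "character",
    markovBackground = "logical",
    plantHairpins = "logical",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (nchar(object@coreMotif) < 4L) msg <- c(msg, "core motif must be >= 4 nt")
  if (object@motifMutationRate < 0 || object@motifMutationRate >= 1)
    msg <- c(msg, "motif mutation rate must be in [0,1)")
  if (object@negPerPosRatio <= 0) msg <- c(msg, "neg:pos ratio must be > 0")
  r <- object@intervalLengthRange
  if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L)
    msg <- c(msg, "interval length range must be (min, max) with 1 <= min <= max")
  if (length(object@flankMotifs) != object@nProteins)
    msg <- c(msg, "need one flank motif per protein (may be empty strings)")
  fl <- object@flankMotifs[nzchar(object@flankMotifs)]
  if (length(fl) && any(nchar(fl) < 4L))
    msg <- c(msg, "non-empty flank motifs must be >= 4 nt")
  ml <- nchar(object@coreMotif) + max(0L, nchar(object@flankMotifs))
  if (ml > r[1L])
    msg <- c(msg, "motif (core + flank) longer than the minimum interval length")
  if (!object@dialect %in% c("rbp24-style", "rbp31-style"))
    msg <- c(msg, "dialect must be rbp24-style or rbp31-style")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec (", object@dialect, "): ", object@nProteins,
      " proteins, core ", object@coreMotif, ", ", object@nPos, " pos / ",
      object@nNeg, " neg per protein, lengths ",
      object@intervalLengthRange[1L], "-", object@intervalLengthRange[2L],
      " nt, mutation ", object@motifMutationRate, ", seed ",
      object@seed, "\n", sep = "")
})
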