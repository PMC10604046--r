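## Dataset assembly: benchmark-dialect FASTA loading, merged-baseline
## construction with overlap purging and ratio preservation, stratified
## train/validation splitting and nested subsampling.

#' Header grammars shipped for the two benchmark dialects
#'
#' Named PCRE patterns with \code{chrom}, \code{start}, \code{end},
#' \code{strand} capture groups. Coordinates in headers are 0-based
#' half-open, as in BED.
#'
#' @examples
#' headerPatterns()
#' @return named character vector of patterns
#' @export
headerPatterns <- function() {
  c("rbp24-style" =
      "(?<chrom>[A-Za-z0-9_.]+):(?<start>\\d+)-(?<end>\\d+)\\((?<strand>[+-])\\)",
    "rbp31-style" =
      "(?<chrom>[A-Za-z0-9_.]+),(?<start>\\d+),(?<end>\\d+),(?<strand>[+-])")
}

.parse_headers <- function(headers, pattern) {
  m <- regexpr(pattern, headers, perl = TRUE)
  if (any(m == -1L)) {
    bad <- headers[which(m == -1L)[1L]]
    stop("unparseable FASTA header '", bad, "' with pattern '", pattern, "'")
  }
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  field <- function(nm) substr(headers, cs[, nm], cs[, nm] + cl[, nm] - 1L)
  .gr_from_bed0(field("chrom"), as.integer(field("start")),
                as.integer(field("end")), field("strand"))
}

#' Load benchmark-style FASTA files into a sample set
#'
#' Reads FASTA files whose headers carry genomic coordinates (see
#' [headerPatterns()] for the shipped grammars), one label and split tag per
#' file. When a genome and \code{recenterTo} are supplied the intervals are
#' recentred and the sequences re-extracted from the genome; otherwise the
#' native FASTA sequences and intervals are kept. Structure and conservation
#' features are attached when a source/track is supplied.
#'
#' @param files character vector of FASTA paths.
#' @param labels integer 0/1, one per file.
#' @param protein protein identifier for all samples.
#' @param dialect "rbp24-style" or "rbp31-style" (chooses the header
#'   grammar unless \code{pattern} overrides it).
#' @param split "train" or "eval", one per file (recycled).
#' @param pattern optional custom header pattern with named groups.
#' @param genome optional FASTA path / \code{FaFile} / \code{DNAStringSet}.
#' @param recenterTo optional target interval length (nt); requires
#'   \code{genome}.
#' @param structureSource optional \linkS4class{StructureSource}.
#' @param conservation optional conservation track \code{GRanges} (from
#'   [readConservationTrack()]).
#' @return an \linkS4class{RBPSampleSet}
#' @export
loadBenchmarkFasta <- function(files, labels, protein,
                               dialect = c("rbp24-style", "rbp31-style"),
                               split = "train", pattern = NULL,
                               genome = NULL, recenterTo = NULL,
                               structureSource = NULL, conservation = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(pattern)) pattern <- headerPatterns()[[dialect]]
  stopifnot(length(files) == length(labels))
  split <- rep_len(split, length(files))

  parts <- lapply(seq_along(files), function(i) {
    f <- files[i]
    if (!file.exists(f)) stop("FASTA file not found: ", f)
    if (file.size(f) == 0L) return(NULL)
    ss <- Biostrings::readDNAStringSet(f)
    if (length(ss) == 0L) return(NULL)
    gr <- .parse_headers(names(ss), pattern)
    list(gr = gr, seq = normalizeSequence(as.character(ss)),
         label = rep(as.integer(labels[i]), length(ss)),
         split = rep(split[i], length(ss)))
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) {
    return(RBPSampleSet(GRanges(), sequence = character(0),
                        label = integer(0), protein = character(0),
                        split = character(0), dialect = dialect))
  }
  gr <- do.call(c, lapply(parts, `[[`, "gr"))
  seqs <- unlist(lapply(parts, `[[`, "seq"))
  label <- unlist(lapply(parts, `[[`, "label"))
  split <- unlist(lapply(parts, `[[`, "split"))

  if (!is.null(recenterTo)) {
    if (is.null(genome))
      stop("recenterTo requires a genome to re-extract sequences from")
    gr <- recenterIntervals(gr, recenterTo)
    seqs <- normalizeSequence(extractSequences(genome, gr))
  }
  structure <- if (!is.null(structureSource))
    getStructure(seqs, structureSource) else rep(NA_character_, length(seqs))
  cons <- if (!is.null(conservation)) {
    lapply(seq_along(gr), function(i) encodeConservation(conservation, gr[i]))
  } else NULL

  RBPSampleSet(gr, sequence = seqs, structure = structure,
               conservation = cons, label = label,
               protein = rep(protein, length(gr)), split = split,
               dialect = dialect)
}

#' Build a merged baseline set for base-model pretraining
#'
#' Merges the training samples of all supplied proteins (optionally leaving
#' one protein out entirely for held-out fine-tuning), removes negative
#' samples that overlap (at least one shared base, same chromosome and, by
#' default, same strand) a binding site of any included protein, then
#' removes uniformly random positive samples so the merged
#' positive:negative ratio is preserved within rounding.
#'
#' @param manifests list of \linkS4class{RBPSampleSet}s sharing a dialect.
#' @param exclude optional protein id to leave out.
#' @param ignoreStrand purge overlaps irrespective of strand.
#' @param seed RNG seed for the random positive removal.
#' @return an \linkS4class{RBPSampleSet} of training samples
#' @export
buildBaseline <- function(manifests, exclude = NULL, ignoreStrand = FALSE,
                          seed = 1L) {
  stopifnot(length(manifests) >= 1L)
  proteins <- unlist(lapply(manifests, function(m) unique(sampleProteins(m))))
  if (!is.null(exclude)) {
    if (!exclude %in% proteins)
      stop("excluded protein '", exclude, "' is not present")
    keep <- vapply(manifests,
                   function(m) !all(sampleProteins(m) == exclude), logical(1))
    manifests <- manifests[keep]
    if (length(manifests) == 0L)
      stop("excluding '", exclude, "' empties the input")
  }
  merged <- do.call(c, unname(lapply(manifests, trainingSet)))
  if (length(merged) == 0L) stop("no training samples to merge")

  pos_all <- do.call(c, unname(lapply(manifests, function(m)
    sampleIntervals(m)[sampleLabels(m) == 1L])))
  lab <- sampleLabels(merged)
  n_pos0 <- sum(lab == 1L)
  n_neg0 <- sum(lab == 0L)

  neg_idx <- which(lab == 0L)
  hits <- GenomicRanges::findOverlaps(sampleIntervals(merged)[neg_idx],
                                      pos_all, minoverlap = 1L,
                                      ignore.strand = ignoreStrand)
  drop_neg <- neg_idx[unique(S4Vectors::queryHits(hits))]

  n_neg1 <- n_neg0 - length(drop_neg)
  ## preserve the pre-merge positive:negative ratio within rounding
  n_pos1 <- if (n_neg0 > 0L) as.integer(round(n_pos0 * n_neg1 / n_neg0))
            else n_pos0
  pos_idx <- which(lab == 1L)
  drop_pos <- integer(0)
  if (n_pos1 < n_pos0) {
    drop_pos <- .with_seed(seed,
      sample(pos_idx, n_pos0 - n_pos1, replace = FALSE))
  }
  drop <- c(drop_neg, drop_pos)
  if (length(drop)) merged <- merged[-drop]
  merged
}

#' Stratified train/validation split
#'
#' Splits a sample set into disjoint, exhaustive training and validation
#' subsets at the given integer ratio (default 9:1), stratified by
#' (protein, label) so that class proportions are preserved per stratum
#' within one sample. Deterministic under \code{seed}.
#'
#' @param manifest an \linkS4class{RBPSampleSet}.
#' @param ratio integer(2), train:validation parts.
#' @param seed RNG seed.
#' @return list with elements \code{train} and \code{validation}
#' @export
splitTrainVal <- function(manifest, ratio = c(9L, 1L), seed = 1L) {
  n <- length(manifest)
  if (n == 0L) stop("cannot split an empty sample set")
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  strata <- paste(sampleProteins(manifest), sampleLabels(manifest), sep = "\r")
  if (n < length(unique(strata)))
    stop("fewer samples than strata; split is degenerate")
  frac_val <- ratio[2L] / sum(ratio)
  groups <- split(seq_len(n), strata)
  ## largest-remainder allocation: per-stratum floor, then distribute the
  ## remainder so the global validation count equals round(n * frac)
  target <- as.integer(round(n * frac_val))
  quota <- vapply(groups, length, integer(1)) * frac_val
  nv <- pmin(floor(quota), vapply(groups, length, integer(1)) - 1L)
  short <- target - sum(nv)
  if (short > 0L) {
    ord <- order(-(quota - floor(quota)), seq_along(groups))
    for (g in ord) {
      if (short == 0L) break
      if (nv[g] + 1L < length(groups[[g]])) { nv[g] <- nv[g] + 1L
                                              short <- short - 1L }
    }
  }
  val_idx <- .with_seed(seed, {
    unlist(lapply(seq_along(groups), function(g) {
      if (nv[g] <= 0L) return(integer(0))
      sample(groups[[g]], nv[g], replace = FALSE)
    }))
  })
  list(train = manifest[setdiff(seq_len(n), val_idx)],
       validation = manifest[sort(val_idx)])
}

#' Nested per-class subsampling
#'
#' Draws a ladder of training subsets of the requested per-class sizes such
#' that each smaller subset is contained in every larger one (per class),
#' isolating the effect of sample size. Sizes exceeding the available class
#' size are skipped with a message. Evaluation samples are carried through
#' unchanged in every rung.
#'
#' @param manifest an \linkS4class{RBPSampleSet}.
#' @param sizesPerClass strictly ascending integer sizes per class.
#' @param seed RNG seed fixing the nesting order.
#' @return named list of \linkS4class{RBPSampleSet}s, one per usable size
#' @export
nestedSubsample <- function(manifest, sizesPerClass, seed = 1L) {
  sizesPerClass <- as.integer(sizesPerClass)
  if (is.unsorted(sizesPerClass, strictly = TRUE))
    stop("sizesPerClass must be strictly ascending")
  tr <- trainingSet(manifest)
  ev <- evaluationSet(manifest)
  lab <- sampleLabels(tr)
  idx_by_class <- split(seq_along(lab), lab)
  max_per_class <- min(lengths(idx_by_class))
  usable <- sizesPerClass[sizesPerClass <= max_per_class]
  if (length(usable) < length(sizesPerClass))
    message("skipping sizes above the smallest class (", max_per_class, "): ",
            paste(setdiff(sizesPerClass, usable), collapse = ", "))
  perm <- .with_seed(seed, lapply(idx_by_class, sample))
  out <- lapply(usable, function(s) {
    take <- sort(unlist(lapply(perm, function(p) p[seq_len(s)])))
    rung <- tr[take]
    if (length(ev) > 0L) rung <- c(rung, ev)
    rung
  })
  names(out) <- as.character(usable)
  out
}

#' Prepare a manifest for modelling at a fixed interval length
#'
#' Recenters every interval to length \code{L}, re-extracts the sequences
#' from the genome, recomputes secondary structure and re-attaches
#' conservation, leaving labels, protein ids and split tags untouched.
#'
#' @param manifest an \linkS4class{RBPSampleSet}.
#' @param genome FASTA path / \code{FaFile} / \code{DNAStringSet}.
#' @param track optional conservation \code{GRanges} (or a track file path);
#'   omitted = conservation left empty.
#' @param L target interval length (nt).
#' @param structureSource a \linkS4class{StructureSource}.
#' @return an \linkS4class{RBPSampleSet} of width-\code{L} samples
#' @export
prepareSamples <- function(manifest, genome, track = NULL, L = 150L,
                           structureSource = structureStub()) {
  gr <- recenterIntervals(sampleIntervals(manifest), L)
  seqs <- normalizeSequence(extractSequences(genome, gr))
  out <- RBPSampleSet(gr, sequence = seqs,
                      structure = getStructure(seqs, structureSource),
                      label = sampleLabels(manifest),
                      protein = sampleProteins(manifest),
                      split = sampleSplit(manifest),
                      dialect = manifest@dialect)
  if (!is.null(track)) {
    if (is.character(track)) track <- readConservationTrack(track)
    out <- attachConservation(out, track)
  }
  out
}

## ---------------------------------------------------------------------------
## Manifest persistence
## ---------------------------------------------------------------------------

#' Persist / load a sample set as plain-text files
#'
#' \code{writeManifest} writes \code{<name>.samples.tsv} (columns chrom,
#' start, end, strand, label, protein, split; coordinates 0-based
#' half-open), \code{<name>.fa} with the sequences, and, when populated,
#' \code{<name>.dotbracket.txt} and \code{<name>.phylop.tsv} (comma-joined
#' per-base scores, one line per sample). \code{readManifest} reverses it.
#'
#' @param x an \linkS4class{RBPSampleSet}.
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return \code{writeManifest}: the file stem path, invisibly;
#'   \code{readManifest}: an \linkS4class{RBPSampleSet}.
#' @export
writeManifest <- function(x, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, name)
  df <- .bed0_from_gr(sampleIntervals(x))
  df$label <- sampleLabels(x)
  df$protein <- sampleProteins(x)
  df$split <- sampleSplit(x)
  utils::write.table(df, paste0(stem, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seqs <- sampleSequences(x)
  if (!all(is.na(seqs))) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- sprintf("%s:%d-%d(%s)", df$chrom, df$start, df$end, df$strand)
    Biostrings::writeXStringSet(ss, paste0(stem, ".fa"))
  }
  st <- sampleStructures(x)
  if (!all(is.na(st)))
    writeLines(st, paste0(stem, ".dotbracket.txt"))
  cons <- sampleConservation(x)
  if (any(lengths(cons) > 0L))
    writeLines(vapply(as.list(cons), function(v)
      paste(format(v, trim = TRUE, scientific = FALSE), collapse = ","),
      character(1)), paste0(stem, ".phylop.tsv"))
  invisible(stem)
}

#' @rdname writeManifest
#' @param dialect dialect tag for the loaded set.
#' @export
readManifest <- function(dir, name, dialect = "synthetic") {
  stem <- file.path(dir, name)
  df <- utils::read.table(paste0(stem, ".samples.tsv"), header = TRUE,
                          sep = "\t", colClasses = c(
                            chrom = "character", start = "integer",
                            end = "integer", strand = "character",
                            label = "integer", protein = "character",
                            split = "character"))
  gr <- .gr_from_bed0(df$chrom, df$start, df$end, df$strand)
  n <- nrow(df)
  seqs <- rep(NA_character_, n)
  fa <- paste0(stem, ".fa")
  if (file.exists(fa))
    seqs <- as.character(Biostrings::readDNAStringSet(fa))
  st <- rep(NA_character_, n)
  dbf <- paste0(stem, ".dotbracket.txt")
  if (file.exists(dbf)) st <- readLines(dbf)
  cons <- NULL
  cf <- paste0(stem, ".phylop.tsv")
  if (file.exists(cf))
    cons <- lapply(strsplit(readLines(cf), ",", fixed = TRUE), as.numeric)
  RBPSampleSet(gr, sequence = unname(seqs), structure = st,
               conservation = cons, label = df$label, protein = df$protein,
               split = df$split, dialect = dialect)
}
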