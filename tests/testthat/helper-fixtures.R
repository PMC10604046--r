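# Shared fixtures: all built in code, nothing read from disk.

DNA <- c("A", "C", "G", "T")

rand_seqs <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n),
         function(i) paste(sample(DNA, len[i], replace = TRUE),
                           collapse = ""),
         character(1))
}

# A sample set with non-overlapping plus-strand intervals on one chromosome,
# stub structure and standard-normal conservation.
mk_samples <- function(seqs, labels = rep(1L, length(seqs)),
                       protein = "P1", split = "train",
                       strand = "+", chrom = "chrT") {
  n <- length(seqs)
  len <- nchar(seqs)
  starts <- cumsum(c(1L, head(len, -1) + 100L))
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts, width = len),
    strand = rep_len(strand, n))
  RBPSampleSet(gr, sequence = seqs,
               structure = getStructure(seqs),
               conservation = lapply(len, rnorm),
               label = rep_len(labels, n),
               protein = rep_len(protein, n),
               split = rep_len(split, n))
}

# Small config with every branch, shrunk below the search space for speed.
tiny_config <- function(branches = c("S", "SS", "EC"), n = 30L) {
  cfg <- modelConfig(branches = branches, outOfSpace = TRUE)
  cfg@bigruUnits <- 6L
  cfg@embeddingDim <- 4L
  cfg@cnnFilters <- 5L
  cfg@intervalLength <- as.integer(n)
  validObject(cfg)
  cfg
}

tiny_vocab <- function(k = 16L, seed = 7L) {
  set.seed(seed)
  trainBPE(rand_seqs(30, 60), k)
}

# Exhaustive greedy longest-match tokenizer used as the independent oracle.
oracle_tokenize <- function(s, tokens) {
  out <- character(0)
  while (nchar(s) > 0) {
    hit <- ""
    for (tok in tokens) {
      if (nchar(tok) > nchar(hit) && startsWith(s, tok)) hit <- tok
    }
    if (hit == "") return(NULL)
    out <- c(out, hit)
    s <- substr(s, nchar(hit) + 1L, nchar(s))
  }
  out
}

# Exhaustive pairwise Mann-Whitney oracle (ties counted one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

hpo_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(71)
      cache <<- mk_samples(rand_seqs(40, 30), labels = rep(c(1L, 0L), 20))
    }
    cache
  }
})

# Heavy end-to-end experiments are computed once per test run and shared.
.exp_cache <- new.env(parent = emptyenv())

cached_solvability <- function() {
  if (is.null(.exp_cache$solv))
    .exp_cache$solv <- runSolvabilityExperiment(seed = 42L)
  .exp_cache$solv
}

cached_transfer_family <- function() {
  if (is.null(.exp_cache$family))
    .exp_cache$family <- runTransferFamilyExperiment(seed = 42L, nSeeds = 5L)
  .exp_cache$family
}
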