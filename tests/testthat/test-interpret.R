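test_that("top-prediction selection is threshold-filtered and stable", {
  set.seed(81)
  cfg <- tiny_config()
  vocab <- tiny_vocab()
  model <- buildModel(cfg, vocab, seed = 6)
  samples <- mk_samples(rand_seqs(30, 30), labels = rep(c(1L, 0L), 15))
  p <- predict(model, samples)
  n_bound <- sum(p >= 0.5)
  if (n_bound >= 3) {
    top <- selectTopPredictions(model, samples, n = 3)
    expect_length(top$index, 3)
    expect_identical(top$probability, sort(p[p >= 0.5], decreasing = TRUE)[1:3])
  }
  # a high threshold leaves fewer predicted-bound samples than requested
  thr <- as.numeric(quantile(p, 0.9))
  expect_warning(all_top <- selectTopPredictions(model, samples,
                                                 n = length(samples),
                                                 threshold = thr),
                 "predicted bound")
  expect_identical(length(all_top$index), sum(p >= thr))
  # permuting the evaluation set leaves the selected multiset unchanged
  perm <- sample(length(samples))
  expect_warning(ptop <- selectTopPredictions(model, samples[perm],
                                              n = length(samples),
                                              threshold = thr))
  expect_setequal(round(ptop$probability, 10), round(all_top$probability, 10))
})

test_that("the maximal-attention window matches a brute-force scan", {
  brute <- function(profile, w) {
    best <- -Inf; at <- NA
    for (i in 1:(length(profile) - w + 1)) {
      m <- mean(profile[i:(i + w - 1)])
      if (m > best + 1e-15) { best <- m; at <- i }
    }
    list(start = at - 1L, mean = best)
  }
  # uniform profile: leftmost tie wins
  u <- maxAttentionWindow(rep(1 / 50, 50), 20)
  expect_identical(u$start, 0L)
  expect_identical(u$end, 20L)
  # a single spike must be inside the window
  p <- numeric(100); p[37] <- 1
  w <- maxAttentionWindow(p, 20)
  expect_true(w$start < 37 && 37 <= w$end)
  expect_identical(w$start, brute(p, 20)$start)
  # random profiles up to length 200
  set.seed(82)
  for (rep in 1:50) {
    n <- sample(20:200, 1)
    prof <- runif(n); prof <- prof / sum(prof)
    wd <- sample(c(5L, 20L), 1)
    got <- maxAttentionWindow(prof, wd)
    ref <- brute(prof, wd)
    expect_identical(got$start, ref$start)
    expect_equal(got$mean_attention, ref$mean, tolerance = 1e-12)
  }
  expect_error(maxAttentionWindow(runif(10), 20), "exceeds")
})

test_that("k-mer counting is overlapping, within-region, totally ordered", {
  expect_identical(countKmers("AAAAAA", 6),
                   data.frame(kmer = "AAAAAA", count = 1L))
  # exhaustive enumeration: ACACAC -> AC,CA,AC,CA,AC; CACACA mirrors it
  rep2 <- countKmers(c("ACACAC", "CACACA"), 2)
  expect_identical(rep2$kmer, c("AC", "CA"))
  expect_identical(rep2$count, c(5L, 5L))
  # total counts equal sum over regions of (width - k + 1)
  set.seed(83)
  regions <- rand_seqs(10, sample(8:20, 10, replace = TRUE))
  rep6 <- countKmers(regions, 6)
  expect_identical(sum(rep6$count), sum(nchar(regions) - 6L + 1L))
  # descending counts with lexicographic ties
  expect_true(all(diff(rep6$count) <= 0))
  for (ct in unique(rep6$count)) {
    grp <- rep6$kmer[rep6$count == ct]
    expect_identical(grp, sort(grp))
  }
  expect_identical(nrow(countKmers(character(0), 6)), 0L)
  expect_error(countKmers("ACG", 6), "exceeds")
})

test_that("motif recovery accepts substrings and Hamming-1 matches", {
  rep_top <- data.frame(kmer = c("TGCATG", "AAAAAA"), count = c(5L, 2L))
  got <- motifRecoveryCheck(rep_top, "TGCATGGA", topM = 3)
  expect_true(got$recovered)
  expect_identical(got$rank, 1L)
  # one mismatch against a motif window still counts
  rep_ham <- data.frame(kmer = "TGCTTG", count = 3L)
  expect_true(motifRecoveryCheck(rep_ham, "TGCATG", topM = 1)$recovered)
  rep_far <- data.frame(kmer = "CCCCCC", count = 3L)
  expect_false(motifRecoveryCheck(rep_far, "TGCATG", topM = 1)$recovered)
  empty <- data.frame(kmer = character(0), count = integer(0))
  got0 <- motifRecoveryCheck(empty, "TGCATG")
  expect_false(got0$recovered)
  expect_true(is.na(got0$rank))
})

test_that("attention windows map back to strand-aware genomic coordinates", {
  gr <- GenomicRanges::GRanges(
    "chr5", IRanges::IRanges(start = c(1001, 2001), width = 100),
    strand = c("+", "-"))
  samples <- RBPSampleSet(gr, sequence = rand_seqs(2, 100),
                          label = c(1L, 1L), protein = c("P", "P"))
  regions <- data.frame(index = c(1L, 2L), probability = c(0.9, 0.8),
                        start = c(10L, 10L), end = c(30L, 30L),
                        mean_attention = c(0.1, 0.2))
  win <- attentionWindowsToGenomic(regions, samples)
  # plus strand: interval 0-based [1000,1100), window offset [10,30)
  expect_identical(GenomicRanges::start(win)[1] - 1L, 1010L)
  expect_identical(GenomicRanges::end(win)[1], 1030L)
  # minus strand: offsets count from the 3' genomic end
  expect_identical(GenomicRanges::end(win)[2], 2100L - 10L)
  expect_identical(GenomicRanges::start(win)[2] - 1L, 2100L - 30L)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeAttentionBed(win, bed)
  lines <- readLines(bed)
  expect_length(lines, 2)
  expect_identical(strsplit(lines[1], "\t")[[1]][1:3],
                   c("chr5", "1010", "1030"))
})

test_that("the interpretation pipeline is deterministic end to end", {
  set.seed(84)
  cfg <- tiny_config()
  vocab <- tiny_vocab()
  model <- buildModel(cfg, vocab, seed = 8)
  samples <- mk_samples(rand_seqs(20, 30), labels = rep(1L, 20))
  r1 <- suppressWarnings(extractAttentionRegions(model, samples, n = 5,
                                                 width = 10))
  r2 <- suppressWarnings(extractAttentionRegions(model, samples, n = 5,
                                                 width = 10))
  expect_identical(r1, r2)
  if (nrow(r1) > 0) {
    expect_true(all(nchar(r1$subsequence) == 10))
    expect_true(all(r1$end - r1$start == 10L))
  }
})
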