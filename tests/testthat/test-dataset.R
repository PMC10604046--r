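write_fasta <- function(seqs, headers, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path)
  path
}

test_that("benchmark headers parse into 0-based half-open intervals", {
  f <- withr::local_tempfile(fileext = ".fa")
  set.seed(40)
  write_fasta(rand_seqs(1, 150), "chr7:1000-1150(+)", f)
  man <- loadBenchmarkFasta(f, labels = 1, protein = "P", dialect = "rbp24-style")
  gr <- sampleIntervals(man)
  expect_identical(as.character(GenomicRanges::seqnames(gr)), "chr7")
  expect_identical(GenomicRanges::start(gr) - 1L, 1000L)
  expect_identical(GenomicRanges::end(gr), 1150L)
  expect_identical(as.character(GenomicRanges::strand(gr)), "+")
})

test_that("the rbp31-style grammar is comma separated", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(strrep("A", 101), "chr2,500,601,-", f)
  man <- loadBenchmarkFasta(f, labels = 0, protein = "P",
                            dialect = "rbp31-style")
  expect_identical(GenomicRanges::width(sampleIntervals(man)), 101L)
  expect_identical(as.character(GenomicRanges::strand(sampleIntervals(man))),
                   "-")
})

test_that("empty FASTA files produce an empty manifest", {
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  man <- loadBenchmarkFasta(f, labels = 1, protein = "P",
                            dialect = "rbp24-style")
  expect_length(man, 0)
})

test_that("unparseable headers name the header and the pattern", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta("ACGT", "weird_header_1", f)
  expect_error(loadBenchmarkFasta(f, labels = 1, protein = "P",
                                  dialect = "rbp24-style"),
               "weird_header_1")
})

# A toy collection builder: per-protein sets with controllable overlap.
toy_manifest <- function(protein, pos_starts, neg_starts, width = 10L,
                         split = "train") {
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(pos_starts, neg_starts),
                             width = width), "+")
  RBPSampleSet(gr, sequence = strrep("A", GenomicRanges::width(gr)),
               label = rep(c(1L, 0L), c(length(pos_starts), length(neg_starts))),
               protein = rep(protein, length(gr)),
               split = rep_len(split, length(gr)))
}

test_that("baseline purging removes overlapping negatives and rebalances", {
  # 4 positives, 4 negatives, exactly one negative overlaps a positive
  m <- toy_manifest("P1", pos_starts = c(100, 200, 300, 400),
                    neg_starts = c(105, 600, 700, 800))
  out <- buildBaseline(list(m), seed = 1)
  lab <- sampleLabels(out)
  expect_identical(sum(lab == 0L), 3L)
  expect_identical(sum(lab == 1L), 3L)
})

test_that("a collection without overlaps passes through unchanged", {
  m <- toy_manifest("P1", c(100, 200), c(400, 600))
  out <- buildBaseline(list(m), seed = 1)
  expect_identical(length(out), 4L)
})

test_that("excluding the held-out protein removes all its samples", {
  m1 <- toy_manifest("P1", c(100, 200), c(400, 600))
  m2 <- toy_manifest("P2", c(1000, 1200), c(1400, 1600))
  out <- buildBaseline(list(m1, m2), exclude = "P2", seed = 1)
  expect_false("P2" %in% sampleProteins(out))
  expect_error(buildBaseline(list(m1, m2), exclude = "P9"), "not present")
  expect_error(buildBaseline(list(m1), exclude = "P1"), "empties")
})

test_that("strand handling of the overlap purge is switchable", {
  pos <- toy_manifest("P1", c(100), c(2000))
  neg <- toy_manifest("P2", c(3000), c(105))
  GenomicRanges::strand(neg@intervals) <- c("+", "-")  # the negative on minus
  same <- buildBaseline(list(pos, neg), seed = 1)
  expect_identical(sum(sampleLabels(same) == 0L), 2L)  # opposite strand kept
  blind <- buildBaseline(list(pos, neg), ignoreStrand = TRUE, seed = 1)
  expect_identical(sum(sampleLabels(blind) == 0L), 1L)
})

test_that("purge completeness and ratio preservation hold on random toys", {
  set.seed(41)
  for (rep in 1:60) {
    mans <- lapply(1:3, function(p) {
      npos <- sample(3:12, 1); nneg <- sample(3:20, 1)
      toy_manifest(paste0("P", p),
                   sample(seq(1, 5000, by = 8), npos),
                   sample(seq(1, 5000, by = 8), nneg))
    })
    before <- do.call(rbind, lapply(mans, function(m)
      table(factor(sampleLabels(m), levels = 0:1))))
    ratio_before <- sum(before[, "1"]) / sum(before[, "0"])
    out <- buildBaseline(mans, seed = rep)
    lab <- sampleLabels(out)
    if (sum(lab == 0L) == 0L) next
    # no remaining negative overlaps any input positive
    pos_all <- do.call(c, unname(lapply(mans, function(m)
      sampleIntervals(m)[sampleLabels(m) == 1L])))
    ov <- GenomicRanges::findOverlaps(
      sampleIntervals(out)[lab == 0L], pos_all, minoverlap = 1L)
    expect_length(ov, 0)
    ratio_after <- sum(lab == 1L) / sum(lab == 0L)
    expect_lte(abs(ratio_after - ratio_before), 1 / sum(lab == 0L))
  }
})

test_that("the 9:1 split hits the documented counts", {
  m <- toy_manifest("P1", seq(1, 8000, by = 8)[1:500],
                    seq(40001, 48000, by = 8)[1:500])
  sp <- splitTrainVal(m, c(9, 1), seed = 2)
  expect_identical(length(sp$train), 900L)
  expect_identical(length(sp$validation), 100L)
  expect_length(intersect(
    GenomicRanges::start(sampleIntervals(sp$train)),
    GenomicRanges::start(sampleIntervals(sp$validation))), 0)
  m10 <- toy_manifest("P1", seq(1, 80, by = 8)[1:5],
                      seq(401, 480, by = 8)[1:5])
  sp10 <- splitTrainVal(m10, c(9, 1), seed = 2)
  expect_identical(length(sp10$train), 9L)
  expect_identical(length(sp10$validation), 1L)
})

test_that("splitting is stratified and deterministic under a seed", {
  # 995 samples at a 4:1 class ratio: round() allocation per class
  m <- toy_manifest("P1", seq(1, 10000, by = 8)[1:796],
                    seq(80001, 90000, by = 8)[1:199])
  sp <- splitTrainVal(m, c(9, 1), seed = 3)
  expect_identical(sum(sampleLabels(sp$validation) == 1L), 80L)  # round(79.6)
  expect_identical(sum(sampleLabels(sp$validation) == 0L), 20L)  # round(19.9)
  sp2 <- splitTrainVal(m, c(9, 1), seed = 3)
  expect_identical(GenomicRanges::start(sampleIntervals(sp2$validation)),
                   GenomicRanges::start(sampleIntervals(sp$validation)))
  expect_error(splitTrainVal(m[0], c(9, 1)), "empty")
})

test_that("nested subsamples are exact and nested per class", {
  set.seed(42)
  m <- toy_manifest("P1", seq(1, 2000, by = 8)[1:60],
                    seq(20001, 22000, by = 8)[1:60])
  rungs <- nestedSubsample(m, c(2, 4, 10, 25), seed = 9)
  key <- function(x) GenomicRanges::start(sampleIntervals(x))
  for (i in seq_along(rungs)) {
    lab <- sampleLabels(trainingSet(rungs[[i]]))
    s <- as.integer(names(rungs)[i])
    expect_identical(as.integer(table(lab)), c(s, s))
    if (i > 1)
      expect_true(all(key(trainingSet(rungs[[i - 1]])) %in%
                      key(trainingSet(rungs[[i]]))))
  }
  expect_error(nestedSubsample(m, c(10, 4)), "ascending")
  expect_message(nestedSubsample(m, c(10, 1000)), "skipping")
})

test_that("evaluation samples never leak into baseline or subsample rungs", {
  tr <- toy_manifest("P1", c(100, 200, 300), c(500, 600, 700))
  ev <- toy_manifest("P1", c(5100, 5200), c(5500, 5600), split = "eval")
  m <- c(tr, ev)
  base <- buildBaseline(list(m), seed = 1)
  expect_length(intersect(
    GenomicRanges::start(sampleIntervals(base)),
    GenomicRanges::start(sampleIntervals(ev))), 0)
  rungs <- nestedSubsample(m, c(2), seed = 1)
  expect_identical(length(evaluationSet(rungs[[1]])), 4L)
  expect_length(intersect(
    GenomicRanges::start(sampleIntervals(trainingSet(rungs[[1]]))),
    GenomicRanges::start(sampleIntervals(ev))), 0)
})

test_that("manifests persist to plain text and load back identically", {
  set.seed(43)
  seqs <- rand_seqs(6, 14)
  x <- mk_samples(seqs, labels = c(1, 1, 1, 0, 0, 0),
                  strand = c("+", "-", "+", "-", "+", "-"))
  x@split <- rep(c("train", "eval"), 3)
  dir <- withr::local_tempdir()
  writeManifest(x, dir, "toy")
  y <- readManifest(dir, "toy")
  expect_identical(sampleSequences(y), sampleSequences(x))
  expect_identical(sampleStructures(y), sampleStructures(x))
  expect_identical(sampleLabels(y), sampleLabels(x))
  expect_identical(sampleSplit(y), sampleSplit(x))
  expect_identical(GenomicRanges::start(sampleIntervals(y)),
                   GenomicRanges::start(sampleIntervals(x)))
  expect_equal(as.list(sampleConservation(y)),
               as.list(sampleConservation(x)), tolerance = 1e-3)
})

test_that("prepareSamples recenters and re-extracts coherently", {
  dir <- withr::local_tempdir()
  set.seed(44)
  chr <- paste(sample(DNA, 4000, replace = TRUE), collapse = "")
  fa <- file.path(dir, "g.fa")
  ss <- Biostrings::DNAStringSet(chr)
  names(ss) <- "chrP"
  Biostrings::writeXStringSet(ss, fa)
  gr <- GenomicRanges::GRanges(
    "chrP", IRanges::IRanges(start = c(501, 1501), width = c(80, 120)),
    strand = c("+", "-"))
  man <- RBPSampleSet(gr, label = c(1L, 0L), protein = c("P", "P"))
  out <- prepareSamples(man, fa, L = 60)
  expect_true(all(GenomicRanges::width(sampleIntervals(out)) == 60L))
  expect_identical(nchar(sampleSequences(out)), c(60L, 60L))
  expect_identical(sampleSequences(out),
                   extractSequences(fa, sampleIntervals(out)))
  expect_identical(nchar(sampleStructures(out)), c(60L, 60L))
})
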