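test_that("rbp31-style collections have fixed 101-nt intervals at 1:4", {
  spec <- syntheticSpec(nProteins = 2, nPos = 15, dialect = "rbp31-style",
                        seed = 5)
  coll <- generateCollection(spec, withr::local_tempdir())
  for (man in coll$manifests) {
    expect_true(all(GenomicRanges::width(sampleIntervals(man)) == 101L))
    lab <- sampleLabels(man)
    expect_identical(sum(lab == 0L) / sum(lab == 1L), 4)
  }
})

test_that("rbp24-style native lengths stay within the configured range", {
  spec <- syntheticSpec(nProteins = 1, nPos = 30, dialect = "rbp24-style",
                        seed = 6)
  coll <- generateCollection(spec, withr::local_tempdir())
  w <- GenomicRanges::width(sampleIntervals(coll$manifests[[1]]))
  expect_true(all(w >= 150L & w <= 375L))
  lab <- sampleLabels(coll$manifests[[1]])
  expect_identical(sum(lab == 0L), sum(lab == 1L))
})

test_that("zero mutation plants the exact consensus in every positive", {
  spec <- syntheticSpec(nProteins = 1, coreMotif = "ACGTGA",
                        flankMotifs = "", motifMutationRate = 0,
                        nPos = 25, dialect = "rbp24-style", seed = 7)
  coll <- generateCollection(spec, withr::local_tempdir())
  man <- coll$manifests[[1]]
  pos <- sampleSequences(man)[sampleLabels(man) == 1L]
  neg <- sampleSequences(man)[sampleLabels(man) == 0L]
  expect_true(all(grepl("ACGTGA", pos, fixed = TRUE)))
  # negatives are background without the motif, so a substring-scan
  # classifier separates the classes perfectly
  sc <- as.integer(grepl("ACGTGA", c(pos, neg), fixed = TRUE))
  lab <- rep(c(1L, 0L), c(length(pos), length(neg)))
  expect_identical(evaluateAUC(sc, lab), 1)
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- syntheticSpec(nProteins = 2, nPos = 10, seed = 8)
  c1 <- generateCollection(spec, withr::local_tempdir())
  c2 <- generateCollection(spec, withr::local_tempdir())
  for (p in names(c1$manifests)) {
    expect_identical(sampleSequences(c1$manifests[[p]]),
                     sampleSequences(c2$manifests[[p]]))
    expect_identical(GenomicRanges::start(sampleIntervals(c1$manifests[[p]])),
                     GenomicRanges::start(sampleIntervals(c2$manifests[[p]])))
    expect_identical(as.list(sampleConservation(c1$manifests[[p]])),
                     as.list(sampleConservation(c2$manifests[[p]])))
  }
  expect_identical(readLines(c1$genome), readLines(c2$genome))
  expect_identical(readLines(c1$track), readLines(c2$track))
})

test_that("motif positions carry elevated conservation", {
  spec <- syntheticSpec(nProteins = 1, coreMotif = "ACGTGA",
                        flankMotifs = "", motifMutationRate = 0,
                        nPos = 60, conservation = c(0, 1, 2, 0.5),
                        dialect = "rbp24-style", seed = 9)
  coll <- generateCollection(spec, withr::local_tempdir())
  man <- coll$manifests[[1]]
  pos_i <- which(sampleLabels(man) == 1L)
  motif_sc <- c(); bg_sc <- c()
  for (i in pos_i) {
    s <- sampleSequences(man)[i]
    off <- regexpr("ACGTGA", s, fixed = TRUE)
    v <- as.numeric(sampleConservation(man)[[i]])
    motif_sc <- c(motif_sc, v[off:(off + 5L)])
    bg_sc <- c(bg_sc, v[-(off:(off + 5L))])
  }
  # means match the spec within 3 standard errors
  expect_lt(abs(mean(motif_sc) - 2), 3 * 0.5 / sqrt(length(motif_sc)))
  expect_lt(abs(mean(bg_sc) - 0), 3 * 1 / sqrt(length(bg_sc)))
})

test_that("a log-odds motif scan separates classes at 5% mutation", {
  spec <- syntheticSpec(nProteins = 1, motifMutationRate = 0.05,
                        nPos = 80, dialect = "rbp24-style", seed = 10)
  coll <- generateCollection(spec, withr::local_tempdir())
  man <- coll$manifests[[1]]
  # scan with the full planted consensus (shared core + protein flank)
  motif <- strsplit(paste0(spec@coreMotif, spec@flankMotifs[1]), "")[[1]]
  score_seq <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch); m <- length(motif)
    best <- -Inf
    for (i in 1:(n - m + 1)) {
      w <- ch[i:(i + m - 1)]
      sc <- sum(ifelse(w == motif, log(0.95 / 0.25), log((0.05 / 3) / 0.25)))
      if (sc > best) best <- sc
    }
    best
  }
  sc <- vapply(sampleSequences(man), score_seq, numeric(1))
  expect_gt(evaluateAUC(sc, sampleLabels(man)), 0.95)
})

test_that("planted hairpins give positives a folded terminal stem", {
  spec <- syntheticSpec(nProteins = 1, nPos = 15, plantHairpins = TRUE,
                        dialect = "rbp24-style", seed = 11)
  coll <- generateCollection(spec, withr::local_tempdir())
  man <- coll$manifests[[1]]
  st <- sampleStructures(man)[sampleLabels(man) == 1L]
  expect_true(all(startsWith(st, "(((")))
})

test_that("the transfer family excludes the held-out protein's flank", {
  spec <- syntheticSpec(nProteins = 3, nPos = 10, seed = 12)
  fam <- generateTransferFamily(spec, withr::local_tempdir())
  expect_length(fam$baseline, 2)
  held_prot <- unique(sampleProteins(fam$heldout))
  base_prots <- unlist(lapply(fam$baseline,
                              function(m) unique(sampleProteins(m))))
  expect_false(held_prot %in% base_prots)
  expect_error(generateTransferFamily(syntheticSpec(nProteins = 1, nPos = 5)),
               "at least 2")
})

test_that("baseline positives carry the shared core at the expected rate", {
  mut <- 0.1
  spec <- syntheticSpec(nProteins = 2, nPos = 60, motifMutationRate = mut,
                        seed = 13)
  fam <- generateTransferFamily(spec, withr::local_tempdir())
  man <- fam$baseline[[1]]
  pos <- sampleSequences(man)[sampleLabels(man) == 1L]
  frac <- mean(grepl(spec@coreMotif, pos, fixed = TRUE))
  p_intact <- (1 - mut)^nchar(spec@coreMotif)
  # within binomial error (3 sd), plus chance background hits
  expect_gt(frac, p_intact - 3 * sqrt(p_intact * (1 - p_intact) / length(pos)))
})

test_that("central motif placement survives recentring at half length", {
  # the central 50% of an l-nt interval sits inside the recentred window
  # whenever L >= l/2, so L = 200 retains every motif for l <= 375
  spec <- syntheticSpec(nProteins = 1, coreMotif = "ACGTGA",
                        flankMotifs = "", motifMutationRate = 0,
                        nPos = 25, dialect = "rbp24-style", seed = 14)
  coll <- generateCollection(spec, withr::local_tempdir())
  prep <- prepareSamples(coll$manifests[[1]], coll$genome, coll$track,
                         L = 200)
  pos <- sampleSequences(prep)[sampleLabels(prep) == 1L]
  expect_true(all(grepl("ACGTGA", pos, fixed = TRUE)))
})
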