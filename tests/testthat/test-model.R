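# Builds a small model plus encoded samples shared across blocks.
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(51)
      cfg <- tiny_config(n = 30L)
      vocab <- tiny_vocab()
      seqs <- rand_seqs(12, 30)
      samples <- mk_samples(seqs, labels = rep(c(1L, 0L), 6))
      model <- buildModel(cfg, vocab, seed = 3)
      cache <<- list(cfg = cfg, vocab = vocab, samples = samples,
                     model = model)
    }
    cache
  }
})

test_that("configurations outside the tuned space need an explicit flag", {
  expect_error(modelConfig(bigruUnits = 100), "outside the search space")
  expect_silent(modelConfig(bigruUnits = 100, outOfSpace = TRUE))
  expect_error(modelConfig(branches = character(0)), "non-empty")
})

test_that("the sequence branch requires a matching vocabulary", {
  cfg <- tiny_config()
  expect_error(buildModel(cfg, NULL, seed = 1), "requires a vocabulary")
  wrong <- tiny_vocab(k = 32)
  expect_error(buildModel(cfg, wrong, seed = 1), "does not match")
})

test_that("parameter count grows with the BiGRU width", {
  vocab <- tiny_vocab()
  m64 <- buildModel(modelConfig(bigruUnits = 64), vocab, seed = 1)
  m128 <- buildModel(modelConfig(bigruUnits = 128), vocab, seed = 1)
  expect_gt(parameterCount(m128), parameterCount(m64))
})

test_that("predictions are probabilities, deterministic and batch-stable", {
  fx <- model_fixture()
  p <- predict(fx$model, fx$samples)
  expect_length(p, length(fx$samples))
  expect_true(all(p >= 0 & p <= 1))
  # duplicated sample in one batch scores identically
  dup <- fx$samples[c(1, 1, 2)]
  pd <- predict(fx$model, dup)
  expect_identical(pd[1], pd[2])
  # batched and single-sample calls agree
  singles <- vapply(seq_along(fx$samples),
                    function(i) predict(fx$model, fx$samples[i]),
                    numeric(1))
  expect_equal(singles, p, tolerance = 1e-6)
  # permuting the batch permutes the outputs
  perm <- c(5, 2, 9, 1, 12, 3)
  expect_equal(predict(fx$model, fx$samples[perm]), p[perm],
               tolerance = 1e-10)
})

test_that("an S-only model ignores structure and conservation entirely", {
  set.seed(52)
  cfg <- tiny_config(branches = "S")
  vocab <- tiny_vocab()
  model <- buildModel(cfg, vocab, seed = 5)
  seqs <- rand_seqs(6, 30)
  a <- mk_samples(seqs)
  b <- a
  b@structure <- vapply(nchar(seqs), function(l) strrep("(", l),
                        character(1))   # clearly different from a's
  b@conservation <- IRanges::NumericList(lapply(nchar(seqs), rnorm))
  expect_identical(predict(model, a), predict(model, b))
})

test_that("encoding rejects mismatched widths and missing features", {
  fx <- model_fixture()
  short <- mk_samples(rand_seqs(3, 20))
  expect_error(encodeSamples(short, fx$vocab, fx$cfg), "interval length")
  nostruct <- fx$samples
  nostruct@structure <- rep(NA_character_, length(nostruct))
  expect_error(encodeSamples(nostruct, fx$vocab, fx$cfg), "no structure")
  nocons <- fx$samples
  nocons@conservation <- IRanges::NumericList(
    rep(list(numeric(0)), length(nocons)))
  expect_error(encodeSamples(nocons, fx$vocab, fx$cfg), "no conservation")
})

test_that("analytic gradients match numerical differentiation", {
  fx <- model_fixture()
  enc <- encodeSamples(fx$samples[1:4], fx$vocab, fx$cfg)
  params <- fx$model@params
  fwd <- asNamespace("rbptl")$.model_forward
  bwd <- asNamespace("rbptl")$.model_backward
  loss <- function(p) {
    pr <- pmin(pmax(fwd(p, fx$cfg, enc, FALSE)$prob, 1e-12), 1 - 1e-12)
    -mean(enc$y * log(pr) + (1 - enc$y) * log(1 - pr))
  }
  fw <- fwd(params, fx$cfg, enc, FALSE)
  grads <- bwd(params, fx$cfg, enc, fw, (fw$prob - enc$y) / enc$B)
  eps <- 1e-6
  set.seed(53)
  for (nm in names(grads)) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (loss(p2) - loss(p3)) / (2 * eps)
      ana <- as.vector(grads[[nm]])[i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4,
                label = sprintf("gradient of %s[%d] (analytic %.3g vs numeric %.3g)",
                                nm, i, ana, num))
    }
  }
})

test_that("attention profiles are distributions aligned to bases", {
  fx <- model_fixture()
  set.seed(54)
  samples <- mk_samples(rand_seqs(40, 30))
  profs <- attentionProfiles(fx$model, samples)
  enc <- encodeSamples(samples, fx$vocab, fx$cfg)
  fw <- asNamespace("rbptl")$.model_forward(fx$model@params, fx$cfg, enc,
                                            FALSE)
  for (i in seq_along(profs)) {
    expect_length(profs[[i]], 30)
    expect_true(all(profs[[i]] >= 0))
    expect_equal(sum(profs[[i]]), 1, tolerance = 1e-5)
    # each token's bases share its weight equally
    spans <- enc$spans[[i]]
    alpha <- fw$alpha[i, seq_len(nrow(spans))]
    for (tk in seq_len(nrow(spans))) {
      seg <- profs[[i]][(spans[tk, "start"] + 1):spans[tk, "end"]]
      expect_equal(sum(seg), alpha[tk], tolerance = 1e-8)
      expect_lt(diff(range(seg)), 1e-12)
    }
  }
})

test_that("a model without the S branch cannot export attention", {
  vocab <- tiny_vocab()
  cfg <- tiny_config(branches = c("SS", "EC"))
  model <- buildModel(cfg, seed = 2)
  samples <- mk_samples(rand_seqs(2, 30))
  expect_error(attentionProfiles(model, samples), "S branch")
})

test_that("checkpoints reproduce predictions bit for bit", {
  fx <- model_fixture()
  dir <- withr::local_tempdir()
  saveModel(fx$model, file.path(dir, "ckpt"))
  back <- loadModel(file.path(dir, "ckpt"))
  expect_identical(predict(back, fx$samples), predict(fx$model, fx$samples))
  expect_identical(vocabTokens(back@vocab), vocabTokens(fx$model@vocab))
  expect_error(loadModel(file.path(dir, "nope")), "checkpoint")
})

test_that("training is reproducible under a fixed seed", {
  fx <- model_fixture()
  sp <- splitTrainVal(fx$samples, c(3, 1), seed = 1)
  spec <- trainSpec("SCR", maxEpochs = 2, batchSize = 4, seed = 99)
  f1 <- trainProtocol(sp$train, sp$validation, spec, config = fx$cfg,
                      vocab = fx$vocab)
  f2 <- trainProtocol(sp$train, sp$validation, spec, config = fx$cfg,
                      vocab = fx$vocab)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1$model, fx$samples),
                   predict(f2$model, fx$samples))
})
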