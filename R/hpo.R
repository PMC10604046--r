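## Staged hyperparameter optimisation: four stages following the network's
## structure (1: BiGRU units x embedding dimension; 2: tokenizer size;
## 3: convolution filters x ResNet blocks, shared by the SS and EC branches;
## 4: fully-connected layer count). Every candidate is scored by mean AUC
## over a stratified k-fold cross-validation (default 10) of the training
## data, and each stage's winner is frozen before the next stage runs, so
## the default space costs 16 + 3 + 6 + 2 = 27 evaluated configurations.
## A random-search baseline shares the identical scoring path.

#' The staged hyperparameter search space
#'
#' Defaults reproduce the tuned space: BiGRU units {64,128,256,512} x
#' embedding {16,32,64,128} (stage 1, 16 combinations), tokenizer size
#' {16,32,64} (stage 2, 3), filters {32,64,128} x ResNet blocks {2,3}
#' (stage 3, 6), dense layers {2,3} (stage 4, 2).
#'
#' @slot stage1,stage2,stage3,stage4 named lists of option vectors.
#' @export
setClass("SearchSpace",
  representation(stage1 = "list", stage2 = "list", stage3 = "list",
                 stage4 = "list"))

setValidity("SearchSpace", function(object) {
  need <- list(stage1 = c("bigruUnits", "embeddingDim"),
               stage2 = "tokenizerK",
               stage3 = c("cnnFilters", "resnetBlocks"),
               stage4 = "denseLayers")
  msg <- NULL
  for (st in names(need)) {
    sl <- slot(object, st)
    if (!setequal(names(sl), need[[st]]))
      msg <- c(msg, paste0(st, " must have fields ",
                           paste(need[[st]], collapse = ", ")))
    if (any(lengths(sl) == 0L))
      msg <- c(msg, paste0(st, " has an empty option list"))
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname SearchSpace-class
#' @param stage1,stage2,stage3,stage4 named option lists (see defaults).
#' @return a \code{SearchSpace}
#' @export
searchSpace <- function(stage1 = list(bigruUnits = c(64L, 128L, 256L, 512L),
                                      embeddingDim = c(16L, 32L, 64L, 128L)),
                        stage2 = list(tokenizerK = c(16L, 32L, 64L)),
                        stage3 = list(cnnFilters = c(32L, 64L, 128L),
                                      resnetBlocks = c(2L, 3L)),
                        stage4 = list(denseLayers = c(2L, 3L))) {
  new("SearchSpace", stage1 = stage1, stage2 = stage2, stage3 = stage3,
      stage4 = stage4)
}

#' @rdname SearchSpace-class
#' @param space a \code{SearchSpace}.
#' @return \code{stagedEvaluationCount}: total configurations a staged run
#'   evaluates (the sum over stages of the per-stage combination counts);
#'   \code{jointSpaceSize}: size of the full cartesian space.
#' @export
stagedEvaluationCount <- function(space) {
  sum(vapply(list(space@stage1, space@stage2, space@stage3, space@stage4),
             function(s) prod(lengths(s)), numeric(1)))
}

#' @rdname SearchSpace-class
#' @param includeTokenizer count the tokenizer dimension in the joint space.
#' @export
jointSpaceSize <- function(space, includeTokenizer = TRUE) {
  stages <- list(space@stage1, space@stage3, space@stage4)
  if (includeTokenizer) stages <- c(stages, list(space@stage2))
  prod(vapply(stages, function(s) prod(lengths(s)), numeric(1)))
}

setMethod("show", "SearchSpace", function(object) {
  cat("SearchSpace: ", stagedEvaluationCount(object),
      " staged evaluations; joint space ", jointSpaceSize(object), "\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## Cross-validated scoring (shared by staged and random search)
## ---------------------------------------------------------------------------

.stratified_folds <- function(labels, k, seed) {
  idx_by <- split(seq_along(labels), labels)
  if (any(lengths(idx_by) < k))
    stop("stratification error: a class has fewer than ", k,
         " samples, so some fold would lack it")
  fold <- integer(length(labels))
  .with_seed(seed, {
    for (cls in names(idx_by)) {
      ix <- sample(idx_by[[cls]])
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  fold
}

## Default scorer: SCR-train on the fold-complement, AUC on the fold.
## Shortened budget (max 30 epochs, patience 3) keeps HPO desk-scale; final
## models are retrained with a full TrainSpec afterwards.
.default_cv_scorer <- function(maxEpochs = 30L, patience = 3L,
                               batchSize = 64L) {
  function(config, trainSet, valSet, vocab, seed) {
    spec <- trainSpec("SCR", maxEpochs = maxEpochs, patience = patience,
                      batchSize = batchSize, seed = seed)
    fit <- trainProtocol(trainSet, valSet, spec, config = config,
                         vocab = vocab)
    evaluateAUC(predict(fit$model, valSet), sampleLabels(valSet))
  }
}

## Score one candidate config by mean CV AUC; returns the per-fold log rows.
.score_config <- function(config, data, fold, vocabs, seed, scorer, stage) {
  vocab <- vocabs[[as.character(config@tokenizerK)]]
  k <- max(fold)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- data[fold != f]
    va <- data[fold == f]
    aucs[f] <- scorer(config, tr, va, vocab,
                      .child_seed(seed, paste0("fold", f)))
  }
  cfg_json <- as.character(jsonlite::toJSON(list(
    bigruUnits = config@bigruUnits, embeddingDim = config@embeddingDim,
    tokenizerK = config@tokenizerK, cnnFilters = config@cnnFilters,
    resnetBlocks = config@resnetBlocks, denseLayers = config@denseLayers),
    auto_unbox = TRUE))
  data.frame(stage = stage, config = cfg_json, fold = seq_len(k),
             auc = aucs, mean_auc = mean(aucs))
}

## Closed-form trainable-parameter count of a configuration (kept in lock
## step with .init_params; checked against parameterCount() in the tests).
.param_count_config <- function(cfg, V) {
  k <- nnConstants()
  H <- cfg@bigruUnits; E <- cfg@embeddingDim; Fc <- cfg@cnnFilters
  total <- 0
  din <- 0L
  if ("S" %in% cfg@branches) {
    A <- k$attentionDim
    total <- total + V * E +
      (k$convKernel * E + 1) * Fc +
      2 * 3 * (Fc * H + H * H + H) +
      2 * H * A + A + A
    din <- din + 2L * H
  }
  for (br in intersect(c("SS", "EC"), cfg@branches)) {
    Cin <- if (br == "SS") 3L else 1L
    for (i in seq_len(cfg@resnetBlocks)) {
      ci <- if (i == 1L) Cin else Fc
      total <- total + (k$resKernel * ci + 1) * Fc + 2 * Fc +
        (k$resKernel * Fc + 1) * Fc + 2 * Fc +
        if (ci != Fc) ci * Fc else 0
    }
    din <- din + Fc
  }
  W <- k$headWidth
  total <- total + (din + 1) * W + (cfg@denseLayers - 1L) * (W + 1) * W +
    W + 1
  total
}

## Deterministic tie-break: higher mean AUC, then fewer parameters, then
## earlier option order.
.pick_winner <- function(configs, mean_aucs, vocabs) {
  best <- which(mean_aucs == max(mean_aucs))
  if (length(best) > 1L) {
    sizes <- vapply(best, function(i) {
      cfg <- configs[[i]]
      .param_count_config(cfg,
                          vocabSize(vocabs[[as.character(cfg@tokenizerK)]]))
    }, numeric(1))
    best <- best[order(sizes, best)][1L]
  }
  best[1L]
}

.train_vocabs <- function(data, ks) {
  corpus <- sampleSequences(data)
  vs <- lapply(ks, function(k) trainBPE(corpus, k))
  names(vs) <- as.character(ks)
  vs
}

#' Run the staged hyperparameter-optimisation pipeline
#'
#' Stages run in order; each candidate is scored by mean AUC over
#' \code{cvFolds}-fold stratified cross-validation of \code{data}, and the
#' per-stage winner is frozen into all later stages. The log records every
#' (stage, config, fold, auc) evaluation. Ties are broken toward the
#' smaller model, then option order.
#'
#' @param space a \linkS4class{SearchSpace}.
#' @param data an \linkS4class{RBPSampleSet} of training samples (use
#'   [downsampleForHPO()] first for very large sets).
#' @param cvFolds number of cross-validation folds (default 10).
#' @param seed master seed.
#' @param scorer scoring function \code{(config, trainSet, valSet, vocab,
#'   seed) -> AUC}; the default trains a shortened SCR model. Staged and
#'   random search share this path.
#' @param baseConfig template config supplying fields outside the search
#'   space (branches, interval length).
#' @return list with \code{best} (a \linkS4class{ModelConfig}), \code{log}
#'   (data.frame of every evaluation, with a \code{selected} flag) and
#'   \code{vocabs}
#' @export
runStagedHPO <- function(space, data, cvFolds = 10L, seed = 1L,
                         scorer = .default_cv_scorer(),
                         baseConfig = modelConfig()) {
  stopifnot(is(space, "SearchSpace"))
  validObject(space)
  fold <- .stratified_folds(sampleLabels(data), cvFolds, seed)
  vocabs <- .train_vocabs(data, space@stage2$tokenizerK)
  ## ensure the frozen pre-stage-2 tokenizer has a vocabulary too
  k0 <- baseConfig@tokenizerK
  if (!as.character(k0) %in% names(vocabs))
    vocabs[[as.character(k0)]] <- trainBPE(sampleSequences(data), k0)

  current <- baseConfig
  log <- NULL
  stage_fields <- list(`1` = space@stage1, `2` = space@stage2,
                       `3` = space@stage3, `4` = space@stage4)
  for (st in names(stage_fields)) {
    opts <- expand.grid(stage_fields[[st]], KEEP.OUT.ATTRS = FALSE)
    configs <- lapply(seq_len(nrow(opts)), function(i) {
      cfg <- current
      for (nm in names(opts)) slot(cfg, nm) <- as.integer(opts[i, nm])
      validObject(cfg)
      cfg
    })
    rows <- lapply(seq_along(configs), function(i)
      .score_config(configs[[i]], data, fold, vocabs,
                    .child_seed(seed, paste0("stage", st, "cand", i)),
                    scorer, stage = as.integer(st)))
    means <- vapply(rows, function(r) r$mean_auc[1L], numeric(1))
    win <- .pick_winner(configs, means, vocabs)
    for (i in seq_along(rows)) rows[[i]]$selected <- i == win
    log <- rbind(log, do.call(rbind, rows))
    current <- configs[[win]]
  }
  list(best = current, log = log, vocabs = vocabs)
}

#' Downsample a training set for hyperparameter optimisation
#'
#' Keeps \code{round(fraction * class size)} training samples per class
#' (preserving the positive:negative ratio within rounding), selected
#' uniformly at random under \code{seed}. Evaluation samples pass through
#' unchanged.
#'
#' @param manifest an \linkS4class{RBPSampleSet}.
#' @param fraction fraction in (0, 1].
#' @param seed RNG seed.
#' @return an \linkS4class{RBPSampleSet}
#' @export
downsampleForHPO <- function(manifest, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (fraction == 1) return(manifest)
  tr <- trainingSet(manifest)
  ev <- evaluationSet(manifest)
  lab <- sampleLabels(tr)
  keep <- .with_seed(seed, {
    unlist(lapply(split(seq_along(lab), lab), function(ix) {
      nk <- as.integer(round(fraction * length(ix)))
      if (nk == 0L)
        stop("downsampling to fraction ", fraction,
             " empties a class (", length(ix), " samples)")
      sample(ix, nk)
    }))
  })
  out <- tr[sort(keep)]
  if (length(ev) > 0L) out <- c(out, ev)
  out
}

#' Random-search baseline at matched trial count
#'
#' Samples configurations uniformly from the joint space (by default
#' without replacement, and excluding the tokenizer dimension, which a
#' plain random search cannot tune because tokenization happens during
#' preprocessing; enable \code{includeTokenizer} to lift that constraint)
#' and scores each with the identical cross-validation path as the staged
#' pipeline.
#'
#' @param space a \linkS4class{SearchSpace}.
#' @param trials number of sampled configurations (27 matches the staged
#'   pipeline's evaluation count on the default space).
#' @param data,cvFolds,seed,scorer,baseConfig as in [runStagedHPO()].
#' @param includeTokenizer sample the tokenizer dimension too.
#' @param replace sample with replacement.
#' @return list with \code{best}, \code{log} and \code{vocabs}
#' @export
runRandomSearch <- function(space, trials, data, cvFolds = 10L, seed = 1L,
                            scorer = .default_cv_scorer(),
                            baseConfig = modelConfig(),
                            includeTokenizer = FALSE, replace = FALSE) {
  stopifnot(is(space, "SearchSpace"), trials >= 1L)
  joint <- c(space@stage1, space@stage3, space@stage4)
  if (includeTokenizer) joint <- c(joint, space@stage2)
  grid <- expand.grid(joint, KEEP.OUT.ATTRS = FALSE)
  if (!replace && trials > nrow(grid))
    stop("trials (", trials, ") exceed the joint space size (", nrow(grid),
         ") for no-replacement sampling")
  pick <- .with_seed(seed, sample.int(nrow(grid), trials, replace = replace))
  fold <- .stratified_folds(sampleLabels(data), cvFolds, seed)
  ks <- if (includeTokenizer) space@stage2$tokenizerK
        else baseConfig@tokenizerK
  vocabs <- .train_vocabs(data, unique(c(ks, baseConfig@tokenizerK)))
  configs <- lapply(pick, function(i) {
    cfg <- baseConfig
    for (nm in names(grid)) slot(cfg, nm) <- as.integer(grid[i, nm])
    validObject(cfg)
    cfg
  })
  rows <- lapply(seq_along(configs), function(i)
    .score_config(configs[[i]], data, fold, vocabs,
                  .child_seed(seed, paste0("trial", i)), scorer,
                  stage = NA_integer_))
  means <- vapply(rows, function(r) r$mean_auc[1L], numeric(1))
  win <- .pick_winner(configs, means, vocabs)
  for (i in seq_along(rows)) rows[[i]]$selected <- i == win
  list(best = configs[[win]], log = do.call(rbind, rows), vocabs = vocabs)
}
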