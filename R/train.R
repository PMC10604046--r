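## Training regimes (BS pretraining, SCR from scratch, TL fine-tuning),
## rank-based AUC evaluation, the benchmark experiment planner and the
## nested-subsampling experiment runner.

#' Area under the ROC curve (rank-based)
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, counting
#' ties as one half. Equivalent to the trapezoidal area under the ROC
#' curve and invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, same length.
#' @return AUC in [0, 1]
#' @examples
#' evaluateAUC(c(.9, .8, .4, .3, .2), c(1, 0, 1, 0, 0))
#' @export
evaluateAUC <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC is undefined: need at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

## ---------------------------------------------------------------------------
## Core fitting loop
## ---------------------------------------------------------------------------

#' Fit a model with early stopping on validation AUC
#'
#' Mini-batch Adam on the binary cross-entropy; after every epoch the
#' validation AUC is computed in inference mode and the best-validation
#' parameters are retained (the returned model is the best checkpoint, not
#' the last epoch). With \code{maxEpochs = 0} the input model is returned
#' untouched. Fully deterministic under \code{spec@seed}.
#'
#' @param model an \linkS4class{RBPModel}.
#' @param train,val \linkS4class{RBPSampleSet}s or [encodeSamples()] output.
#' @param spec a \linkS4class{TrainSpec}.
#' @return list with \code{model} (best checkpoint) and \code{history}
#'   (data.frame epoch, loss, val_auc)
#' @export
fitModel <- function(model, train, val, spec) {
  stopifnot(is(model, "RBPModel"), is(spec, "TrainSpec"))
  validObject(spec)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auc = numeric(0))
  if (spec@maxEpochs == 0L)
    return(list(model = model, history = history))
  config <- model@config
  encT <- if (is(train, "RBPSampleSet"))
    encodeSamples(train, model@vocab, config) else train
  encV <- if (is(val, "RBPSampleSet"))
    encodeSamples(val, model@vocab, config) else val

  params <- model@params
  n <- encT$B
  y <- encT$y
  w <- rep(1, n)
  if (spec@classWeights) {
    np <- sum(y == 1); nn <- n - np
    w <- ifelse(y == 1, n / (2 * np), n / (2 * nn))
  }
  state <- .adam_init(params[!grepl("^bn_run", names(params))])
  best_params <- params
  best_auc <- -Inf
  stall <- 0L

  .with_seed(spec@seed, {
    for (epoch in seq_len(spec@maxEpochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = spec@batchSize)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + spec@batchSize - 1L, n)]
        sl <- .slice_encoded(encT, idx)
        fw <- .model_forward(params, config, sl, training = TRUE)
        pb <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
        wb <- w[idx]
        loss <- -sum(wb * (sl$y * log(pb) + (1 - sl$y) * log(1 - pb))) /
          sum(wb)
        ep_loss <- ep_loss + loss * length(idx)
        dlogit <- wb * (fw$prob - sl$y) / sum(wb)
        grads <- .model_backward(params, config, sl, fw, dlogit)
        upd <- .adam_step(params[names(state$m)], grads, state,
                          lr = spec@learningRate, skip = spec@freeze)
        params[names(state$m)] <- upd$params
        state <- upd$state
        run_ups <- .collect_run_updates(fw, config)
        params[names(run_ups)] <- run_ups
      }
      tmp_model <- new("RBPModel", config = config, params = params,
                       vocab = model@vocab)
      val_scores <- predict(tmp_model, encV)
      val_auc <- evaluateAUC(val_scores, encV$y)
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss = ep_loss / n,
                                           val_auc = val_auc))
      if (val_auc > best_auc + 1e-9) {
        best_auc <- val_auc
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= spec@patience) break
      }
    }
  })
  list(model = new("RBPModel", config = config, params = best_params,
                   vocab = model@vocab),
       history = history)
}

#' Run one training protocol end to end
#'
#' \code{BS}/\code{SCR} build a fresh model from \code{config} and
#' \code{vocab}; \code{TL} loads the base checkpoint named by
#' \code{spec@initFrom} and fine-tunes all (non-frozen) layers. A config
#' passed alongside a TL spec must agree with the checkpoint's architecture
#' (error on mismatch, never silent reinitialisation).
#'
#' @param train,val \linkS4class{RBPSampleSet}s (or encoded inputs for
#'   pre-encoded pipelines).
#' @param spec a \linkS4class{TrainSpec}.
#' @param config a \linkS4class{ModelConfig} (BS/SCR; optional check for TL).
#' @param vocab a \linkS4class{BPEVocabulary} (BS/SCR with S branch).
#' @return list with \code{model} and \code{history}
#' @export
trainProtocol <- function(train, val, spec, config = NULL, vocab = NULL) {
  validObject(spec)
  if (spec@protocol == "TL") {
    model <- loadModel(spec@initFrom)
    if (!is.null(config)) {
      ck <- model@config
      for (nm in c("bigruUnits", "embeddingDim", "tokenizerK", "cnnFilters",
                   "resnetBlocks", "denseLayers", "intervalLength")) {
        if (!identical(slot(ck, nm), slot(config, nm)))
          stop("checkpoint/config shape mismatch on '", nm, "': ",
               slot(ck, nm), " vs ", slot(config, nm))
      }
      if (!setequal(ck@branches, config@branches))
        stop("checkpoint/config mismatch on branches")
    }
  } else {
    if (is.null(config)) stop("BS/SCR training requires a ModelConfig")
    model <- buildModel(config, vocab, seed = spec@seed)
  }
  fitModel(model, train, val, spec)
}

## ---------------------------------------------------------------------------
## Experiment planning
## ---------------------------------------------------------------------------

#' Plan the full benchmark experiment matrix
#'
#' One base-model (BS) job per collection, plus one from-scratch (SCR) and
#' one fine-tuning (TL) job per protein dataset; every TL job references its
#' collection's BS job. Two collections of 24 and 31 proteins yield the
#' full 2 + 55 + 55 = 112-job matrix.
#'
#' @param collections named list; each element is a character vector of
#'   protein ids or a list of per-protein manifests.
#' @return data.frame with columns job, protocol, collection, protein,
#'   init_from
#' @export
planExperiments <- function(collections) {
  stopifnot(is.list(collections), length(collections) > 0L,
            !is.null(names(collections)))
  rows <- list()
  for (cn in names(collections)) {
    cl <- collections[[cn]]
    prots <- if (is.character(cl)) cl
             else if (is.list(cl)) {
               if (!is.null(names(cl))) names(cl)
               else vapply(cl, function(m) unique(sampleProteins(m))[1L],
                           character(1))
             } else stop("collection '", cn, "' must be a character vector or list")
    if (length(prots) == 0L) stop("collection '", cn, "' is empty")
    bs_job <- paste0("BS_", cn)
    rows[[length(rows) + 1L]] <- data.frame(
      job = bs_job, protocol = "BS", collection = cn,
      protein = NA_character_, init_from = NA_character_)
    for (p in prots) {
      rows[[length(rows) + 1L]] <- data.frame(
        job = paste0("SCR_", cn, "_", p), protocol = "SCR", collection = cn,
        protein = p, init_from = NA_character_)
      rows[[length(rows) + 1L]] <- data.frame(
        job = paste0("TL_", cn, "_", p), protocol = "TL", collection = cn,
        protein = p, init_from = bs_job)
    }
  }
  plan <- do.call(rbind, rows)
  rownames(plan) <- NULL
  validateExperimentPlan(plan)
  plan
}

#' @rdname planExperiments
#' @param plan an experiment-plan data.frame.
#' @return \code{validateExperimentPlan}: \code{plan}, invisibly (errors on
#'   an invalid plan)
#' @export
validateExperimentPlan <- function(plan) {
  if (anyDuplicated(plan$job)) stop("experiment plan has duplicate jobs")
  tl <- plan[plan$protocol == "TL", ]
  bs <- plan$job[plan$protocol == "BS"]
  missing <- setdiff(tl$init_from, bs)
  if (length(missing))
    stop("TL job(s) reference missing BS job(s): ",
         paste(missing, collapse = ", "))
  invisible(plan)
}

## ---------------------------------------------------------------------------
## Nested-subsampling experiment
## ---------------------------------------------------------------------------

#' Compare TL and SCR across nested training-set sizes
#'
#' For every rung of the nested subsample ladder and every replicate, trains
#' one SCR model from scratch and fine-tunes one TL model from the base
#' checkpoint, evaluating both on the manifest's (unchanged) evaluation
#' set. Replicate seeds are derived deterministically from \code{seed}.
#'
#' @param manifest an \linkS4class{RBPSampleSet} with train and eval
#'   samples.
#' @param sizes ascending per-class training sizes (use the full class size
#'   as the last entry for the "entire dataset" rung).
#' @param replicates trainings per (size, protocol) cell.
#' @param baseCheckpoint directory of the pretrained base model; supplies
#'   the architecture and vocabulary for the SCR models too.
#' @param maxEpochs,patience,batchSize training controls applied to both
#'   protocols.
#' @param seed master seed.
#' @return list with \code{results} (protein, protocol, size, replicate,
#'   auc) and \code{summary} (per size and protocol: mean and sd)
#' @export
runSubsampleExperiment <- function(manifest, sizes, replicates = 10L,
                                   baseCheckpoint, maxEpochs = 30L,
                                   patience = 5L, batchSize = 64L,
                                   seed = 1L) {
  if (replicates < 2L)
    warning("fewer than 2 replicates: standard deviations are undefined")
  base <- loadModel(baseCheckpoint)
  config <- base@config
  vocab <- base@vocab
  rungs <- nestedSubsample(manifest, sizes, seed = seed)
  ev <- evaluationSet(manifest)
  encE <- encodeSamples(ev, vocab, config)
  protein <- unique(sampleProteins(manifest))[1L]
  rows <- list()
  for (sz in names(rungs)) {
    tr_all <- trainingSet(rungs[[sz]])
    for (rep_i in seq_len(replicates)) {
      rs <- .child_seed(seed, paste0("rung", sz, "rep", rep_i))
      sp <- splitTrainVal(tr_all, c(9L, 1L), seed = rs)
      for (proto in c("SCR", "TL")) {
        spec <- if (proto == "TL")
          trainSpec("TL", initFrom = baseCheckpoint, maxEpochs = maxEpochs,
                    patience = patience, batchSize = batchSize, seed = rs)
        else
          trainSpec("SCR", maxEpochs = maxEpochs, patience = patience,
                    batchSize = batchSize, seed = rs)
        fit <- trainProtocol(sp$train, sp$validation, spec,
                             config = config, vocab = vocab)
        auc <- evaluateAUC(predict(fit$model, encE), encE$y)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = protein, protocol = proto, size = as.integer(sz),
          replicate = rep_i, auc = auc)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg_m <- stats::aggregate(auc ~ size + protocol, results, mean)
  agg_s <- stats::aggregate(auc ~ size + protocol, results, stats::sd)
  summary <- merge(agg_m, agg_s, by = c("size", "protocol"),
                   suffixes = c("_mean", "_sd"))
  summary <- summary[order(summary$size, summary$protocol), ]
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}

#' Write a results table as TSV
#'
#' @param results data.frame as produced by [runSubsampleExperiment()].
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writeResultsTable <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
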