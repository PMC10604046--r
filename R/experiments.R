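## Desk-scale benchmark experiments on the synthetic collections. These
## drive the package end to end: generation, preparation, baseline
## assembly, BS pretraining, TL/SCR comparison at limited sample sizes and
## attention-based motif recovery.

#' From-scratch training on a zero-noise synthetic collection
#'
#' Generates a single-protein collection with an exact (unmutated) planted
#' motif, 500 samples per class in the training split, prepares it at
#' 150 nt, and trains a from-scratch model with the smallest architecture
#' configuration. Establishes that the learning task is solvable: the
#' motif-scan oracle separates the classes, so a sound implementation must
#' reach a high validation AUC.
#'
#' @param seed master seed for generation and training.
#' @param maxEpochs,patience training budget.
#' @return list with \code{val_auc} (best validation AUC),
#'   \code{eval_auc}, \code{oracle_auc} (substring-scan AUC on the
#'   evaluation set), \code{history} and \code{n_train}
#' @export
runSolvabilityExperiment <- function(seed = 1L, maxEpochs = 8L,
                                     patience = 3L) {
  spec <- syntheticSpec(nProteins = 1, flankMotifs = "",
                        motifMutationRate = 0, nPos = 625,
                        dialect = "rbp24-style",
                        seed = .child_seed(seed, "solv"))
  coll <- generateCollection(spec)
  on.exit(unlink(coll$dir, recursive = TRUE), add = TRUE)
  ## motif-scan oracle on the generated (native-length) evaluation set
  nat_ev <- evaluationSet(coll$manifests[[1L]])
  oracle <- evaluateAUC(
    as.integer(grepl(spec@coreMotif, sampleSequences(nat_ev), fixed = TRUE)),
    sampleLabels(nat_ev))
  prep <- prepareSamples(coll$manifests[[1L]], coll$genome, coll$track,
                         L = 150L)
  tr <- trainingSet(prep)
  ev <- evaluationSet(prep)
  vocab <- trainBPE(sampleSequences(tr), 16L)
  sp <- splitTrainVal(tr, c(9L, 1L), seed = seed)
  fit <- trainProtocol(sp$train, sp$validation,
                       trainSpec("SCR", maxEpochs = maxEpochs,
                                 patience = patience, seed = seed),
                       config = modelConfig(), vocab = vocab)
  list(val_auc = max(fit$history$val_auc),
       eval_auc = evaluateAUC(predict(fit$model, ev), sampleLabels(ev)),
       oracle_auc = oracle,
       history = fit$history,
       n_train = length(tr))
}

#' Transfer-versus-scratch comparison on a synthetic transfer family
#'
#' Generates a transfer family (baseline proteins plus one held-out protein
#' sharing the core motif but carrying an unseen flank), pretrains a base
#' model on the purged merged baseline, then, for each replicate seed,
#' fine-tunes it (TL) and trains from scratch (SCR) on
#' \code{sizePerClass} held-out training samples per class, evaluating both
#' on the held-out protein's unchanged evaluation set. For every TL
#' replicate the attention interpretation pipeline (top predictions,
#' maximal 20-nt attention windows, 6-mer counts) is run and checked for
#' recovery of the planted core motif among the top 3 k-mers.
#'
#' @param seed master seed.
#' @param nSeeds replicate count.
#' @param sizePerClass held-out training samples per class.
#' @param bsEpochs,bsPatience base-model training budget.
#' @param ftEpochs,ftPatience per-protein training budget.
#' @return list with \code{comparison} (data.frame seed, scr_auc, tl_auc,
#'   recovered, rank), \code{tl_mean}, \code{scr_mean},
#'   \code{recovery_fraction}, \code{bs_val_auc}, \code{bs_heldout_auc}
#'   and \code{baseline_n}
#' @export
runTransferFamilyExperiment <- function(seed = 1L, nSeeds = 5L,
                                        sizePerClass = 100L,
                                        bsEpochs = 8L, bsPatience = 3L,
                                        ftEpochs = 12L, ftPatience = 4L) {
  spec <- syntheticSpec(nProteins = 4, nPos = 500,
                        dialect = "rbp24-style",
                        seed = .child_seed(seed, "family"))
  fam <- generateTransferFamily(spec)
  on.exit(unlink(fam$dir, recursive = TRUE), add = TRUE)
  track <- readConservationTrack(fam$track)
  base_prep <- lapply(fam$baseline, prepareSamples, genome = fam$genome,
                      track = track, L = 150L)
  held <- prepareSamples(fam$heldout, fam$genome, track, L = 150L)

  base_tr <- buildBaseline(base_prep, seed = seed)
  vocab <- trainBPE(sampleSequences(base_tr), 16L)
  cfg <- modelConfig()
  sp <- splitTrainVal(base_tr, c(9L, 1L), seed = seed)
  bs <- trainProtocol(sp$train, sp$validation,
                      trainSpec("BS", maxEpochs = bsEpochs,
                                patience = bsPatience, seed = seed),
                      config = cfg, vocab = vocab)
  ckpt <- file.path(tempfile("bs_ckpt"))
  saveModel(bs$model, ckpt)
  on.exit(unlink(ckpt, recursive = TRUE), add = TRUE)

  ev <- evaluationSet(held)
  bs_heldout <- evaluateAUC(predict(bs$model, ev), sampleLabels(ev))
  rung <- nestedSubsample(held, sizePerClass,
                          seed = .child_seed(seed, "rung"))[[1L]]
  tr_small <- trainingSet(rung)
  held_motif <- paste0(spec@coreMotif,
                       spec@flankMotifs[spec@nProteins])

  rows <- lapply(seq_len(nSeeds), function(i) {
    rs <- .child_seed(seed, paste0("replicate", i))
    sp2 <- splitTrainVal(tr_small, c(9L, 1L), seed = rs)
    scr <- trainProtocol(sp2$train, sp2$validation,
                         trainSpec("SCR", maxEpochs = ftEpochs,
                                   patience = ftPatience, seed = rs),
                         config = cfg, vocab = vocab)
    tl <- trainProtocol(sp2$train, sp2$validation,
                        trainSpec("TL", initFrom = ckpt,
                                  maxEpochs = ftEpochs,
                                  patience = ftPatience, seed = rs))
    regions <- extractAttentionRegions(tl$model, ev, n = 50L, width = 20L)
    rec <- motifRecoveryCheck(countKmers(regions, k = 6L), held_motif,
                              topM = 3L)
    data.frame(seed = rs,
               scr_auc = evaluateAUC(predict(scr$model, ev),
                                     sampleLabels(ev)),
               tl_auc = evaluateAUC(predict(tl$model, ev),
                                    sampleLabels(ev)),
               recovered = rec$recovered,
               rank = if (is.na(rec$rank)) NA_integer_ else rec$rank)
  })
  comparison <- do.call(rbind, rows)
  list(comparison = comparison,
       tl_mean = mean(comparison$tl_auc),
       scr_mean = mean(comparison$scr_auc),
       recovery_fraction = mean(comparison$recovered),
       bs_val_auc = max(bs$history$val_auc),
       bs_heldout_auc = bs_heldout,
       baseline_n = length(base_tr))
}
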