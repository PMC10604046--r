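## Three-branch classifier: sequence branch (token embedding -> 1D
## convolution -> BiGRU -> additive attention), secondary-structure and
## conservation branches (ResNet blocks with global average pooling),
## concatenation and a fully connected head with a sigmoid output.

## ---------------------------------------------------------------------------
## Parameter construction
## ---------------------------------------------------------------------------

.init_params <- function(config, vocab) {
  k <- nnConstants()
  p <- list()
  H <- config@bigruUnits
  Fc <- config@cnnFilters
  E <- config@embeddingDim
  if ("S" %in% config@branches) {
    V <- vocabSize(vocab)
    p$emb <- .glorot(V, E)
    p$conv_W <- .glorot(k$convKernel * E, Fc)
    p$conv_b <- numeric(Fc)
    for (d in c("gru_f", "gru_b")) {
      for (g in c("r", "z", "n")) {
        p[[paste0(d, "_Wx", g)]] <- .glorot(Fc, H)
        p[[paste0(d, "_Wh", g)]] <- .glorot(H, H)
        p[[paste0(d, "_b", g)]] <- numeric(H)
      }
    }
    A <- k$attentionDim
    p$att_W <- .glorot(2L * H, A)
    p$att_b <- numeric(A)
    p$att_v <- as.vector(.glorot(A, 1L))
  }
  for (br in intersect(c("SS", "EC"), config@branches)) {
    pr <- tolower(br)
    Cin <- if (br == "SS") 3L else 1L
    for (i in seq_len(config@resnetBlocks)) {
      ci <- if (i == 1L) Cin else Fc
      p[[paste0(pr, "_b", i, "_c1_W")]] <- .glorot(k$resKernel * ci, Fc)
      p[[paste0(pr, "_b", i, "_c1_b")]] <- numeric(Fc)
      p[[paste0(pr, "_b", i, "_g1")]] <- rep(1, Fc)
      p[[paste0(pr, "_b", i, "_be1")]] <- numeric(Fc)
      p[[paste0(pr, "_b", i, "_c2_W")]] <- .glorot(k$resKernel * Fc, Fc)
      p[[paste0(pr, "_b", i, "_c2_b")]] <- numeric(Fc)
      p[[paste0(pr, "_b", i, "_g2")]] <- rep(1, Fc)
      p[[paste0(pr, "_b", i, "_be2")]] <- numeric(Fc)
      if (ci != Fc)
        p[[paste0(pr, "_b", i, "_proj_W")]] <- .glorot(ci, Fc)
      p[[paste0("bn_run_", pr, "_b", i, "_m1")]] <- numeric(Fc)
      p[[paste0("bn_run_", pr, "_b", i, "_v1")]] <- rep(1, Fc)
      p[[paste0("bn_run_", pr, "_b", i, "_m2")]] <- numeric(Fc)
      p[[paste0("bn_run_", pr, "_b", i, "_v2")]] <- rep(1, Fc)
    }
  }
  din <- 0L
  if ("S" %in% config@branches) din <- din + 2L * H
  if ("SS" %in% config@branches) din <- din + Fc
  if ("EC" %in% config@branches) din <- din + Fc
  W <- k$headWidth
  for (i in seq_len(config@denseLayers)) {
    p[[paste0("head", i, "_W")]] <- .glorot(if (i == 1L) din else W, W)
    p[[paste0("head", i, "_b")]] <- numeric(W)
  }
  p$out_W <- .glorot(W, 1L)
  p$out_b <- 0
  p
}

#' Build a randomly initialised three-branch model
#'
#' Realises exactly the branches enabled in the configuration; disabled
#' branches contribute nothing to the concatenated representation.
#' Initialisation (Glorot uniform) is deterministic under \code{seed}.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param vocab a \linkS4class{BPEVocabulary}; required when the S branch is
#'   enabled and its \code{k} must equal the config's \code{tokenizerK}.
#' @param seed RNG seed for initialisation.
#' @return an \linkS4class{RBPModel}
#' @export
buildModel <- function(config, vocab = NULL, seed = 1L) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  if ("S" %in% config@branches) {
    if (is.null(vocab))
      stop("the S branch requires a vocabulary; none was supplied")
    if (vocab@k != config@tokenizerK)
      stop("vocabulary k (", vocab@k, ") does not match config tokenizerK (",
           config@tokenizerK, ")")
  } else if (is.null(vocab)) {
    vocab <- new("BPEVocabulary", tokens = .DNA_ALPHABET,
                 merges = matrix(character(0), ncol = 2L,
                                 dimnames = list(NULL, c("left", "right"))),
                 k = 4L, alphabet = .DNA_ALPHABET)
  }
  params <- .with_seed(seed, .init_params(config, vocab))
  new("RBPModel", config = config, params = params, vocab = vocab)
}

## ---------------------------------------------------------------------------
## Sample encoding
## ---------------------------------------------------------------------------

#' Encode samples into model-ready tensors
#'
#' Tokenizes sequences (S), one-hot encodes structure (SS) and lays out
#' conservation (EC) into the flat matrices the network consumes. All
#' sample widths must equal the configuration's interval length.
#'
#' @param x an \linkS4class{RBPSampleSet}.
#' @param vocab a \linkS4class{BPEVocabulary} (needed when S is enabled).
#' @param config a \linkS4class{ModelConfig}.
#' @return an opaque list of encoded inputs, labels and token spans
#' @export
encodeSamples <- function(x, vocab, config) {
  n <- config@intervalLength
  B <- length(x)
  if (B == 0L) stop("cannot encode an empty sample set")
  w <- GenomicRanges::width(sampleIntervals(x))
  if (!all(w == n))
    stop("sample width(s) ", paste(unique(w[w != n]), collapse = ","),
         " do not match the model interval length ", n,
         "; recenter the intervals first")
  enc <- list(B = B, n = n, y = as.numeric(sampleLabels(x)))
  if ("S" %in% config@branches) {
    toks <- bpeTokenize(vocab, sampleSequences(x))
    lens <- vapply(toks, function(t) length(t$ids), integer(1))
    Tmax <- max(lens)
    ids <- matrix(0L, B, Tmax)
    for (i in seq_len(B)) ids[i, seq_len(lens[i])] <- toks[[i]]$ids
    enc$ids <- ids
    enc$lens <- lens
    enc$spans <- lapply(toks, `[[`, "spans")
  }
  if ("SS" %in% config@branches) {
    st <- sampleStructures(x)
    if (anyNA(st))
      stop("SS branch enabled but ", sum(is.na(st)),
           " sample(s) have no structure string")
    jm <- matrix(match(unlist(strsplit(st, "", fixed = TRUE)), .DOTBRACKET),
                 nrow = n)
    if (anyNA(jm)) stop("structure strings contain non dot-bracket symbols")
    flatj <- as.vector(t(jm))
    M <- matrix(0, B * n, 3L)
    M[cbind(seq_len(B * n), flatj)] <- 1
    enc$ss <- M
  }
  if ("EC" %in% config@branches) {
    cons <- sampleConservation(x)
    if (any(lengths(cons) != n))
      stop("EC branch enabled but ", sum(lengths(cons) != n),
           " sample(s) have no conservation vector")
    cm <- matrix(unlist(cons), nrow = n)
    enc$ec <- matrix(as.vector(t(cm)), ncol = 1L)
  }
  enc
}

## Subset an encoded set by sample indices (keeps the flat layouts valid).
.slice_encoded <- function(enc, idx) {
  B2 <- length(idx)
  out <- list(B = B2, n = enc$n, y = enc$y[idx])
  if (!is.null(enc$ids)) {
    lens <- enc$lens[idx]
    Tmax <- max(lens)
    out$ids <- enc$ids[idx, seq_len(Tmax), drop = FALSE]
    out$lens <- lens
    out$spans <- enc$spans[idx]
  }
  if (!is.null(enc$ss) || !is.null(enc$ec)) {
    rows <- rep((seq_len(enc$n) - 1L) * enc$B, each = B2) + idx
    if (!is.null(enc$ss)) out$ss <- enc$ss[rows, , drop = FALSE]
    if (!is.null(enc$ec)) out$ec <- enc$ec[rows, , drop = FALSE]
  }
  out
}

## ---------------------------------------------------------------------------
## ResNet branch
## ---------------------------------------------------------------------------

.resnet_fwd <- function(p, pr, flat, B, n, blocks, training) {
  k <- nnConstants()
  caches <- vector("list", blocks)
  run_updates <- list()
  x <- flat
  for (i in seq_len(blocks)) {
    nm <- function(s) paste0(pr, "_b", i, "_", s)
    rn <- function(s) paste0("bn_run_", pr, "_b", i, "_", s)
    c1 <- .conv1d_fwd(x, B, n, p[[nm("c1_W")]], p[[nm("c1_b")]],
                      k$resKernel, act = FALSE)
    bn1 <- .bn_fwd(c1$out, p[[nm("g1")]], p[[nm("be1")]],
                   p[[rn("m1")]], p[[rn("v1")]], training,
                   k$bnEps, k$bnMomentum)
    r1 <- .relu_fwd(bn1$out)
    c2 <- .conv1d_fwd(r1, B, n, p[[nm("c2_W")]], p[[nm("c2_b")]],
                      k$resKernel, act = FALSE)
    bn2 <- .bn_fwd(c2$out, p[[nm("g2")]], p[[nm("be2")]],
                   p[[rn("m2")]], p[[rn("v2")]], training,
                   k$bnEps, k$bnMomentum)
    proj <- !is.null(p[[nm("proj_W")]])
    skip <- if (proj) x %*% p[[nm("proj_W")]] else x
    pre <- bn2$out + skip
    out <- .relu_fwd(pre)
    caches[[i]] <- list(x = x, c1 = c1, bn1 = bn1, r1pre = bn1$out,
                        c2 = c2, bn2 = bn2, pre = pre, proj = proj)
    if (training) {
      run_updates[[rn("m1")]] <- bn1$run_mean
      run_updates[[rn("v1")]] <- bn1$run_var
      run_updates[[rn("m2")]] <- bn2$run_mean
      run_updates[[rn("v2")]] <- bn2$run_var
    }
    x <- out
  }
  gap <- rowsum(x, group = rep.int(seq_len(B), n)) / n
  list(gap = gap, caches = caches, run_updates = run_updates, out_flat = x)
}

.resnet_bwd <- function(p, pr, dgap, fwd, B, n, blocks) {
  grads <- list()
  dx <- dgap[rep.int(seq_len(B), n), , drop = FALSE] / n
  for (i in rev(seq_len(blocks))) {
    nm <- function(s) paste0(pr, "_b", i, "_", s)
    cc <- fwd$caches[[i]]
    dpre <- dx
    dpre[cc$pre <= 0] <- 0
    dskip <- dpre
    db2 <- .bn_bwd(dpre, cc$bn2$cache, p[[nm("g2")]])
    grads[[nm("g2")]] <- db2$dgamma
    grads[[nm("be2")]] <- db2$dbeta
    dc2 <- .conv1d_bwd(db2$dx, cc$c2$cache, p[[nm("c2_W")]])
    grads[[nm("c2_W")]] <- dc2$dW
    grads[[nm("c2_b")]] <- dc2$db
    dr1 <- dc2$dx
    dr1[cc$r1pre <= 0] <- 0
    db1 <- .bn_bwd(dr1, cc$bn1$cache, p[[nm("g1")]])
    grads[[nm("g1")]] <- db1$dgamma
    grads[[nm("be1")]] <- db1$dbeta
    dc1 <- .conv1d_bwd(db1$dx, cc$c1$cache, p[[nm("c1_W")]])
    grads[[nm("c1_W")]] <- dc1$dW
    grads[[nm("c1_b")]] <- dc1$db
    dxin <- dc1$dx
    if (cc$proj) {
      grads[[nm("proj_W")]] <- crossprod(cc$x, dskip)
      dxin <- dxin + dskip %*% t(p[[nm("proj_W")]])
    } else {
      dxin <- dxin + dskip
    }
    dx <- dxin
  }
  list(dx = dx, grads = grads)
}

## ---------------------------------------------------------------------------
## Full forward / backward
## ---------------------------------------------------------------------------

## Reversal gather index: reversed position t of sample b reads original
## position len_b - t + 1; positions past len_b read the zero pad row.
.rev_index <- function(lens, B, T) {
  tvec <- rep(seq_len(T), each = B)
  bvec <- rep.int(seq_len(B), T)
  src <- lens[bvec] - tvec + 1L
  ifelse(src >= 1L, (src - 1L) * B + bvec, B * T + 1L)
}

.model_forward <- function(p, config, enc, training = FALSE) {
  k <- nnConstants()
  B <- enc$B
  cache <- list(B = B)
  feats <- NULL
  if ("S" %in% config@branches) {
    T <- ncol(enc$ids)
    idvec <- as.vector(enc$ids)
    embP <- rbind(0, p$emb)
    flatE <- embP[idvec + 1L, , drop = FALSE]
    conv <- .conv1d_fwd(flatE, B, T, p$conv_W, p$conv_b, k$convKernel)
    gf <- .gru_fwd(conv$out, B, T, p, "gru_f")
    ridx <- .rev_index(enc$lens, B, T)
    convP <- rbind(conv$out, 0)
    crev <- convP[ridx, , drop = FALSE]
    gb <- .gru_fwd(crev, B, T, p, "gru_b")
    hbP <- rbind(gb$hflat, 0)
    hb <- hbP[ridx, , drop = FALSE]
    hflat <- cbind(gf$hflat, hb)
    mask <- matrix(rep(seq_len(T), each = B) <= enc$lens[rep.int(seq_len(B), T)],
                   B, T)
    att <- .attention_fwd(hflat, B, T, p$att_W, p$att_b, p$att_v, mask)
    feats <- cbind(feats, att$ctx)
    cache$s <- list(T = T, idvec = idvec, conv = conv, gf = gf, gb = gb,
                    ridx = ridx, hflat = hflat, att = att, mask = mask)
  }
  for (br in intersect(c("SS", "EC"), config@branches)) {
    pr <- tolower(br)
    flat <- if (br == "SS") enc$ss else enc$ec
    rf <- .resnet_fwd(p, pr, flat, B, enc$n, config@resnetBlocks, training)
    feats <- cbind(feats, rf$gap)
    cache[[pr]] <- rf
  }
  z <- feats
  heads <- vector("list", config@denseLayers)
  for (i in seq_len(config@denseLayers)) {
    pre <- .addrow(z %*% p[[paste0("head", i, "_W")]],
                   p[[paste0("head", i, "_b")]])
    a <- .relu_fwd(pre)
    drop_mask <- NULL
    if (training && k$dropout > 0) {
      drop_mask <- (matrix(runif(length(a)), nrow(a)) >= k$dropout) /
        (1 - k$dropout)
      a <- a * drop_mask
    }
    heads[[i]] <- list(zin = z, pre = pre, drop = drop_mask)
    z <- a
  }
  logit <- as.vector(z %*% p$out_W) + p$out_b
  prob <- .sigmoid(logit)
  cache$heads <- heads
  cache$zlast <- z
  cache$feats <- feats
  list(prob = prob, logit = logit, cache = cache,
       alpha = if ("S" %in% config@branches) cache$s$att$alpha else NULL)
}

.model_backward <- function(p, config, enc, fw, dlogit) {
  cache <- fw$cache
  B <- cache$B
  grads <- list()
  dz <- outer(dlogit, as.vector(p$out_W))
  grads$out_W <- crossprod(cache$zlast, matrix(dlogit, ncol = 1L))
  grads$out_b <- sum(dlogit)
  for (i in rev(seq_len(config@denseLayers))) {
    hd <- cache$heads[[i]]
    if (!is.null(hd$drop)) dz <- dz * hd$drop
    dz[hd$pre <= 0] <- 0
    grads[[paste0("head", i, "_W")]] <- crossprod(hd$zin, dz)
    grads[[paste0("head", i, "_b")]] <- colSums(dz)
    dz <- dz %*% t(p[[paste0("head", i, "_W")]])
  }
  ## dz is now the gradient on the concatenated features
  off <- 0L
  if ("S" %in% config@branches) {
    H2 <- 2L * config@bigruUnits
    dctx <- dz[, (off + 1L):(off + H2), drop = FALSE]
    off <- off + H2
    sc <- cache$s
    T <- sc$T
    ab <- .attention_bwd(dctx, sc$att$cache, B, T, p$att_W, p$att_v)
    grads$att_W <- ab$dW
    grads$att_b <- ab$db
    grads$att_v <- ab$dv
    H <- config@bigruUnits
    dhf <- ab$dh[, seq_len(H), drop = FALSE]
    dhb <- ab$dh[, H + seq_len(H), drop = FALSE]
    gfb <- .gru_bwd(dhf, sc$gf, p, "gru_f", B, T)
    grads <- c(grads, gfb$grads)
    ## gradient on the un-reversed backward states -> scatter to reversed
    n_rows <- B * T
    dhbrev <- matrix(0, n_rows, H)
    v <- sc$ridx <= n_rows
    dhbrev[sc$ridx[v], ] <- dhb[v, , drop = FALSE]
    gbb <- .gru_bwd(dhbrev, sc$gb, p, "gru_b", B, T)
    grads <- c(grads, gbb$grads)
    dconv <- gfb$dx
    dcrev <- gbb$dx
    dconv[sc$ridx[v], ] <- dconv[sc$ridx[v], , drop = FALSE] +
      dcrev[v, , drop = FALSE]
    cb <- .conv1d_bwd(dconv, sc$conv$cache, p$conv_W)
    grads$conv_W <- cb$dW
    grads$conv_b <- cb$db
    demb <- matrix(0, nrow(p$emb), ncol(p$emb))
    keep <- sc$idvec > 0L
    acc <- rowsum(cb$dx[keep, , drop = FALSE], group = sc$idvec[keep])
    demb[as.integer(rownames(acc)), ] <- acc
    grads$emb <- demb
  }
  for (br in intersect(c("SS", "EC"), config@branches)) {
    pr <- tolower(br)
    Fc <- config@cnnFilters
    dgap <- dz[, (off + 1L):(off + Fc), drop = FALSE]
    off <- off + Fc
    rb <- .resnet_bwd(p, pr, dgap, cache[[pr]], B, enc$n,
                      config@resnetBlocks)
    grads <- c(grads, rb$grads)
  }
  grads
}

## Collect batch-norm running-statistic updates from a training forward.
.collect_run_updates <- function(fw, config) {
  ups <- list()
  for (br in intersect(c("SS", "EC"), config@branches)) {
    pr <- tolower(br)
    ups <- c(ups, fw$cache[[pr]]$run_updates)
  }
  ups
}

## ---------------------------------------------------------------------------
## Prediction and attention export
## ---------------------------------------------------------------------------

#' Predict binding probabilities
#'
#' Inference-mode forward pass (no dropout, batch-norm running statistics):
#' deterministic for fixed parameters and inputs, and identical between
#' batched and single-sample calls.
#'
#' @param object an \linkS4class{RBPModel}.
#' @param samples an \linkS4class{RBPSampleSet} or the result of
#'   [encodeSamples()].
#' @param batchSize samples per forward chunk.
#' @param ... unused.
#' @return numeric vector of probabilities in [0, 1]
#' @export
setMethod("predict", "RBPModel",
          function(object, samples, batchSize = 512L, ...) {
  enc <- if (is(samples, "RBPSampleSet"))
    encodeSamples(samples, object@vocab, object@config) else samples
  out <- numeric(enc$B)
  starts <- seq(1L, enc$B, by = batchSize)
  for (s in starts) {
    idx <- s:min(s + batchSize - 1L, enc$B)
    fw <- .model_forward(object@params, object@config,
                         .slice_encoded(enc, idx), training = FALSE)
    out[idx] <- fw$prob
  }
  out
})

#' Per-nucleotide attention profiles
#'
#' Runs the sequence branch in inference mode and maps the token-level
#' attention distribution onto nucleotides: each base inherits its covering
#' token's weight divided by the token length, then the profile is
#' renormalised to sum to one. Requires the S branch.
#'
#' @param model an \linkS4class{RBPModel} with the S branch enabled.
#' @param samples an \linkS4class{RBPSampleSet}.
#' @param batchSize samples per forward chunk.
#' @return list of numeric vectors (one per sample, length = interval
#'   length, nonnegative, summing to 1)
#' @export
attentionProfiles <- function(model, samples, batchSize = 512L) {
  stopifnot(is(model, "RBPModel"))
  if (!"S" %in% model@config@branches)
    stop("attention profiles require the S branch, which this model lacks")
  enc <- encodeSamples(samples, model@vocab, model@config)
  n <- enc$n
  out <- vector("list", enc$B)
  starts <- seq(1L, enc$B, by = batchSize)
  for (s in starts) {
    idx <- s:min(s + batchSize - 1L, enc$B)
    sl <- .slice_encoded(enc, idx)
    fw <- .model_forward(model@params, model@config, sl, training = FALSE)
    for (j in seq_along(idx)) {
      spans <- sl$spans[[j]]
      a <- fw$alpha[j, seq_len(sl$lens[j])]
      prof <- numeric(n)
      lenw <- spans[, "end"] - spans[, "start"]
      per_base <- rep.int(a / lenw, lenw)
      pos <- sequence(lenw, from = spans[, "start"] + 1L)
      prof[pos] <- per_base
      ssum <- sum(prof)
      if (ssum > 0) prof <- prof / ssum
      out[[idx[j]]] <- prof
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Checkpoints
## ---------------------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding \code{config.json},
#' \code{vocabulary.json}, a versioned \code{checkpoint.json} marker and the
#' parameter archive \code{params.rds}. Loading reproduces predictions
#' bit-for-bit in inference mode.
#'
#' @param model an \linkS4class{RBPModel}.
#' @param dir checkpoint directory (created).
#' @return \code{saveModel}: \code{dir}, invisibly; \code{loadModel}: an
#'   \linkS4class{RBPModel}.
#' @export
saveModel <- function(model, dir) {
  stopifnot(is(model, "RBPModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model@config
  jsonlite::write_json(
    list(bigruUnits = cfg@bigruUnits, embeddingDim = cfg@embeddingDim,
         tokenizerK = cfg@tokenizerK, cnnFilters = cfg@cnnFilters,
         resnetBlocks = cfg@resnetBlocks, denseLayers = cfg@denseLayers,
         branches = as.list(cfg@branches),
         intervalLength = cfg@intervalLength,
         outOfSpace = cfg@outOfSpace),
    file.path(dir, "config.json"), auto_unbox = TRUE)
  saveVocabulary(model@vocab, file.path(dir, "vocabulary.json"))
  jsonlite::write_json(list(format = "rbptl-checkpoint", version = 1L),
                       file.path(dir, "checkpoint.json"), auto_unbox = TRUE)
  saveRDS(model@params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  cfg_file <- file.path(dir, "config.json")
  if (!file.exists(cfg_file)) stop("not a checkpoint directory: ", dir)
  cj <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
  config <- modelConfig(bigruUnits = cj$bigruUnits,
                        embeddingDim = cj$embeddingDim,
                        tokenizerK = cj$tokenizerK,
                        cnnFilters = cj$cnnFilters,
                        resnetBlocks = cj$resnetBlocks,
                        denseLayers = cj$denseLayers,
                        branches = cj$branches,
                        intervalLength = cj$intervalLength,
                        outOfSpace = isTRUE(cj$outOfSpace))
  vocab <- loadVocabulary(file.path(dir, "vocabulary.json"))
  params <- readRDS(file.path(dir, "params.rds"))
  new("RBPModel", config = config, params = params, vocab = vocab)
}
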