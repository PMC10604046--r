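## Primitive neural-network layers with hand-derived backward passes.
##
## All sequence-shaped activations are stored "flat": a (B*T) x C matrix
## whose row (t-1)*B + b holds sample b at position t (first dimension
## varies fastest, matching R's column-major array flattening; Armadillo is
## column-major too, so matrices cross into the compiled kernels in
## src/kernels.cpp without reshaping). The time-stepped inner loops (GRU,
## convolution im2col, batch norm, attention) live in those kernels; this
## file holds their calling conventions and the optimiser.

#' Fixed architecture constants of the classifier
#'
#' These are the constants that are not part of the staged search space:
#' sequence-branch convolution kernel 5 (stride 1, same padding, ReLU),
#' ResNet convolution kernel 3, additive-attention width 64, head width 128
#' with dropout 0.2, batch-normalisation epsilon 1e-5 and running-average
#' momentum 0.9.
#'
#' @return named list of constants
#' @export
nnConstants <- function() {
  list(convKernel = 5L, resKernel = 3L, attentionDim = 64L,
       headWidth = 128L, dropout = 0.2, bnEps = 1e-5, bnMomentum = 0.9)
}

## Glorot-uniform initialiser
.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

.relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

## Fast row-broadcast (sweep() is too slow for the inner loop):
## add a length-ncol vector across all rows.
.addrow <- function(x, v) x + rep(v, each = nrow(x))

## ---------------------------------------------------------------------------
## 1D convolution on flat (B*T) x C activations, stride 1, same padding
## ---------------------------------------------------------------------------

.conv1d_fwd <- function(flat, B, T, W, b, kernel, act = TRUE) {
  r <- .cpp_conv1d_fwd(flat, B, T, W, b, kernel, act)
  list(out = r$out, cache = list(xcol = r$xcol, pre = r$pre, B = B, T = T,
                                 kernel = kernel, act = act))
}

.conv1d_bwd <- function(dout, cache, W) {
  .cpp_conv1d_bwd(dout, cache$xcol, cache$pre, cache$B, cache$T, W,
                  cache$kernel, cache$act)
}

## ---------------------------------------------------------------------------
## Batch normalisation over rows, per column (channel)
## ---------------------------------------------------------------------------

.bn_fwd <- function(x, gamma, beta, run_mean, run_var, training, eps, mom) {
  r <- .cpp_bn_fwd(x, gamma, beta, run_mean, run_var, training, eps, mom)
  list(out = r$out,
       cache = list(xhat = r$xhat, istd = r$istd, training = training),
       run_mean = as.vector(r$run_mean), run_var = as.vector(r$run_var))
}

.bn_bwd <- function(dy, cache, gamma) {
  r <- .cpp_bn_bwd(dy, cache$xhat, cache$istd, gamma, cache$training)
  list(dx = r$dx, dgamma = as.vector(r$dgamma), dbeta = as.vector(r$dbeta))
}

## ---------------------------------------------------------------------------
## GRU (single direction); inputs as a flat (B*T) x F matrix
## ---------------------------------------------------------------------------

## h_t = (1 - z_t) * g_t + z_t * h_{t-1}
## r, z: sigmoid gates; g: tanh candidate on (r * h_{t-1})
.gru_fwd <- function(flat, B, T, p, prefix) {
  g <- function(s) p[[paste0(prefix, "_", s)]]
  r <- .cpp_gru_fwd(flat, B, T, g("Wxr"), g("Whr"), g("br"),
                    g("Wxz"), g("Whz"), g("bz"),
                    g("Wxn"), g("Whn"), g("bn"))
  list(hflat = r$hflat, flat = flat,
       R = r$R, Z = r$Z, G = r$G, Q = r$Q, H = ncol(g("Whr")))
}

## dhflat: direct gradient on every h_t (flat layout). Returns dx (flat)
## and parameter gradients.
.gru_bwd <- function(dhflat, fwd, p, prefix, B, T) {
  g <- function(s) p[[paste0(prefix, "_", s)]]
  r <- .cpp_gru_bwd(dhflat, fwd$flat, fwd$hflat, fwd$R, fwd$Z, fwd$G,
                    fwd$Q, B, T, g("Wxr"), g("Whr"), g("Wxz"), g("Whz"),
                    g("Wxn"), g("Whn"))
  gr <- r[c("Wxr", "Whr", "br", "Wxz", "Whz", "bz", "Wxn", "Whn", "bn")]
  gr[c("br", "bz", "bn")] <- lapply(gr[c("br", "bz", "bn")], as.vector)
  names(gr) <- paste0(prefix, "_", names(gr))
  list(dx = r$dx, grads = gr)
}

## ---------------------------------------------------------------------------
## Additive attention over flat (B*T) x D states with a validity mask
## ---------------------------------------------------------------------------

## e_t = v' tanh(W h_t + b); alpha = masked softmax; context = sum alpha_t h_t
.attention_fwd <- function(hflat, B, T, W, b, v, mask) {
  m <- mask
  storage.mode(m) <- "integer"
  r <- .cpp_att_fwd(hflat, B, T, W, b, v, m)
  list(ctx = r$ctx, alpha = r$alpha,
       cache = list(U = r$U, alpha = r$alpha, hflat = hflat))
}

.attention_bwd <- function(dctx, cache, B, T, W, v) {
  r <- .cpp_att_bwd(dctx, cache$hflat, cache$U, cache$alpha, B, T, W, v)
  list(dh = r$dh, dW = r$dW, db = as.vector(r$db), dv = as.vector(r$dv))
}

## ---------------------------------------------------------------------------
## Adam optimiser over a named parameter list
## ---------------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       skip = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (length(skip) && any(startsWith(nm, skip))) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
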