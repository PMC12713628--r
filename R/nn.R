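## Minimal dense-network machinery used by both VAEs: seeded initialization,
## activations, and Adam. Parameters are named lists of matrices/vectors;
## gradients are computed analytically in the model-specific training code.

.relu <- function(x) pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

## Xavier/Glorot uniform initialization (seed handled by caller)
.initW <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

## In-place Adam: the C++ kernel mutates the parameter and moment buffers
## directly, so the optimizer owns them exclusively -- anything kept across
## steps (e.g. a best-validation checkpoint) must be a .deepCopy().
.adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads))
    .adam_update_cpp(params[[nm]], state$m[[nm]], state$v[[nm]],
                     grads[[nm]], lr, beta1, beta2, eps, state$t)
  list(params = params, state = state)
}

.deepCopy <- function(params) lapply(params, function(p) p + 0)

## add a bias row-vector to every row of a matrix product
.affine <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

## stratified validation split: per class, round(frac * n) indices (>= 1
## when the class has at least 2 members), drawn with the current RNG
.stratifiedVal <- function(classes, frac) {
  val <- integer(0)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    nv <- if (length(idx) >= 2L) max(1L, round(frac * length(idx))) else 0L
    if (nv > 0L) val <- c(val, sample(idx, nv))
  }
  sort(val)
}
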