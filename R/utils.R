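# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Derive a reproducible per-stage seed from a single global seed.
# Counter-based so toggling one stage does not shift the streams of the rest.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) + 104729 * as.numeric(stage)) %% 2147483647)
}

# Numerically stable softplus; strictly positive, monotone.
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

relu <- function(x) {
  x * (x > 0)
}

# Adam optimiser state for a list of parameter matrices.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Full pairwise Euclidean distance matrix (rows of Z).
pairwise_dist <- function(Z) {
  as.matrix(stats::dist(Z))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
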