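# Small numerical helpers shared across the package.

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-item substream seed from a master seed
#'
#' Deterministic counter-based derivation so that item \code{k} always sees
#' the same random stream regardless of generation order.
#'
#' @param master integer master seed.
#' @param k non-negative integer counter.
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @keywords internal
derive_seed <- function(master, k) {
  m <- 2147483647
  s <- (as.double(master) %% m)
  ((s * 48271) %% m + (as.double(k) * 104729) %% m) %% m
}

stopifnot_finite <- function(x, what = "values") {
  if (!all(is.finite(x))) stop("non-finite ", what, " encountered", call. = FALSE)
  invisible(x)
}

## ---- Adam optimizer over a named list of arrays ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## time stamps for one stroke window: T samples at sample_rate_hz starting at 0
stroke_times <- function(duration_s, sample_rate_hz) {
  n <- round(duration_s * sample_rate_hz)
  (seq_len(n) - 1) / sample_rate_hz
}
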