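# Magnitude pruning with mask-frozen retraining.
#
# Pruning starts from a trained model, removes the smallest-|weight|
# connections across ALL weight matrices (one global threshold; biases are
# exempt), then retrains with the removed connections frozen at zero so
# they are never recreated.

#' Compute a global magnitude-pruning mask
#'
#' Ranks every entry of every weight matrix (LSTM cells and readout;
#' biases exempt) by absolute value and zeroes out exactly
#' \code{floor(sparsity * n_weights)} of the smallest, ties broken by
#' array order.
#'
#' @param model a trained \code{\link{lstm_classifier}} (or list with
#'   \code{params}).
#' @param sparsity fraction of weights to remove, in [0, 1).
#' @return An object of class \code{prune_mask}: a named list of 0/1
#'   matrices matching the model's weight matrices, with attributes
#'   \code{sparsity} (target) and \code{n_zero}.
#' @export
compute_mask <- function(model, sparsity) {
  if (sparsity < 0 || sparsity >= 1)
    stop("sparsity must be in [0, 1)", call. = FALSE)
  params <- model$params
  wn <- weight_names(params)
  sizes <- vapply(wn, function(nm) length(params[[nm]]), 0L)
  allw <- unlist(lapply(wn, function(nm) as.vector(params[[nm]])))
  n <- length(allw)
  k <- floor(sparsity * n)
  keep <- rep(1, n)
  if (k > 0) keep[order(abs(allw))[seq_len(k)]] <- 0
  mask <- list()
  off <- 0L
  for (i in seq_along(wn)) {
    m <- keep[off + seq_len(sizes[i])]
    dim(m) <- dim(params[[wn[i]]])
    mask[[wn[i]]] <- m
    off <- off + sizes[i]
  }
  structure(mask, class = "prune_mask", sparsity = sparsity, n_zero = k,
            n_weights = n)
}

#' Apply a pruning mask to a parameter list
#'
#' Masked weight entries become exactly zero; biases and parameters not in
#' the mask are untouched.
#'
#' @param params named parameter list.
#' @param mask a \code{\link{compute_mask}} result.
#' @return Masked parameter list.
#' @export
apply_mask <- function(params, mask) {
  for (nm in names(mask)) params[[nm]] <- params[[nm]] * mask[[nm]]
  params
}

#' @export
print.prune_mask <- function(x, ...) {
  cat("<prune_mask> target sparsity ", format(attr(x, "sparsity")), ": ",
      attr(x, "n_zero"), " of ", attr(x, "n_weights"),
      " weights removed\n", sep = "")
  invisible(x)
}

#' Retrain a pruned classifier with frozen masks
#'
#' Continues training from the masked parameters; after every optimizer
#' step the masked entries are reset to exactly zero, so removed
#' connections are never recreated.
#'
#' @param model a trained \code{\link{lstm_classifier}}.
#' @param mask a \code{\link{compute_mask}} result for this model.
#' @param data the \code{\link{stroke_dataset}} to retrain on.
#' @param epochs,learning_rate,batch_size,l2,seed training controls;
#'   defaults reuse the original fit's configuration.
#' @return A retrained \code{lstm_classifier} carrying the mask.
#' @export
retrain_pruned <- function(model, mask, data,
                           epochs = model$config$epochs,
                           learning_rate = model$config$learning_rate,
                           batch_size = model$config$batch_size,
                           l2 = model$config$l2,
                           seed = model$config$seed) {
  if (!all(names(mask) %in% names(model$params)))
    stop("mask does not match the model's parameters", call. = FALSE)
  lstm_classifier(data, direction = model$arch$direction,
                  hidden = model$arch$hidden, epochs = epochs,
                  batch_size = batch_size, learning_rate = learning_rate,
                  l2 = l2, seed = seed,
                  pooling = model$arch$pooling %||% "final",
                  init_params = apply_mask(model$params, mask), mask = mask)
}

#' Parameter count remaining after pruning
#'
#' Bookkeeping on printed initial parameter counts: remaining =
#' round(initial * (1 - sparsity)), reported in units of 10^3 rounded to
#' two decimals (e.g. 9260 weights at 30\% sparsity -> 6482 -> "6.48").
#'
#' @param initial_count positive integer initial parameter count.
#' @param sparsity fraction removed, in [0, 1].
#' @return list with \code{remaining} (integer) and \code{report}
#'   (remaining / 1000 rounded to 2 decimals).
#' @export
remaining_after_prune <- function(initial_count, sparsity) {
  stopifnot(initial_count > 0, sparsity >= 0, sparsity <= 1)
  remaining <- round(initial_count * (1 - sparsity))
  list(remaining = remaining, report = round(remaining / 1000, 2))
}

#' Sparsity actually achieved by a mask or model
#'
#' @param mask a \code{prune_mask}, or an \code{lstm_classifier} whose
#'   weight matrices are inspected for exact zeros.
#' @return fraction of weight entries that are zero.
#' @export
achieved_sparsity <- function(mask) {
  if (inherits(mask, "prune_mask"))
    return(attr(mask, "n_zero") / attr(mask, "n_weights"))
  params <- mask$params
  wn <- weight_names(params)
  tot <- sum(vapply(wn, function(nm) length(params[[nm]]), 0L))
  zer <- sum(vapply(wn, function(nm) sum(params[[nm]] == 0), 0L))
  zer / tot
}
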