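# Stacked uni/bidirectional LSTM sequence classifiers.
#
# The cell follows the standard gate equations: at time t, with input x_t,
# previous hidden state h_{t-1} and previous internal state c_{t-1},
#   f_t = sigma(W_xf x_t + W_hf h_{t-1} + b_f)      (forget gate)
#   i_t = sigma(W_xi x_t + W_hi h_{t-1} + b_i)      (input gate)
#   o_t = sigma(W_xo x_t + W_ho h_{t-1} + b_o)      (output gate)
#   g_t = tanh (W_xg x_t + W_hg h_{t-1} + b_g)      (input modulation)
#   c_t = f_t * c_{t-1} + g_t * i_t
#   h_t = o_t * tanh(c_t)
# Two cells are stacked (level 2 consumes level 1's hidden states); the
# bidirectional variant runs a second pair of cells over the time-reversed
# sequence and concatenates forward and backward features. Classification
# reads out softmax(W_out [final features] + b_out) over the 10 joint
# (subject x skill) classes.
#
# Everything is batched base-R matrix code; gradients are exact
# backpropagation through time (verified against finite differences in the
# test suite).

GATES <- c("f", "i", "o", "g")

arch_spec <- function(direction = c("bi", "uni"), hidden = 38, input = 18,
                      n_classes = 10, levels = 2,
                      pooling = c("final", "mean")) {
  direction <- match.arg(direction)
  pooling <- match.arg(pooling)
  stopifnot(hidden >= 1, input >= 1, n_classes >= 2, levels == 2)
  list(direction = direction, hidden = hidden, input = input,
       n_classes = n_classes, levels = levels, pooling = pooling,
       feature = if (direction == "bi") 2L * hidden else hidden)
}

cell_names <- function(arch) {
  dirs <- if (arch$direction == "bi") c("f", "b") else "f"
  unlist(lapply(1:2, function(l) paste0("l", l, ".", dirs)))
}

cell_input_dim <- function(arch, level) {
  if (level == 1) arch$input
  else if (arch$direction == "bi") 2L * arch$hidden else arch$hidden
}

#' Pack per-gate LSTM weight matrices into a cell parameter block
#'
#' @param W_x named list with elements f, i, o, g: hidden x input matrices.
#' @param W_h named list with elements f, i, o, g: hidden x hidden matrices.
#' @param b named list with elements f, i, o, g: length-hidden biases.
#' @return list with a combined (input+hidden) x (4*hidden) weight matrix
#'   \code{W} (gate blocks in f, i, o, g order) and bias vector \code{b}.
#' @export
lstm_cell_params <- function(W_x, W_h, b) {
  stopifnot(all(GATES %in% names(W_x)), all(GATES %in% names(W_h)),
            all(GATES %in% names(b)))
  W <- do.call(cbind, lapply(GATES, function(k) rbind(t(W_x[[k]]), t(W_h[[k]]))))
  list(W = W, b = unlist(b[GATES], use.names = FALSE))
}

#' One LSTM cell step
#'
#' Applies the gate equations to a single time step. Inputs may be vectors
#' (one sequence) or matrices with one row per sequence in a batch.
#'
#' @param cell list with combined weights \code{W} ((input+hidden) x
#'   4*hidden, gate order f,i,o,g) and bias \code{b}; see
#'   \code{\link{lstm_cell_params}}.
#' @param x input at time t (length input, or N x input matrix).
#' @param state list with \code{h} and \code{c}, shapes matching \code{x}'s
#'   batch; defaults to zeros.
#' @return list with \code{h}, \code{c} and the gate activations
#'   \code{f}, \code{i}, \code{o}, \code{g}.
#' @export
lstm_cell_step <- function(cell, x, state = NULL) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  h4 <- ncol(cell$W)
  h <- h4 %/% 4L
  if (ncol(x) + h != nrow(cell$W))
    stop("shape mismatch: input has ", ncol(x), " columns but the cell expects ",
         nrow(cell$W) - h, call. = FALSE)
  if (is.null(state)) state <- list(h = matrix(0, nrow(x), h),
                                    c = matrix(0, nrow(x), h))
  hp <- if (is.matrix(state$h)) state$h else matrix(state$h, nrow = 1)
  cp <- if (is.matrix(state$c)) state$c else matrix(state$c, nrow = 1)
  z <- cbind(x, hp) %*% cell$W + matrix(cell$b, nrow(x), h4, byrow = TRUE)
  f <- sigmoid(z[, 1:h, drop = FALSE])
  i <- sigmoid(z[, h + 1:h, drop = FALSE])
  o <- sigmoid(z[, 2 * h + 1:h, drop = FALSE])
  g <- tanh(z[, 3 * h + 1:h, drop = FALSE])
  cc <- f * cp + g * i
  hh <- o * tanh(cc)
  list(h = hh, c = cc, f = f, i = i, o = o, g = g)
}

init_classifier_params <- function(arch, seed = 1L) {
  set.seed(as.integer(seed))
  h <- arch$hidden
  params <- list()
  for (cn in cell_names(arch)) {
    lvl <- as.integer(substr(cn, 2, 2))
    ind <- cell_input_dim(arch, lvl)
    s <- 1 / sqrt(ind + h)
    params[[paste0(cn, ".W")]] <- matrix(stats::runif((ind + h) * 4 * h, -s, s),
                                         ind + h, 4 * h)
    b <- numeric(4 * h)
    b[1:h] <- 1  # forget-gate bias starts open so memory persists early on
    params[[paste0(cn, ".b")]] <- b
  }
  s <- 1 / sqrt(arch$feature)
  params[["out.W"]] <- matrix(stats::runif(arch$feature * arch$n_classes, -s, s),
                              arch$feature, arch$n_classes)
  params[["out.b"]] <- numeric(arch$n_classes)
  params
}

weight_names <- function(params) grep("\\.W$", names(params), value = TRUE)

## ---- batched forward/backward over a sequence ----

# X: N x T x in array. Returns H (N x T x h) plus caches for BPTT.
# The per-time-step recursion runs in compiled code (src/lstm_kernels.cpp).
cell_forward_seq <- function(cell, X, reverse = FALSE, keep_cache = TRUE) {
  out <- .cell_forward_cpp(cell$W, cell$b, X, reverse, keep_cache)
  cache <- if (keep_cache) out[c("F", "I", "O", "G", "C", "TanC")]
  list(H = out$H, cache = cache, reverse = reverse, X = if (keep_cache) X)
}

# dH_ext: N x T x h external gradient on the hidden states.
# Returns dX (N x T x in), dW, db. Compiled BPTT loop.
cell_backward_seq <- function(cell, fwd, dH_ext) {
  .cell_backward_cpp(cell$W, fwd$X, fwd$H, fwd$cache$F, fwd$cache$I,
                     fwd$cache$O, fwd$cache$G, fwd$cache$C, fwd$cache$TanC,
                     dH_ext, fwd$reverse)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full stack forward. X: N x T x input (already scaled).
# Returns probs, logits, feat, H2 (level-2 hidden sequence, N x T x feature)
# and, when keep_cache, everything needed for the backward pass.
stack_forward <- function(params, arch, X, keep_cache = FALSE) {
  N <- dim(X)[1]; Tn <- dim(X)[2]
  h <- arch$hidden
  bi <- arch$direction == "bi"
  f1 <- cell_forward_seq(list(W = params[["l1.f.W"]], b = params[["l1.f.b"]]),
                         X, FALSE, keep_cache)
  if (bi) {
    b1 <- cell_forward_seq(list(W = params[["l1.b.W"]], b = params[["l1.b.b"]]),
                           X, TRUE, keep_cache)
    H1 <- array(0, c(N, Tn, 2 * h))
    H1[, , 1:h] <- f1$H; H1[, , h + 1:h] <- b1$H
  } else H1 <- f1$H
  f2 <- cell_forward_seq(list(W = params[["l2.f.W"]], b = params[["l2.f.b"]]),
                         H1, FALSE, keep_cache)
  pool <- function(H) {
    if ((arch$pooling %||% "final") == "mean")
      matrix(colMeans(aperm(H, c(2, 1, 3))), N)
    else NULL
  }
  if (bi) {
    b2 <- cell_forward_seq(list(W = params[["l2.b.W"]], b = params[["l2.b.b"]]),
                           H1, TRUE, keep_cache)
    H2 <- array(0, c(N, Tn, 2 * h))
    H2[, , 1:h] <- f2$H; H2[, , h + 1:h] <- b2$H
    feat <- if ((arch$pooling %||% "final") == "mean")
      cbind(pool(f2$H), pool(b2$H))
    else cbind(matrix(f2$H[, Tn, ], N), matrix(b2$H[, 1, ], N))
  } else {
    H2 <- f2$H
    feat <- if ((arch$pooling %||% "final") == "mean") pool(f2$H)
    else matrix(f2$H[, Tn, ], N)
  }
  logits <- feat %*% params[["out.W"]] +
    matrix(params[["out.b"]], N, arch$n_classes, byrow = TRUE)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits, feat = feat, H2 = H2)
  if (keep_cache) out <- c(out, list(f1 = f1, b1 = if (bi) b1, f2 = f2,
                                     b2 = if (bi) b2, H1 = H1))
  out
}

# Gradient of mean cross-entropy + l2 * sum(W^2) w.r.t. all parameters.
stack_backward <- function(params, arch, fwd, Y, l2 = 0) {
  N <- nrow(Y); Tn <- dim(fwd$H2)[2]; h <- arch$hidden
  bi <- arch$direction == "bi"
  dlogits <- (fwd$probs - Y) / N
  grads <- list()
  grads[["out.W"]] <- crossprod(fwd$feat, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  dfeat <- dlogits %*% t(params[["out.W"]])
  mean_pool <- (arch$pooling %||% "final") == "mean"
  dH2f <- array(0, c(N, Tn, h))
  if (mean_pool) {
    for (t in seq_len(Tn)) dH2f[, t, ] <- dfeat[, 1:h, drop = FALSE] / Tn
  } else dH2f[, Tn, ] <- dfeat[, 1:h, drop = FALSE]
  bk2 <- NULL
  if (bi) {
    dH2b <- array(0, c(N, Tn, h))
    if (mean_pool) {
      for (t in seq_len(Tn)) dH2b[, t, ] <- dfeat[, h + 1:h, drop = FALSE] / Tn
    } else dH2b[, 1, ] <- dfeat[, h + 1:h, drop = FALSE]
    bk2 <- cell_backward_seq(list(W = params[["l2.b.W"]], b = params[["l2.b.b"]]),
                             fwd$b2, dH2b)
    grads[["l2.b.W"]] <- bk2$dW; grads[["l2.b.b"]] <- bk2$db
  }
  fk2 <- cell_backward_seq(list(W = params[["l2.f.W"]], b = params[["l2.f.b"]]),
                           fwd$f2, dH2f)
  grads[["l2.f.W"]] <- fk2$dW; grads[["l2.f.b"]] <- fk2$db
  dH1 <- fk2$dX
  if (!is.null(bk2)) dH1 <- dH1 + bk2$dX
  if (bi) {
    dH1f <- dH1[, , 1:h, drop = FALSE]
    dH1b <- dH1[, , h + 1:h, drop = FALSE]
    bk1 <- cell_backward_seq(list(W = params[["l1.b.W"]], b = params[["l1.b.b"]]),
                             fwd$b1, dH1b)
    grads[["l1.b.W"]] <- bk1$dW; grads[["l1.b.b"]] <- bk1$db
  } else dH1f <- dH1
  fk1 <- cell_backward_seq(list(W = params[["l1.f.W"]], b = params[["l1.f.b"]]),
                           fwd$f1, dH1f)
  grads[["l1.f.W"]] <- fk1$dW; grads[["l1.f.b"]] <- fk1$db
  if (l2 > 0)
    for (nm in weight_names(params))
      grads[[nm]] <- grads[[nm]] + 2 * l2 * params[[nm]]
  grads[names(params)]
}

cross_entropy <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-300)))
}

l2_penalty <- function(params, l2) {
  if (l2 <= 0) return(0)
  l2 * sum(vapply(weight_names(params), function(nm) sum(params[[nm]]^2), 0))
}

#' Run a stacked LSTM classifier over one sequence
#'
#' Low-level forward pass for a single (already scaled) T x C matrix:
#' per-time level-2 features and softmax class scores.
#'
#' @param model an \code{\link{lstm_classifier}} fit, or a bare list with
#'   elements \code{params} and \code{arch}.
#' @param seq numeric T x C matrix.
#' @return list with \code{features} (T x feature matrix of level-2 hidden
#'   states; forward and backward concatenated for bidirectional models)
#'   and \code{scores} (length n_classes softmax vector over the final
#'   feature).
#' @export
run_stack <- function(model, seq) {
  seq <- as.matrix(seq)
  if (ncol(seq) != model$arch$input)
    stop("sequence has ", ncol(seq), " channels; model expects ",
         model$arch$input, call. = FALSE)
  X <- array(seq, c(1, nrow(seq), ncol(seq)))
  fwd <- stack_forward(model$params, model$arch, X)
  list(features = matrix(fwd$H2[1, , ], nrow(seq)),
       scores = drop(fwd$probs))
}

## ---- fitting ----

#' Fit a stacked LSTM stroke classifier
#'
#' Trains a two-level (optionally bidirectional) LSTM on the training split
#' of a stroke dataset to predict the joint (subject, skill) class, by
#' minimizing mean cross-entropy plus an L2 weight penalty with Adam.
#' Min-max scaling is fitted on the training split only and stored in the
#' returned model. No dropout is used.
#'
#' @param data a \code{\link{stroke_dataset}} with train (and usually test)
#'   splits, unscaled.
#' @param direction "bi" (bidirectional, default) or "uni".
#' @param hidden hidden units per cell (default 38).
#' @param epochs training epochs (default 300).
#' @param batch_size minibatch size (default 10); use \code{Inf} or the
#'   training-set size for full-batch steps.
#' @param learning_rate Adam step size (default 1e-3).
#' @param l2 L2 penalty coefficient on weight matrices (default 1e-4);
#'   biases are exempt.
#' @param seed integer seed controlling initialization and shuffling; fits
#'   are bitwise reproducible given the seed.
#' @param init_params optional warm-start parameter list (e.g. for
#'   retraining after pruning).
#' @param mask optional \code{\link{compute_mask}} result; masked weights
#'   are forced to exactly zero after initialization and after every
#'   optimizer step.
#' @param pooling classification feature: "final" (default) uses the
#'   final-time level-2 hidden state (final forward and final backward
#'   states concatenated for "bi"); "mean" averages the level-2 hidden
#'   states over time, which weights evidence from every time step
#'   equally.
#' @param max_grad_norm global gradient-norm clip (default 5); recurrent
#'   nets are prone to occasional exploding gradients and clipping keeps
#'   Adam steps stable. Set \code{Inf} to disable.
#' @param eval_every record learning-curve points every this many epochs.
#' @param verbose print progress.
#' @return An object of class \code{lstm_classifier} with elements
#'   \code{params}, \code{arch}, \code{scaler}, \code{labels},
#'   \code{history} (learning curves), \code{mask} and \code{config}.
#' @export
lstm_classifier <- function(data, direction = c("bi", "uni"), hidden = 38,
                            epochs = 300, batch_size = 10,
                            learning_rate = 1e-3, l2 = 1e-4, seed = 1L,
                            init_params = NULL, mask = NULL,
                            pooling = c("final", "mean"),
                            max_grad_norm = 5, eval_every = 10,
                            verbose = FALSE) {
  direction <- match.arg(direction)
  pooling <- match.arg(pooling)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, l2 >= 0)
  tr <- dataset_split(data, "train")
  te <- dataset_split(data, "test")
  if (!length(tr)) stop("no training strokes")
  scaler <- fit_scaler(data)
  Xtr <- scale_array(scaler, dataset_array(tr))
  ytr <- dataset_meta(tr)$class
  K <- data$labels$n_classes
  arch <- arch_spec(direction, hidden, dim(Xtr)[3], K, pooling = pooling)
  Ntr <- dim(Xtr)[1]
  Ytr <- matrix(0, Ntr, K); Ytr[cbind(seq_len(Ntr), ytr)] <- 1
  has_test <- length(te) > 0
  if (has_test) {
    Xte <- scale_array(scaler, dataset_array(te))
    yte <- dataset_meta(te)$class
    Yte <- matrix(0, dim(Xte)[1], K); Yte[cbind(seq_len(dim(Xte)[1]), yte)] <- 1
  }
  params <- if (is.null(init_params)) init_classifier_params(arch, seed)
            else init_params
  set.seed(as.integer(derive_seed(seed, 7)))
  if (!is.null(mask)) params <- apply_mask(params, mask)
  state <- adam_init(params)
  bs <- min(batch_size, Ntr)
  hist <- list()
  record <- function(epoch) {
    ftr <- stack_forward(params, arch, Xtr)
    row <- data.frame(epoch = epoch,
                      train_cost = cross_entropy(ftr$probs, Ytr) +
                        l2_penalty(params, l2),
                      train_acc = mean(max.col(ftr$probs) == ytr),
                      test_cost = NA_real_, test_acc = NA_real_)
    if (has_test) {
      fte <- stack_forward(params, arch, Xte)
      row$test_cost <- cross_entropy(fte$probs, Yte)
      row$test_acc <- mean(max.col(fte$probs) == yte)
    }
    row
  }
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(Ntr)
    for (start in seq(1, Ntr, by = bs)) {
      idx <- perm[start:min(start + bs - 1, Ntr)]
      fwd <- stack_forward(params, arch, Xtr[idx, , , drop = FALSE],
                           keep_cache = TRUE)
      cost <- cross_entropy(fwd$probs, Ytr[idx, , drop = FALSE]) +
        l2_penalty(params, l2)
      if (!is.finite(cost))
        stop("training diverged (cost is not finite) at epoch ", epoch,
             "; try a smaller learning rate", call. = FALSE)
      grads <- stack_backward(params, arch, fwd, Ytr[idx, , drop = FALSE], l2)
      if (is.finite(max_grad_norm)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
        if (gn > max_grad_norm)
          grads <- lapply(grads, function(g) g * (max_grad_norm / gn))
      }
      upd <- adam_step(params, grads, state, lr = learning_rate)
      params <- upd$params; state <- upd$state
      if (!is.null(mask)) params <- apply_mask(params, mask)
    }
    if (epoch %% eval_every == 0 || epoch == epochs) {
      hist[[length(hist) + 1]] <- record(epoch)
      if (verbose) {
        r <- hist[[length(hist)]]
        message(sprintf("epoch %d: train cost %.4f acc %.3f%s", epoch,
                        r$train_cost, r$train_acc,
                        if (has_test) sprintf(" | test acc %.3f", r$test_acc)
                        else ""))
      }
    }
  }
  structure(list(params = params, arch = arch, scaler = scaler,
                 labels = data$labels,
                 history = do.call(rbind, hist), mask = mask,
                 config = list(direction = direction, hidden = hidden,
                               epochs = epochs, batch_size = bs,
                               learning_rate = learning_rate, l2 = l2,
                               seed = seed),
                 call = match.call()),
            class = "lstm_classifier")
}

#' @export
print.lstm_classifier <- function(x, ...) {
  cat("<lstm_classifier> two-stacked ",
      if (x$arch$direction == "bi") "bidirectional" else "unidirectional",
      " LSTM\n", sep = "")
  cat("  input ", x$arch$input, " channels, hidden ", x$arch$hidden,
      ", classes ", x$arch$n_classes, ", parameters ", count_params(x), "\n",
      sep = "")
  if (!is.null(x$mask))
    cat("  pruned: sparsity ", format(attr(x$mask, "sparsity")), "\n", sep = "")
  h <- x$history
  if (!is.null(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final train accuracy %.1f%%", 100 * last$train_acc))
    if (is.finite(last$test_acc))
      cat(sprintf(", test accuracy %.1f%%", 100 * last$test_acc))
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.lstm_classifier <- function(object, ...) {
  h <- object$arch$hidden
  out <- list()
  for (cn in cell_names(object$arch)) {
    W <- object$params[[paste0(cn, ".W")]]
    b <- object$params[[paste0(cn, ".b")]]
    ind <- nrow(W) - h
    gates <- lapply(seq_along(GATES), function(k) {
      cols <- (k - 1) * h + 1:h
      list(W_x = t(W[1:ind, cols, drop = FALSE]),
           W_h = t(W[ind + 1:h, cols, drop = FALSE]),
           b = b[cols])
    })
    names(gates) <- GATES
    out[[cn]] <- gates
  }
  out$readout <- list(W = t(object$params[["out.W"]]),
                      b = object$params[["out.b"]])
  out
}

#' Predict from a fitted LSTM stroke classifier
#'
#' @param object an \code{\link{lstm_classifier}}.
#' @param newdata a \code{\link{stroke_dataset}} (unscaled; the model's
#'   stored scaler is applied).
#' @param type "class" for joint class indices, "prob" for the softmax
#'   matrix, "label" for a data.frame of predicted subject and skill.
#' @param ... unused.
#' @return Per \code{type}.
#' @export
predict.lstm_classifier <- function(object, newdata,
                                    type = c("class", "prob", "label"), ...) {
  type <- match.arg(type)
  X <- scale_array(object$scaler, dataset_array(newdata))
  fwd <- stack_forward(object$params, object$arch, X)
  cls <- max.col(fwd$probs)
  switch(type,
         class = cls,
         prob = fwd$probs,
         label = split_label(object$labels, cls))
}

#' @export
plot.lstm_classifier <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no training history recorded")
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "accuracy", ...)
  if (any(is.finite(h$test_acc)))
    graphics::lines(h$epoch, h$test_acc, lty = 2)
  graphics::plot(h$epoch, h$train_cost, type = "l", xlab = "epoch",
                 ylab = "cost", main = "cost", ...)
  if (any(is.finite(h$test_cost)))
    graphics::lines(h$epoch, h$test_cost, lty = 2)
  invisible(x)
}

## ---- evaluation ----

#' Evaluate a classifier on a labelled stroke dataset
#'
#' @param model an \code{\link{lstm_classifier}}.
#' @param data a labelled \code{\link{stroke_dataset}} (typically the test
#'   split).
#' @return An \code{eval_report}: confusion matrix (rows = true class),
#'   overall accuracy, and macro-averaged precision, recall and F1.
#' @export
evaluate_classifier <- function(model, data) {
  if (!length(data)) stop("cannot evaluate on an empty dataset")
  truth <- dataset_meta(data)$class
  pred <- predict(model, data)
  eval_report(truth, pred, model$labels)
}

#' Build a classification evaluation report
#'
#' @param truth,pred integer joint class indices.
#' @param labels a \code{\link{label_spec}}.
#' @return An object of class \code{eval_report}.
#' @export
eval_report <- function(truth, pred, labels = label_spec()) {
  K <- labels$n_classes
  cm <- matrix(0L, K, K)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  present <- which(rowSums(cm) > 0)
  if (length(present) < K)
    warning("class(es) absent from the evaluation set are skipped in ",
            "macro averages: ", paste(setdiff(seq_len(K), present),
                                      collapse = ", "), call. = FALSE)
  prec <- rec <- f1 <- numeric(0)
  for (k in present) {
    tp <- cm[k, k]
    p <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    r <- tp / sum(cm[k, ])
    prec <- c(prec, p); rec <- c(rec, r)
    f1 <- c(f1, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  nm <- paste(rep(labels$subjects, each = length(labels$skills)),
              labels$skills, sep = ":")
  dimnames(cm) <- list(true = nm, predicted = nm)
  structure(list(confusion = cm, n = length(truth),
                 accuracy = sum(diag(cm)) / length(truth),
                 macro_precision = mean(prec), macro_recall = mean(rec),
                 macro_f1 = mean(f1)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n = ", x$n, "\n", sep = "")
  cat(sprintf("  overall accuracy  %.1f%%\n", 100 * x$accuracy))
  cat(sprintf("  macro precision   %.1f%%\n", 100 * x$macro_precision))
  cat(sprintf("  macro recall      %.1f%%\n", 100 * x$macro_recall))
  cat(sprintf("  macro F1          %.1f%%\n", 100 * x$macro_f1))
  invisible(x)
}

## ---- parameter counting ----

#' Count trainable parameters of a classifier
#'
#' @param model an \code{\link{lstm_classifier}} (or list with
#'   \code{params}).
#' @return integer total number of stored weights and biases.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' Closed-form parameter count for a stacked LSTM architecture
#'
#' Per cell 4 * (hidden * (input + hidden) + hidden); readout
#' n_classes * feature + n_classes.
#'
#' @param direction "uni" or "bi".
#' @param hidden,input,n_classes architecture sizes.
#' @return integer count, equal to \code{\link{count_params}} on a model
#'   with the same architecture.
#' @export
param_count_formula <- function(direction = c("bi", "uni"), hidden = 38,
                                input = 18, n_classes = 10) {
  direction <- match.arg(direction)
  arch <- arch_spec(direction, hidden, input, n_classes)
  total <- 0
  for (cn in cell_names(arch)) {
    lvl <- as.integer(substr(cn, 2, 2))
    ind <- cell_input_dim(arch, lvl)
    total <- total + 4 * (hidden * (ind + hidden) + hidden)
  }
  total + n_classes * arch$feature + n_classes
}
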