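# Deep Markov model (nonlinear Gaussian state-space model) fitted by
# structured variational inference.
#
# Generative model (parameters theta):
#   z_1 ~ N(mu0, diag(v0));  z_t | z_{t-1} ~ N(mu_tr(z_{t-1}), diag(v_tr(z_{t-1})))
#   x_t | z_t ~ N(mu_em(z_t), diag(v_em(z_t)))
# with mu/v given by small neural networks (one tanh hidden layer; width 0
# means affine), variances softplus-parameterized.
#
# Structured variational posterior (parameters phi):
#   q(z_t | z_{t-1}, x_{t:T}) = N(mu_q(z_{t-1}, s_t), diag(v_q(z_{t-1}, s_t)))
# where s_t is the state of a backward (anti-causal) tanh RNN summarizing
# the future observations x_{t:T}.
#
# Training maximizes the evidence lower bound
#   ELBO = E_q[ log p(x_{1:T} | z_{1:T}) ] - KL( q(z_{1:T}|x_{1:T}) || p(z_{1:T}) )
# by reparameterized sampling of the reconstruction term and per-step
# analytic Gaussian KL conditioned on the sampled z_{t-1}. Gradients are
# exact reverse-mode differentiation written out by hand (checked against
# finite differences in the test suite).

VAR_EPS <- 1e-6

## ---- small Gaussian-output networks ----

gauss_net_init <- function(din, dout, width, prefix, params, scale = 0.1) {
  if (width > 0) {
    params[[paste0(prefix, ".W1")]] <- matrix(stats::rnorm(din * width, 0,
                                                           scale / sqrt(din)),
                                              din, width)
    params[[paste0(prefix, ".b1")]] <- numeric(width)
    dh <- width
  } else dh <- din
  params[[paste0(prefix, ".Wm")]] <- matrix(stats::rnorm(dh * dout, 0,
                                                         scale / sqrt(dh)),
                                            dh, dout)
  params[[paste0(prefix, ".bm")]] <- numeric(dout)
  params[[paste0(prefix, ".Wv")]] <- matrix(stats::rnorm(dh * dout, 0,
                                                         scale / sqrt(dh)),
                                            dh, dout)
  params[[paste0(prefix, ".bv")]] <- rep(-1, dout)  # start with small variances
  params
}

gauss_net_forward <- function(params, prefix, input) {
  W1 <- params[[paste0(prefix, ".W1")]]
  if (!is.null(W1)) {
    a <- input %*% W1 + matrix(params[[paste0(prefix, ".b1")]],
                               nrow(input), ncol(W1), byrow = TRUE)
    h <- tanh(a)
  } else h <- input
  mean <- h %*% params[[paste0(prefix, ".Wm")]] +
    matrix(params[[paste0(prefix, ".bm")]], nrow(input),
           ncol(params[[paste0(prefix, ".Wm")]]), byrow = TRUE)
  rawv <- h %*% params[[paste0(prefix, ".Wv")]] +
    matrix(params[[paste0(prefix, ".bv")]], nrow(input),
           ncol(params[[paste0(prefix, ".Wv")]]), byrow = TRUE)
  list(mean = mean, var = softplus(rawv) + VAR_EPS, h = h, rawv = rawv,
       input = input)
}

gauss_net_backward <- function(params, prefix, cache, dmean, dvar, grads) {
  drawv <- dvar * sigmoid(cache$rawv)
  add <- function(nm, g) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  }
  add(paste0(prefix, ".Wm"), crossprod(cache$h, dmean))
  add(paste0(prefix, ".bm"), colSums(dmean))
  add(paste0(prefix, ".Wv"), crossprod(cache$h, drawv))
  add(paste0(prefix, ".bv"), colSums(drawv))
  dh <- dmean %*% t(params[[paste0(prefix, ".Wm")]]) +
    drawv %*% t(params[[paste0(prefix, ".Wv")]])
  W1 <- params[[paste0(prefix, ".W1")]]
  if (!is.null(W1)) {
    da <- dh * (1 - cache$h^2)
    add(paste0(prefix, ".W1"), crossprod(cache$input, da))
    add(paste0(prefix, ".b1"), colSums(da))
    dinput <- da %*% t(W1)
  } else dinput <- dh
  list(grads = grads, dinput = dinput)
}

## ---- exported Gaussian primitives ----

#' KL divergence between diagonal Gaussians
#'
#' Closed-form KL(N(mq, diag(vq)) || N(mp, diag(vp))), non-negative and
#' zero iff the two distributions coincide.
#'
#' @param mq,vq mean and variance vectors of the first Gaussian.
#' @param mp,vp mean and variance vectors of the second Gaussian.
#' @return scalar KL divergence (nats).
#' @export
kl_gaussian <- function(mq, vq, mp, vp) {
  if (any(vq <= 0) || any(vp <= 0))
    stop("variances must be positive", call. = FALSE)
  0.5 * sum(log(vp / vq) + (vq + (mq - mp)^2) / vp - 1)
}

#' Log-density of a diagonal Gaussian
#'
#' @param x observation vector (or matrix, rows summed independently).
#' @param mean,var mean and variance (recycled to x's shape).
#' @return scalar (or per-row vector) log-density.
#' @export
diag_gauss_loglik <- function(x, mean, var) {
  if (any(var <= 0)) stop("variances must be positive", call. = FALSE)
  ll <- -0.5 * (log(2 * pi) + log(var) + (x - mean)^2 / var)
  if (is.matrix(x)) rowSums(ll) else sum(ll)
}

## ---- model construction ----

dmm_arch <- function(obs_dim, latent_dim = 2, trans_width = 32,
                     emis_width = 32, q_width = 32, summary_dim = 32) {
  stopifnot(obs_dim >= 1, latent_dim >= 1, summary_dim >= 1)
  list(obs_dim = obs_dim, latent_dim = latent_dim, trans_width = trans_width,
       emis_width = emis_width, q_width = q_width, summary_dim = summary_dim)
}

dmm_init_params <- function(arch, seed = 1L) {
  set.seed(as.integer(seed))
  L <- arch$latent_dim; D <- arch$obs_dim; m <- arch$summary_dim
  params <- list()
  params[["theta.mu0"]] <- numeric(L)
  params[["theta.rho0"]] <- numeric(L)  # prior variance = softplus(0) ~ 0.69
  params <- gauss_net_init(L, L, arch$trans_width, "theta.tr", params)
  params <- gauss_net_init(L, D, arch$emis_width, "theta.em", params)
  params[["phi.sum.Wx"]] <- matrix(stats::rnorm(D * m, 0, 1 / sqrt(D)), D, m)
  params[["phi.sum.Ws"]] <- matrix(stats::rnorm(m * m, 0, 0.5 / sqrt(m)), m, m)
  params[["phi.sum.b"]] <- numeric(m)
  params <- gauss_net_init(L + m, L, arch$q_width, "phi.q", params)
  params
}

# backward (anti-causal) summarizer over x: S[, t, ] summarizes x_{t:T}
dmm_summarize <- function(params, X) {
  N <- dim(X)[1]; Tn <- dim(X)[2]
  m <- ncol(params[["phi.sum.Wx"]])
  S <- array(0, c(N, Tn, m))
  s_next <- matrix(0, N, m)
  bmat <- matrix(params[["phi.sum.b"]], N, m, byrow = TRUE)
  for (t in Tn:1) {
    a <- matrix(X[, t, ], N) %*% params[["phi.sum.Wx"]] +
      s_next %*% params[["phi.sum.Ws"]] + bmat
    s_next <- tanh(a)
    S[, t, ] <- s_next
  }
  S
}

# One-sample ELBO forward (and optionally backward) pass, batched over N.
# X: N x T x D; eps: N x T x L standard normal draws.
# Returns per-sequence recon and kl vectors and, with grads = TRUE, the
# gradient of mean(recon - kl) w.r.t. every parameter.
dmm_pass <- function(params, arch, X, eps, grads = FALSE) {
  N <- dim(X)[1]; Tn <- dim(X)[2]
  L <- arch$latent_dim
  S <- dmm_summarize(params, X)
  v0 <- softplus(params[["theta.rho0"]]) + VAR_EPS
  mu0 <- params[["theta.mu0"]]
  z_prev <- matrix(mu0, N, L, byrow = TRUE)
  recon <- numeric(N); kl <- numeric(N)
  qc <- vector("list", Tn); trc <- vector("list", Tn); emc <- vector("list", Tn)
  Z <- array(0, c(N, Tn, L)); MUP <- array(0, c(N, Tn, L))
  VP <- array(0, c(N, Tn, L))
  for (t in seq_len(Tn)) {
    u <- cbind(z_prev, matrix(S[, t, ], N))
    q <- gauss_net_forward(params, "phi.q", u)
    zt <- q$mean + sqrt(q$var) * matrix(eps[, t, ], N)
    if (t == 1) {
      mup <- matrix(mu0, N, L, byrow = TRUE)
      vp <- matrix(v0, N, L, byrow = TRUE)
    } else {
      tr <- gauss_net_forward(params, "theta.tr", z_prev)
      mup <- tr$mean; vp <- tr$var
      trc[[t]] <- tr
    }
    kl <- kl + 0.5 * rowSums(log(vp / q$var) + (q$var + (q$mean - mup)^2) / vp - 1)
    em <- gauss_net_forward(params, "theta.em", zt)
    recon <- recon + rowSums(-0.5 * (log(2 * pi) + log(em$var) +
                                       (matrix(X[, t, ], N) - em$mean)^2 / em$var))
    qc[[t]] <- q; emc[[t]] <- em
    Z[, t, ] <- zt; MUP[, t, ] <- mup; VP[, t, ] <- vp
    z_prev <- zt
  }
  if (!all(is.finite(recon)) || !all(is.finite(kl)))
    stop("non-finite ELBO terms encountered", call. = FALSE)
  out <- list(recon = recon, kl = kl)
  if (!grads) return(out)

  G <- list()
  dmu0 <- numeric(L); drho0_v <- numeric(L)
  dz_carry <- matrix(0, N, L)
  for (t in Tn:1) {
    q <- qc[[t]]; em <- emc[[t]]
    zt <- matrix(Z[, t, ], N)
    xt <- matrix(X[, t, ], N)
    mup <- matrix(MUP[, t, ], N); vp <- matrix(VP[, t, ], N)
    # reconstruction term at t (part of +recon)
    dmean_e <- (xt - em$mean) / em$var
    dvar_e <- 0.5 * ((xt - em$mean)^2 / em$var^2 - 1 / em$var)
    eb <- gauss_net_backward(params, "theta.em", em, dmean_e, dvar_e, G)
    G <- eb$grads
    dz <- dz_carry + eb$dinput
    # sampling: z_t = mu_q + sqrt(v_q) * eps
    ept <- matrix(eps[, t, ], N)
    dmq <- dz
    dvq <- dz * ept / (2 * sqrt(q$var))
    # -KL_t contributions
    delta <- q$mean - mup
    dmq <- dmq - delta / vp
    dvq <- dvq - 0.5 * (1 / vp - 1 / q$var)
    dmp <- delta / vp
    dvp <- -0.5 * (1 / vp - (q$var + delta^2) / vp^2)
    if (t == 1) {
      dmu0 <- dmu0 + colSums(dmp)
      drho0_v <- drho0_v + colSums(dvp)
      dz_prior <- matrix(0, N, L)
    } else {
      tb <- gauss_net_backward(params, "theta.tr", trc[[t]], dmp, dvp, G)
      G <- tb$grads
      dz_prior <- tb$dinput
    }
    qb <- gauss_net_backward(params, "phi.q", q, dmq, dvq, G)
    G <- qb$grads
    du <- qb$dinput
    if (is.null(G[["dS"]])) G[["dS"]] <- array(0, dim(S))
    G[["dS"]][, t, ] <- du[, L + seq_len(arch$summary_dim), drop = FALSE]
    dz_carry <- dz_prior + du[, seq_len(L), drop = FALSE]
  }
  dmu0 <- dmu0 + colSums(dz_carry)  # z_0 is the broadcast prior mean
  dS <- G[["dS"]]; G[["dS"]] <- NULL
  # summarizer BPTT (computed T..1, so reverse pass runs 1..T)
  Wx <- params[["phi.sum.Wx"]]; Ws <- params[["phi.sum.Ws"]]
  dWx <- Wx * 0; dWs <- Ws * 0; db <- numeric(ncol(Wx))
  carry <- matrix(0, N, ncol(Wx))
  for (t in seq_len(Tn)) {
    st <- matrix(S[, t, ], N)
    ds <- matrix(dS[, t, ], N) + carry
    da <- ds * (1 - st^2)
    dWx <- dWx + crossprod(matrix(X[, t, ], N), da)
    if (t < Tn) dWs <- dWs + crossprod(matrix(S[, t + 1, ], N), da)
    db <- db + colSums(da)
    carry <- da %*% t(Ws)
  }
  G[["phi.sum.Wx"]] <- dWx; G[["phi.sum.Ws"]] <- dWs; G[["phi.sum.b"]] <- db
  G[["theta.mu0"]] <- dmu0
  G[["theta.rho0"]] <- drho0_v * sigmoid(params[["theta.rho0"]])
  # mean over sequences
  for (nm in names(G)) G[[nm]] <- G[[nm]] / N
  missing <- setdiff(names(params), names(G))
  for (nm in missing) G[[nm]] <- params[[nm]] * 0
  list(recon = recon, kl = kl, grads = G[names(params)])
}

as_dmm_array <- function(x) {
  if (inherits(x, "embedding_set")) return(x$x)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) return(array(x, c(1, nrow(x), ncol(x))))
  if (is.list(x)) {
    Tn <- nrow(x[[1]]); D <- ncol(x[[1]])
    out <- array(0, c(length(x), Tn, D))
    for (i in seq_along(x)) out[i, , ] <- x[[i]]
    return(out)
  }
  stop("cannot interpret observations: need an N x T x D array, a T x D ",
       "matrix, a list of T x D matrices, or an embedding_set", call. = FALSE)
}

#' Fit a deep Markov model by variational inference
#'
#' Fits the generative parameters theta (initial prior, transition and
#' emission networks) and the variational parameters phi (backward
#' summarizer and posterior network) by full-batch Adam ascent on the
#' reparameterized evidence lower bound.
#'
#' @param x observations: an \code{embedding_set} from
#'   \code{\link{embed_sequences}}, an N x T x D array, or a list of T x D
#'   matrices.
#' @param latent_dim latent state dimension (default 2: the coaching
#'   artifact is a low-dimensional trajectory).
#' @param epochs Adam epochs (one full-batch gradient step each).
#' @param learning_rate Adam step size.
#' @param n_samples Monte-Carlo samples per gradient step (default 1,
#'   reparameterized).
#' @param trans_width,emis_width,q_width hidden width of the transition,
#'   emission and posterior networks (0 = affine).
#' @param summary_dim state size of the backward summarizer RNN.
#' @param seed integer seed; fits are reproducible bitwise.
#' @param verbose print ELBO progress.
#' @return An object of class \code{dmm} with \code{params}, \code{arch},
#'   \code{history} (per-epoch one-sample ELBO) and \code{config}.
#' @export
dmm <- function(x, latent_dim = 2, epochs = 500, learning_rate = 1e-2,
                n_samples = 1, trans_width = 32, emis_width = 32,
                q_width = 32, summary_dim = 32, seed = 1L, verbose = FALSE) {
  X <- as_dmm_array(x)
  meta <- if (inherits(x, "embedding_set")) x$meta
  N <- dim(X)[1]; Tn <- dim(X)[2]; D <- dim(X)[3]
  stopifnot(N >= 1, Tn >= 1, epochs >= 1, n_samples >= 1)
  arch <- dmm_arch(D, latent_dim, trans_width, emis_width, q_width,
                   summary_dim)
  params <- dmm_init_params(arch, seed)
  set.seed(as.integer(derive_seed(seed, 11)))
  state <- adam_init(params)
  elbo_curve <- numeric(epochs)
  L <- latent_dim
  for (epoch in seq_len(epochs)) {
    acc <- NULL; obj <- 0
    for (s in seq_len(n_samples)) {
      eps <- array(stats::rnorm(N * Tn * L), c(N, Tn, L))
      p <- dmm_pass(params, arch, X, eps, grads = TRUE)
      obj <- obj + mean(p$recon - p$kl) / n_samples
      if (is.null(acc)) acc <- p$grads
      else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + p$grads[[nm]]
    }
    if (!is.finite(obj))
      stop("ELBO optimization diverged at epoch ", epoch,
           "; try a smaller learning rate", call. = FALSE)
    for (nm in names(acc)) acc[[nm]] <- -acc[[nm]] / n_samples  # minimize -ELBO
    upd <- adam_step(params, acc, state, lr = learning_rate)
    params <- upd$params; state <- upd$state
    elbo_curve[epoch] <- obj
    if (verbose && (epoch %% 50 == 0 || epoch == 1))
      message(sprintf("epoch %d: ELBO %.3f", epoch, obj))
  }
  structure(list(params = params, arch = arch,
                 history = data.frame(epoch = seq_len(epochs),
                                      elbo = elbo_curve),
                 meta = meta,
                 config = list(latent_dim = latent_dim, epochs = epochs,
                               learning_rate = learning_rate,
                               n_samples = n_samples, seed = seed)),
            class = "dmm")
}

#' @export
print.dmm <- function(x, ...) {
  cat("<dmm> deep Markov model: latent dim ", x$arch$latent_dim,
      ", observation dim ", x$arch$obs_dim, "\n", sep = "")
  cat(sprintf("  trained %d epochs; final one-sample ELBO %.3f\n",
              nrow(x$history), x$history$elbo[nrow(x$history)]))
  invisible(x)
}

#' @export
plot.dmm <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$elbo, type = "l",
                 xlab = "epoch", ylab = "ELBO (one-sample)", ...)
  invisible(x)
}

#' Monte-Carlo evidence lower bound of a fitted deep Markov model
#'
#' Estimates the ELBO with \code{n_samples} reparameterized draws; the
#' reconstruction term is Monte-Carlo, the per-step KL term is analytic
#' given the sampled previous latent. By construction
#' \code{total = reconstruction - kl} exactly.
#'
#' @param model a \code{\link{dmm}} fit (or list with \code{params},
#'   \code{arch}).
#' @param x observations (same forms as in \code{\link{dmm}}).
#' @param n_samples Monte-Carlo draws (default 32).
#' @param seed seed for the draws.
#' @return An \code{elbo_report}: \code{total}, \code{reconstruction},
#'   \code{kl} (dataset means per sequence) and \code{per_sequence}.
#' @export
dmm_elbo <- function(model, x, n_samples = 32, seed = 1L) {
  X <- as_dmm_array(x)
  N <- dim(X)[1]; Tn <- dim(X)[2]; L <- model$arch$latent_dim
  set.seed(as.integer(seed))
  recon <- matrix(0, N, n_samples); kl <- matrix(0, N, n_samples)
  for (s in seq_len(n_samples)) {
    eps <- array(stats::rnorm(N * Tn * L), c(N, Tn, L))
    p <- dmm_pass(model$params, model$arch, X, eps)
    recon[, s] <- p$recon; kl[, s] <- p$kl
  }
  rs <- rowMeans(recon); ks <- rowMeans(kl)
  structure(list(total = mean(rs - ks), reconstruction = mean(rs),
                 kl = mean(ks),
                 per_sequence = data.frame(reconstruction = rs, kl = ks,
                                           elbo = rs - ks),
                 n_samples = n_samples),
            class = "elbo_report")
}

#' @export
print.elbo_report <- function(x, ...) {
  cat(sprintf("<elbo_report> ELBO %.4f = reconstruction %.4f - KL %.4f (%d samples)\n",
              x$total, x$reconstruction, x$kl, x$n_samples))
  invisible(x)
}

#' Posterior-mean latent trajectory for one sequence
#'
#' Deterministic mean propagation through the structured posterior:
#' z_0 is the prior mean and z_t = mu_q(z_{t-1}, s_t) with s_t the
#' backward summarizer state. No sampling is involved, so identical
#' inputs give identical trajectories.
#'
#' @param model a fitted \code{\link{dmm}}.
#' @param x a T x D observation (embedding) matrix.
#' @param labels optional named list/vector of stroke labels (subject,
#'   skill, rep, split) attached as attributes.
#' @return T x latent_dim matrix of class \code{latent_trajectory}.
#' @export
infer_trajectory <- function(model, x, labels = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != model$arch$obs_dim)
    stop("observation dim ", ncol(x), " does not match model (",
         model$arch$obs_dim, ")", call. = FALSE)
  params <- model$params
  X <- array(x, c(1, nrow(x), ncol(x)))
  S <- dmm_summarize(params, X)
  L <- model$arch$latent_dim
  z <- matrix(params[["theta.mu0"]], 1, L)
  out <- matrix(0, nrow(x), L)
  for (t in seq_len(nrow(x))) {
    q <- gauss_net_forward(params, "phi.q", cbind(z, matrix(S[, t, ], 1)))
    z <- q$mean
    out[t, ] <- z
  }
  structure(out, class = c("latent_trajectory", "matrix"),
            labels = as.list(labels))
}

#' Latent trajectories for a whole embedding set
#'
#' @param model a fitted \code{\link{dmm}}.
#' @param x an \code{embedding_set}, N x T x D array or list of matrices.
#' @return list of \code{latent_trajectory} objects (with labels when the
#'   input carries metadata).
#' @export
infer_trajectories <- function(model, x) {
  X <- as_dmm_array(x)
  meta <- if (inherits(x, "embedding_set")) x$meta else NULL
  lapply(seq_len(dim(X)[1]), function(i)
    infer_trajectory(model, matrix(X[i, , ], dim(X)[2]),
                     labels = if (!is.null(meta)) as.list(meta[i, ])))
}

#' @export
predict.dmm <- function(object, newdata, ...) {
  if (is.matrix(newdata)) infer_trajectory(object, newdata)
  else infer_trajectories(object, newdata)
}

#' Simulate sequences from a fitted deep Markov model
#'
#' Generative rollout: draw z_1 from the initial prior, propagate through
#' the transition network, and emit observations.
#'
#' @param object a \code{\link{dmm}}.
#' @param nsim number of sequences.
#' @param seed optional integer seed.
#' @param n_time sequence length (default 27).
#' @param ... unused.
#' @return list of \code{nsim} elements, each with matrices \code{x}
#'   (n_time x obs_dim) and \code{z} (n_time x latent_dim).
#' @export
simulate.dmm <- function(object, nsim = 1, seed = NULL, n_time = 27, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  params <- object$params
  L <- object$arch$latent_dim; D <- object$arch$obs_dim
  v0 <- softplus(params[["theta.rho0"]]) + VAR_EPS
  lapply(seq_len(nsim), function(i) {
    z <- matrix(0, n_time, L); x <- matrix(0, n_time, D)
    zt <- matrix(params[["theta.mu0"]] + sqrt(v0) * stats::rnorm(L), 1)
    for (t in seq_len(n_time)) {
      z[t, ] <- zt
      em <- gauss_net_forward(params, "theta.em", zt)
      x[t, ] <- em$mean + sqrt(em$var) * stats::rnorm(D)
      tr <- gauss_net_forward(params, "theta.tr", zt)
      zt <- tr$mean + sqrt(tr$var) * stats::rnorm(L)
    }
    list(x = x, z = z)
  })
}

#' @export
summary.dmm <- function(object, ...) {
  cat("Deep Markov model\n")
  print(object)
  cat("  networks: transition width ", object$arch$trans_width,
      ", emission width ", object$arch$emis_width, ", posterior width ",
      object$arch$q_width, ", summarizer dim ", object$arch$summary_dim,
      "\n", sep = "")
  invisible(object)
}

## ---- classifier embeddings ----

#' Embed strokes through a frozen LSTM classifier
#'
#' Returns the level-2 hidden-state sequences of the classifier (forward
#' and backward concatenated for bidirectional models): the features the
#' classifier itself uses, re-used as observations for the deep Markov
#' model.
#'
#' @param model a trained \code{\link{lstm_classifier}}.
#' @param data a \code{\link{stroke_dataset}} (unscaled; the model's
#'   scaler is applied first).
#' @return An \code{embedding_set}: list with \code{x} (N x T x obs_dim
#'   array, obs_dim = hidden for "uni", 2*hidden for "bi") and \code{meta}
#'   (the dataset's design metadata).
#' @export
embed_sequences <- function(model, data) {
  X <- scale_array(model$scaler, dataset_array(data))
  fwd <- stack_forward(model$params, model$arch, X)
  structure(list(x = fwd$H2, meta = dataset_meta(data)),
            class = "embedding_set")
}

## ---- Kalman filter oracle ----

#' Exact log-likelihood of a linear-Gaussian state-space model
#'
#' Kalman-filter prediction-error decomposition: for z_1 ~ N(m0, P0),
#' z_t = A z_{t-1} + w_t, x_t = C z_t + v_t with w ~ N(0, Q), v ~ N(0, R),
#' returns exact log p(x_{1:T}). Used as an independent oracle against
#' which the variational lower bound is validated.
#'
#' @param x T x D observation matrix.
#' @param A,Q latent transition matrix and noise covariance (L x L).
#' @param C,R emission matrix (D x L) and noise covariance (D x D).
#' @param m0,P0 initial state mean (length L) and covariance (L x L).
#' @return scalar exact log-likelihood.
#' @export
kalman_loglik <- function(x, A, Q, C, R, m0, P0) {
  x <- as.matrix(x)
  L <- length(m0); D <- ncol(x)
  stopifnot(all(dim(A) == L), all(dim(Q) == L), nrow(C) == D, ncol(C) == L,
            all(dim(R) == D), all(dim(P0) == L))
  m <- m0; P <- P0
  ll <- 0
  for (t in seq_len(nrow(x))) {
    if (t > 1) {
      m <- drop(A %*% m)
      P <- A %*% P %*% t(A) + Q
    }
    innov <- x[t, ] - drop(C %*% m)
    Sinn <- C %*% P %*% t(C) + R
    ch <- tryCatch(chol(Sinn), error = function(e)
      stop("singular innovation covariance at time step ", t, call. = FALSE))
    logdet <- 2 * sum(log(diag(ch)))
    sol <- backsolve(ch, forwardsolve(t(ch), innov))
    ll <- ll - 0.5 * (D * log(2 * pi) + logdet + sum(innov * sol))
    K <- P %*% t(C) %*% chol2inv(ch)
    m <- m + drop(K %*% innov)
    P <- P - K %*% C %*% P
  }
  ll
}
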