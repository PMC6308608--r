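test_that("diagonal-Gaussian KL follows the closed form", {
  expect_equal(kl_gaussian(0, 1, 0, 1), 0)
  expect_equal(kl_gaussian(1, 1, 0, 1), 0.5)       # (mu^2)/2
  expect_equal(kl_gaussian(c(1, 0), c(1, 1), c(0, 0), c(1, 1)), 0.5)
  set.seed(16)
  for (k in 1:1000) {
    mq <- rnorm(2); vq <- rexp(2) + 0.01
    mp <- rnorm(2); vp <- rexp(2) + 0.01
    expect_gte(kl_gaussian(mq, vq, mp, vp), 0)
  }
  expect_error(kl_gaussian(0, -1, 0, 1), "positive")
})

test_that("Kalman log-likelihood reduces to a Gaussian density at T = 1", {
  mod <- random_lgssm(2, 3, seed = 2)
  x1 <- c(0.3, -0.2, 1.1)
  S <- mod$C %*% mod$P0 %*% t(mod$C) + mod$R
  mu <- drop(mod$C %*% mod$m0)
  direct <- -0.5 * (3 * log(2 * pi) + determinant(S)$modulus[1] +
                      drop(t(x1 - mu) %*% solve(S) %*% (x1 - mu)))
  expect_equal(kalman_loglik(matrix(x1, 1), mod$A, mod$Q, mod$C, mod$R,
                             mod$m0, mod$P0), direct, tolerance = 1e-10)
})

test_that("Kalman log-likelihood agrees with quadrature on a 1-D latent, T = 2", {
  A <- matrix(0.8); Q <- matrix(0.3); C <- matrix(1.2); R <- matrix(0.4)
  m0 <- 0.5; P0 <- matrix(0.6)
  x <- matrix(c(1.0, -0.3), 2, 1)
  # brute force: integrate p(x1,x2) over (z1, z2) on a grid
  g <- seq(-8, 8, length.out = 801)
  dz <- g[2] - g[1]
  pz1 <- dnorm(g, m0, sqrt(P0[1]))
  px1 <- dnorm(x[1], 1.2 * g, sqrt(R[1]))
  joint <- 0
  for (i in seq_along(g)) {
    pz2 <- dnorm(g, 0.8 * g[i], sqrt(Q[1]))
    px2 <- dnorm(x[2], 1.2 * g, sqrt(R[1]))
    joint <- joint + pz1[i] * px1[i] * sum(pz2 * px2) * dz * dz
  }
  expect_equal(kalman_loglik(x, A, Q, C, R, m0, P0), log(joint),
               tolerance = 1e-4)
})

test_that("Kalman log-likelihood is invariant to latent-space rotation", {
  mod <- random_lgssm(2, 3, seed = 4)
  sim <- simulate_lgssm(mod, 1, 6, seed = 5)
  x <- matrix(sim$x[1, , ], 6)
  th <- 0.7
  Rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  ll1 <- kalman_loglik(x, mod$A, mod$Q, mod$C, mod$R, mod$m0, mod$P0)
  ll2 <- kalman_loglik(x, Rot %*% mod$A %*% t(Rot), Rot %*% mod$Q %*% t(Rot),
                       mod$C %*% t(Rot), mod$R, drop(Rot %*% mod$m0),
                       Rot %*% mod$P0 %*% t(Rot))
  expect_equal(ll1, ll2, tolerance = 1e-10)
  expect_error(kalman_loglik(x, mod$A, mod$Q, mod$C, 0 * mod$R, mod$m0,
                             0 * mod$P0), "singular")
})

test_that("ELBO gradients match finite differences", {
  set.seed(17)
  arch <- strokecoach:::dmm_arch(obs_dim = 3, latent_dim = 2,
                                 trans_width = 4, emis_width = 4,
                                 q_width = 4, summary_dim = 3)
  params <- strokecoach:::dmm_init_params(arch, 2)
  N <- 2; Tn <- 3
  X <- array(rnorm(N * Tn * 3), c(N, Tn, 3))
  eps <- array(rnorm(N * Tn * 2), c(N, Tn, 2))
  p <- strokecoach:::dmm_pass(params, arch, X, eps, grads = TRUE)
  obj <- function(pp) {
    q <- strokecoach:::dmm_pass(pp, arch, X, eps)
    mean(q$recon - q$kl)
  }
  h <- 1e-6
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
      fd <- (obj(p1) - obj(p2)) / (2 * h)
      expect_lt(abs(fd - p$grads[[nm]][i]) /
                  max(1e-5, abs(fd) + abs(p$grads[[nm]][i])), 1e-3)
    }
  }
})

test_that("the ELBO report satisfies total = reconstruction - KL and the KL term is analytic", {
  set.seed(18)
  mod <- random_lgssm(2, 3, seed = 6)
  sim <- simulate_lgssm(mod, 4, 5, seed = 7)
  fit <- dmm(sim$x, latent_dim = 2, epochs = 30, learning_rate = 1e-2,
             seed = 3, trans_width = 4, emis_width = 4, q_width = 4,
             summary_dim = 3)
  rep <- dmm_elbo(fit, sim$x, n_samples = 8, seed = 4)
  expect_equal(rep$total, rep$reconstruction - rep$kl, tolerance = 1e-12)
  expect_equal(rep$per_sequence$elbo,
               rep$per_sequence$reconstruction - rep$per_sequence$kl,
               tolerance = 1e-12)
  # KL at T = 1 does not depend on the number of Monte-Carlo draws:
  # the first-step KL is analytic (no sampled conditioning), so averaging
  # over draws leaves it unchanged
  x1 <- sim$x[, 1, , drop = FALSE]
  r1 <- dmm_elbo(fit, x1, n_samples = 4, seed = 9)
  r2 <- dmm_elbo(fit, x1, n_samples = 64, seed = 10)
  expect_equal(r1$kl, r2$kl, tolerance = 1e-12)
})

test_that("the ELBO never exceeds the exact Kalman evidence", {
  # theta fixed to a true linear-Gaussian model (affine networks);
  # 100 random phi draws must all stay below the exact log-likelihood
  mod <- random_lgssm(2, 3, seed = 8)
  sim <- simulate_lgssm(mod, 1, 5, seed = 9)
  x <- matrix(sim$x[1, , ], 5)
  exact <- kalman_loglik(x, mod$A, mod$Q, mod$C, mod$R, mod$m0, mod$P0)
  arch <- strokecoach:::dmm_arch(obs_dim = 3, latent_dim = 2,
                                 trans_width = 0, emis_width = 0,
                                 q_width = 0, summary_dim = 3)
  softplus_inv <- function(y) log(expm1(y))
  set.seed(19)
  for (draw in 1:100) {
    params <- strokecoach:::dmm_init_params(arch, draw)
    # overwrite theta with the exact generative model (Q, R, P0 diagonal)
    params[["theta.mu0"]] <- mod$m0
    params[["theta.rho0"]] <- softplus_inv(diag(mod$P0) - 1e-6)
    params[["theta.tr.Wm"]] <- t(mod$A)
    params[["theta.tr.bm"]] <- c(0, 0)
    params[["theta.tr.Wv"]][] <- 0
    params[["theta.tr.bv"]] <- softplus_inv(diag(mod$Q) - 1e-6)
    params[["theta.em.Wm"]] <- t(mod$C)
    params[["theta.em.bm"]] <- c(0, 0, 0)
    params[["theta.em.Wv"]][] <- 0
    params[["theta.em.bv"]] <- softplus_inv(diag(mod$R) - 1e-6)
    # random phi: perturb the posterior nets
    params[["phi.q.Wm"]] <- params[["phi.q.Wm"]] + matrix(rnorm(10, sd = 0.5), 5, 2)
    params[["phi.q.bm"]] <- rnorm(2, sd = 0.5)
    model <- list(params = params, arch = arch)
    rep <- dmm_elbo(model, array(x, c(1, 5, 3)), n_samples = 64, seed = draw)
    expect_lte(rep$total, exact)
  }
})

test_that("with the exact conjugate posterior the T = 1 ELBO attains the evidence", {
  # one latent step, affine model: q*(z1|x1) is Gaussian and available in
  # closed form, so ELBO(q*) = log p(x1) up to Monte-Carlo error
  mod <- random_lgssm(2, 3, seed = 10)
  sim <- simulate_lgssm(mod, 1, 1, seed = 11)
  x1 <- drop(sim$x[1, 1, ])
  exact <- kalman_loglik(matrix(x1, 1), mod$A, mod$Q, mod$C, mod$R,
                         mod$m0, mod$P0)
  # conjugate posterior: Sigma* = (P0^-1 + C' R^-1 C)^-1 (non-diagonal in
  # general; this instance's posterior is evaluated exactly below)
  Sig <- solve(solve(mod$P0) + t(mod$C) %*% solve(mod$R) %*% mod$C)
  mu <- drop(Sig %*% (solve(mod$P0) %*% mod$m0 +
                        t(mod$C) %*% solve(mod$R) %*% x1))
  # Monte-Carlo ELBO with q = N(mu, Sig) using the package's Gaussian
  # primitives: E_q[log p(x|z)] - KL(q || prior)
  set.seed(20)
  ch <- chol(Sig)
  n_mc <- 1e4
  z <- matrix(rnorm(n_mc * 2), n_mc) %*% ch + matrix(mu, n_mc, 2, byrow = TRUE)
  recon <- mean(diag_gauss_loglik(z %*% t(mod$C), matrix(x1, n_mc, 3,
                                                         byrow = TRUE),
                                  matrix(diag(mod$R), n_mc, 3, byrow = TRUE)))
  klq <- 0.5 * (sum(diag(solve(mod$P0) %*% Sig)) - 2 +
                  drop(t(mu - mod$m0) %*% solve(mod$P0) %*% (mu - mod$m0)) +
                  determinant(mod$P0)$modulus[1] - determinant(Sig)$modulus[1])
  expect_equal(recon - klq, exact, tolerance = 1e-2)
})

test_that("DMM fitting raises the ELBO, is seed-stable, and recovers latents", {
  mod <- random_lgssm(2, 8, seed = 12)
  sim <- simulate_lgssm(mod, 50, 15, seed = 13)
  fit <- dmm(sim$x, latent_dim = 2, epochs = 600, learning_rate = 1e-2,
             seed = 5)
  expect_gt(fit$history$elbo[nrow(fit$history)], fit$history$elbo[1])
  fit2 <- dmm(sim$x, latent_dim = 2, epochs = 600, learning_rate = 1e-2,
              seed = 5)
  expect_identical(fit$params, fit2$params)
  # posterior-mean trajectories track the true latents after affine alignment
  est <- do.call(rbind, lapply(infer_trajectories(fit, sim$x), unclass))
  tru <- do.call(rbind, lapply(1:50, function(i) matrix(sim$z[i, , ], 15)))
  ali <- lm(tru ~ est)
  cors <- diag(cor(cbind(1, est) %*% coef(ali), tru))
  expect_gte(mean(cors), 0.9)
})

test_that("posterior-mean trajectories are deterministic with the right shape", {
  mod <- random_lgssm(2, 3, seed = 14)
  sim <- simulate_lgssm(mod, 2, 6, seed = 15)
  fit <- dmm(sim$x, latent_dim = 2, epochs = 20, seed = 6, trans_width = 4,
             emis_width = 4, q_width = 4, summary_dim = 3)
  x1 <- matrix(sim$x[1, , ], 6)
  tr1 <- infer_trajectory(fit, x1)
  tr2 <- infer_trajectory(fit, x1)
  expect_identical(unclass(tr1), unclass(tr2))
  expect_equal(dim(tr1), c(6, 2))
  expect_error(infer_trajectory(fit, x1[, 1:2]), "observation dim")
})

test_that("classifier embeddings have the contract shape and tanh range", {
  set.seed(21)
  ds <- synth_dataset(generator_config(seed = 2, reps_per_cell = 2,
                                       train_reps = 1))
  for (dir in c("uni", "bi")) {
    m <- lstm_classifier(ds, dir, hidden = 6, epochs = 3, batch_size = 10,
                         seed = 2)
    emb <- embed_sequences(m, ds)
    expect_equal(dim(emb$x),
                 c(length(ds), 27, if (dir == "bi") 12 else 6))
    expect_true(all(abs(emb$x) < 1))
    emb2 <- embed_sequences(m, ds)
    expect_identical(emb$x, emb2$x)
  }
})
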