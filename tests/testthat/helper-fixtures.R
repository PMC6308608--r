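# Shared small fixtures, built in code at test time.

# tiny, fast generator config: full design but cheap to synthesize
tiny_config <- function(seed = 1) generator_config(seed = seed)

# style pair with all randomness off (deterministic template evaluation)
silent_styles <- function(labels = label_spec()) {
  st <- list(subject_style(labels$subjects[1], 0, 0, 0),
             subject_style(labels$subjects[2], 0, 0, 0))
  names(st) <- labels$subjects[1:2]
  st
}

# small random linear-Gaussian state-space instance (list of matrices)
random_lgssm <- function(latent = 2, obs = 3, seed = 1) {
  set.seed(seed)
  th <- stats::runif(1, 0.1, 0.6)
  A <- stats::runif(1, 0.7, 0.97) *
    matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)[1:latent, 1:latent]
  list(A = A,
       Q = diag(stats::runif(latent, 0.02, 0.2), latent),
       C = matrix(stats::rnorm(obs * latent), obs, latent),
       R = diag(stats::runif(obs, 0.05, 0.3), obs),
       m0 = stats::rnorm(latent), P0 = diag(0.3, latent))
}

simulate_lgssm <- function(mod, n_seq, n_time, seed = 1) {
  set.seed(seed)
  L <- length(mod$m0); D <- nrow(mod$C)
  zs <- array(0, c(n_seq, n_time, L)); xs <- array(0, c(n_seq, n_time, D))
  cQ <- chol(mod$Q); cP0 <- chol(mod$P0)
  for (i in seq_len(n_seq)) {
    z <- mod$m0 + drop(t(cP0) %*% stats::rnorm(L))
    for (t in seq_len(n_time)) {
      zs[i, t, ] <- z
      xs[i, t, ] <- drop(mod$C %*% z) + sqrt(diag(mod$R)) * stats::rnorm(D)
      z <- drop(mod$A %*% z) + drop(t(cQ) %*% stats::rnorm(L))
    }
  }
  list(z = zs, x = xs)
}

# labelled random latent trajectory for coaching tests
random_traj <- function(n_time, latent = 2, subject = "coach",
                        skill = "forehand_drive", split = "train") {
  structure(matrix(stats::rnorm(n_time * latent), n_time, latent),
            class = c("latent_trajectory", "matrix"),
            labels = list(subject = subject, skill = skill, split = split))
}
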