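scalar_cell <- function(wx = 1, wh = 0, b = 0) {
  g1 <- function(v) matrix(v, 1, 1)
  lstm_cell_params(W_x = list(f = g1(wx), i = g1(wx), o = g1(wx), g = g1(wx)),
                   W_h = list(f = g1(wh), i = g1(wh), o = g1(wh), g = g1(wh)),
                   b = list(f = b, i = b, o = b, g = b))
}

test_that("zero-parameter cell sits at its fixed point", {
  cell <- scalar_cell(0, 0, 0)
  out <- lstm_cell_step(cell, 1, list(h = 0, c = 0))
  expect_equal(drop(out$f), 0.5)
  expect_equal(drop(out$i), 0.5)
  expect_equal(drop(out$o), 0.5)
  expect_equal(drop(out$g), 0)
  expect_equal(drop(out$c), 0)
  expect_equal(drop(out$h), 0)
})

test_that("a saturated forget gate preserves the internal state", {
  g1 <- function(v) matrix(v, 1, 1)
  cell <- lstm_cell_params(
    W_x = list(f = g1(0), i = g1(0), o = g1(0), g = g1(0)),
    W_h = list(f = g1(0), i = g1(0), o = g1(0), g = g1(0)),
    b = list(f = 20, i = 0, o = 0, g = 0))
  v <- 0.7
  out <- lstm_cell_step(cell, 0, list(h = 0, c = v))
  # c_t = sigma(20) * v + g * i with g = tanh(0) = 0
  expect_lt(abs(drop(out$c) - plogis(20) * v), 1e-8 * abs(v))
  expect_lt(abs(drop(out$c) - v), 1e-7)
})

test_that("the scalar hand-computed step reproduces the gate equations", {
  cell <- scalar_cell(1, 0, 0)
  out <- lstm_cell_step(cell, 1, list(h = 0, c = 0))
  s1 <- 1 / (1 + exp(-1))
  expect_equal(drop(out$f), s1, tolerance = 1e-10)
  expect_equal(drop(out$i), s1, tolerance = 1e-10)
  expect_equal(drop(out$o), s1, tolerance = 1e-10)
  expect_equal(drop(out$g), tanh(1), tolerance = 1e-10)
  expect_equal(drop(out$c), s1 * tanh(1), tolerance = 1e-8)
  expect_equal(drop(out$h), s1 * tanh(s1 * tanh(1)), tolerance = 1e-8)
  # frozen values from direct evaluation of the equations:
  # c = sigma(1) * tanh(1), h = sigma(1) * tanh(sigma(1) * tanh(1))
  expect_equal(drop(out$c), 0.5567699, tolerance = 1e-6)
  expect_equal(drop(out$h), 0.3696064, tolerance = 1e-6)
})

test_that("gate ranges hold on random inputs", {
  set.seed(8)
  arch <- strokecoach:::arch_spec("uni", hidden = 6, input = 4, n_classes = 3)
  params <- strokecoach:::init_classifier_params(arch, 8)
  cell <- list(W = params[["l1.f.W"]], b = params[["l1.f.b"]])
  for (k in 1:20) {
    out <- lstm_cell_step(cell, matrix(rnorm(4 * 3, sd = 3), 3),
                          list(h = matrix(rnorm(18), 3),
                               c = matrix(rnorm(18), 3)))
    for (gate in c("f", "i", "o"))
      expect_true(all(out[[gate]] > 0 & out[[gate]] < 1))
    expect_true(all(abs(out$g) < 1))
    expect_true(all(abs(out$h) < 1))
  }
})

test_that("shape mismatches are rejected", {
  cell <- scalar_cell()
  expect_error(lstm_cell_step(cell, c(1, 2)), "shape mismatch")
})

test_that("softmax scores are normalized and bi degenerates to uni", {
  set.seed(9)
  h <- 5; C <- 3; K <- 4; Tn <- 7
  archU <- strokecoach:::arch_spec("uni", h, C, K)
  pu <- strokecoach:::init_classifier_params(archU, 3)
  archB <- strokecoach:::arch_spec("bi", h, C, K)
  pb <- strokecoach:::init_classifier_params(archB, 4)
  # embed the uni weights in the bi model, zero the backward path
  pb[["l1.f.W"]] <- pu[["l1.f.W"]]; pb[["l1.f.b"]] <- pu[["l1.f.b"]]
  pb[["l1.b.W"]][] <- 0; pb[["l1.b.b"]][] <- 0
  pb[["l2.b.W"]][] <- 0; pb[["l2.b.b"]][] <- 0
  # level-2 forward consumes [h_f1, h_b1]; rows for h_b1 must be zero
  W2 <- matrix(0, 2 * h + h, 4 * h)
  W2[1:h, ] <- pu[["l2.f.W"]][1:h, ]
  W2[2 * h + 1:h, ] <- pu[["l2.f.W"]][h + 1:h, ]
  pb[["l2.f.W"]] <- W2; pb[["l2.f.b"]] <- pu[["l2.f.b"]]
  Wout <- matrix(0, 2 * h, K)
  Wout[1:h, ] <- pu[["out.W"]]
  pb[["out.W"]] <- Wout; pb[["out.b"]] <- pu[["out.b"]]
  # NB: with a zeroed backward path its cells still output h = o*tanh(c) = 0
  X <- array(rnorm(2 * Tn * C), c(2, Tn, C))
  fu <- strokecoach:::stack_forward(pu, archU, X)
  fb <- strokecoach:::stack_forward(pb, archB, X)
  expect_equal(fb$probs, fu$probs, tolerance = 1e-12)
  expect_equal(rowSums(fb$probs), c(1, 1), tolerance = 1e-12)
})

test_that("swapping forward/backward cells mirrors time reversal", {
  set.seed(10)
  arch <- strokecoach:::arch_spec("bi", 4, 3, 3)
  p <- strokecoach:::init_classifier_params(arch, 5)
  h <- 4
  pswap <- p
  pswap[["l1.f.W"]] <- p[["l1.b.W"]]; pswap[["l1.f.b"]] <- p[["l1.b.b"]]
  pswap[["l1.b.W"]] <- p[["l1.f.W"]]; pswap[["l1.b.b"]] <- p[["l1.f.b"]]
  # level-2 inputs are [h_f1, h_b1]; after the swap those blocks arrive in
  # the opposite order, so the input rows of the level-2 weights swap too
  swap_in <- function(W) rbind(W[h + 1:h, ], W[1:h, ], W[2 * h + 1:h, ])
  pswap[["l2.f.W"]] <- swap_in(p[["l2.b.W"]])
  pswap[["l2.f.b"]] <- p[["l2.b.b"]]
  pswap[["l2.b.W"]] <- swap_in(p[["l2.f.W"]])
  pswap[["l2.b.b"]] <- p[["l2.f.b"]]
  pswap[["out.W"]] <- rbind(p[["out.W"]][h + 1:h, ], p[["out.W"]][1:h, ])
  Tn <- 6
  X <- array(rnorm(1 * Tn * 3), c(1, Tn, 3))
  Xrev <- X[, Tn:1, , drop = FALSE]
  f1 <- strokecoach:::stack_forward(p, arch, X)
  f2 <- strokecoach:::stack_forward(pswap, arch, Xrev)
  expect_equal(f1$probs, f2$probs, tolerance = 1e-12)
})

test_that("backpropagation matches finite differences", {
  set.seed(11)
  for (dir in c("uni", "bi")) {
    arch <- strokecoach:::arch_spec(dir, 3, 2, 3)
    params <- strokecoach:::init_classifier_params(arch, 12)
    N <- 3; Tn <- 5
    X <- array(rnorm(N * Tn * 2), c(N, Tn, 2))
    Y <- diag(3)[sample(1:3, N, replace = TRUE), ]
    l2 <- 1e-3
    fwd <- strokecoach:::stack_forward(params, arch, X, keep_cache = TRUE)
    gr <- strokecoach:::stack_backward(params, arch, fwd, Y, l2)
    costfun <- function(p) {
      f <- strokecoach:::stack_forward(p, arch, X)
      strokecoach:::cross_entropy(f$probs, Y) + strokecoach:::l2_penalty(p, l2)
    }
    h <- 1e-6
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
        fd <- (costfun(p1) - costfun(p2)) / (2 * h)
        expect_lt(abs(fd - gr[[nm]][i]) /
                    max(1e-6, abs(fd) + abs(gr[[nm]][i])), 1e-4)
      }
    }
  }
})

test_that("training is seed-reproducible and its cost decreases on a separable toy", {
  set.seed(13)
  # two far-apart template classes, tiny noise: linearly separable
  mk <- function(mu, subject, skill, n, split) {
    lapply(seq_len(n), function(i)
      stroke_sequence(matrix(mu + rnorm(10 * 6, sd = 0.05), 10, 6),
                      subject, skill, i, split))
  }
  labs <- label_spec()
  strokes <- c(mk(0, "coach", "forehand_stroke", 6, "train"),
               mk(3, "beginner", "backhand_drive", 6, "train"),
               mk(0, "coach", "forehand_stroke", 2, "test"),
               mk(3, "beginner", "backhand_drive", 2, "test"))
  ds <- stroke_dataset(strokes, labs)
  m1 <- lstm_classifier(ds, "uni", hidden = 6, epochs = 40, batch_size = 4,
                        learning_rate = 5e-3, seed = 21, eval_every = 5)
  m2 <- lstm_classifier(ds, "uni", hidden = 6, epochs = 40, batch_size = 4,
                        learning_rate = 5e-3, seed = 21, eval_every = 5)
  expect_identical(m1$params, m2$params)  # bitwise determinism
  costs <- m1$history$train_cost
  # non-increasing trend, allowing small transient upticks
  upticks <- diff(costs) > 0.05 * costs[-length(costs)]
  expect_lte(mean(upticks), 0.05)
  expect_lt(costs[length(costs)], costs[1])
  expect_equal(m1$history$test_acc[nrow(m1$history)], 1)
})

test_that("evaluation metrics follow the confusion-matrix definitions", {
  labs <- label_spec()
  truth <- rep(1:10, each = 3)
  # perfect
  r <- eval_report(truth, truth, labs)
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_f1, 1)
  expect_equal(sum(r$confusion), 30)
  expect_equal(unname(diag(r$confusion)), rep(3, 10))
  # 28 of 30 correct -> 93.3%
  pred <- truth; pred[c(1, 4)] <- c(2, 5)
  r <- eval_report(truth, pred, labs)
  expect_equal(round(100 * r$accuracy, 1), 93.3)
  # all-one-class collapse on a balanced set
  r <- suppressWarnings(eval_report(truth, rep(1, 30), labs))
  expect_equal(round(100 * r$accuracy, 1), 10.0)
  expect_equal(r$macro_recall, 0.1)
  # absent class warns
  expect_warning(eval_report(rep(1:9, each = 3), rep(1:9, each = 3), labs),
                 "absent")
})

test_that("parameter counts match brute-force enumeration", {
  for (dir in c("uni", "bi")) for (h in c(5, 11)) {
    arch <- strokecoach:::arch_spec(dir, h, 18, 10)
    params <- strokecoach:::init_classifier_params(arch, 1)
    expect_equal(param_count_formula(dir, h, 18, 10),
                 sum(vapply(params, length, 0L)))
  }
})
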