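test_that("trajectory distance is a symmetric metric with the translation property", {
  set.seed(22)
  a <- random_traj(10)
  expect_equal(trajectory_distance(a, a), 0)
  delta <- c(0.7, -0.4)
  b <- unclass(a) + matrix(delta, 10, 2, byrow = TRUE)
  expect_equal(trajectory_distance(a, b), sqrt(sum(delta^2)),
               tolerance = 1e-12)
  # symmetry and triangle inequality over random triples
  for (k in 1:100) {
    x <- matrix(rnorm(16), 8); y <- matrix(rnorm(16), 8)
    z <- matrix(rnorm(16), 8)
    dxy <- trajectory_distance(x, y)
    expect_equal(dxy, trajectory_distance(y, x), tolerance = 1e-12)
    expect_lte(dxy, trajectory_distance(x, z) + trajectory_distance(z, y)
               + 1e-12)
  }
  expect_error(trajectory_distance(matrix(0, 5, 2), matrix(0, 5, 3)),
               "latent dimensions")
})

test_that("distance handles unequal lengths by resampling and dtw is available", {
  a <- matrix(seq(0, 1, length.out = 11), ncol = 1)
  b <- matrix(seq(0, 1, length.out = 21), ncol = 1)
  # same underlying line sampled at different rates -> distance ~ 0
  expect_lt(trajectory_distance(a, b), 1e-10)
  expect_lt(trajectory_distance(a, b, method = "dtw"), 0.05)
  expect_equal(trajectory_distance(a, a, method = "dtw"), 0)
})

test_that("the reference library stores per-cell summaries as pointwise means", {
  trs <- c(lapply(1:3, function(i) random_traj(9, subject = "coach",
                                               skill = "forehand_cut")),
           lapply(1:2, function(i) random_traj(9, subject = "beginner",
                                               skill = "backhand_drive")))
  lib <- build_reference_library(trs)
  expect_setequal(names(lib$cells),
                  c("coach:forehand_cut", "beginner:backhand_drive"))
  manual <- (unclass(trs[[1]]) + unclass(trs[[2]]) + unclass(trs[[3]])) / 3
  expect_equal(lib$cells[["coach:forehand_cut"]]$summary, manual,
               tolerance = 1e-12)
})

test_that("holdout validation passes trivially when test equals training", {
  set.seed(23)
  trs <- unlist(lapply(c("coach", "beginner"), function(su)
    lapply(label_spec()$skills, function(sk) {
      base <- random_traj(8, subject = su, skill = sk)
      base
    })), recursive = FALSE)
  lib <- build_reference_library(trs)
  tests <- lapply(trs, function(tr) {
    attr(tr, "labels")$split <- "test"
    tr
  })
  v <- holdout_validate(lib, tests)
  expect_true(all(v$pass))
  expect_true(all(v$own_distance == 0))
  expect_true(all(v$margin > 0))
})

test_that("shuffled labels destroy holdout validation down to chance", {
  set.seed(24)
  # ten well-separated cells with cluster structure
  centers <- expand.grid(subject = c("coach", "beginner"),
                         skill = label_spec()$skills,
                         stringsAsFactors = FALSE)
  mk_cell <- function(i, n, split) lapply(seq_len(n), function(j) {
    z <- matrix(rnorm(8 * 2, sd = 0.1), 8, 2) + 3 * i
    structure(z, class = c("latent_trajectory", "matrix"),
              labels = list(subject = centers$subject[i],
                            skill = centers$skill[i], split = split))
  })
  train <- unlist(lapply(1:10, mk_cell, n = 4, split = "train"),
                  recursive = FALSE)
  test <- unlist(lapply(1:10, mk_cell, n = 2, split = "test"),
                 recursive = FALSE)
  lib <- build_reference_library(train)
  v <- holdout_validate(lib, test)
  expect_true(all(v$pass))  # structured labels validate perfectly
  # permutation null: shuffling test labels leaves ~1/10 passing
  rates <- replicate(100, {
    shuffled <- test[sample(length(test))]
    for (i in seq_along(shuffled))
      attr(shuffled[[i]], "labels")[c("subject", "skill")] <-
      list(centers$subject[(i - 1) %/% 2 + 1], centers$skill[(i - 1) %/% 2 + 1])
    mean(holdout_validate(lib, shuffled)$pass)
  })
  expect_lt(mean(rates), 0.35)
  expect_gt(mean(rates), 0.01)
})

test_that("empty cells are skipped with a warning", {
  trs <- lapply(1:3, function(i) random_traj(6, subject = "coach",
                                             skill = "forehand_cut"))
  lib <- build_reference_library(trs)
  tests <- list(random_traj(6, subject = "coach", skill = "forehand_cut",
                            split = "test"))
  mixed_lib <- build_reference_library(
    c(trs, list(random_traj(6, subject = "beginner",
                            skill = "backhand_short"))))
  expect_warning(v <- holdout_validate(mixed_lib, tests), "skipped")
  expect_equal(nrow(v), 1)
})

test_that("coach_compare runs the full chain and reports consistent rankings", {
  set.seed(25)
  ds <- synth_dataset(generator_config(seed = 5, reps_per_cell = 3,
                                       train_reps = 2))
  clf <- lstm_classifier(ds, "uni", hidden = 6, epochs = 5, batch_size = 20,
                         seed = 4)
  emb <- embed_sequences(clf, dataset_split(ds, "train"))
  dmf <- dmm(emb, latent_dim = 2, epochs = 30, seed = 4, trans_width = 4,
             emis_width = 4, q_width = 4, summary_dim = 4)
  lib <- build_reference_library(infer_trajectories(dmf, emb))
  bundle <- coaching_bundle(clf, dmf, lib)
  rep <- coach_compare(ds$strokes[[1]], bundle)
  expect_s3_class(rep, "similarity_report")
  expect_equal(nrow(rep$distances), 10)
  expect_true(all(rep$distances$distance >= 0))
  expect_true(!is.unsorted(rep$distances$distance))
  expect_equal(rep$closest, rep$distances$cell[1])
  # consistency: the training stroke's distance to its own cell equals a
  # direct recomputation
  own <- paste(ds$strokes[[1]]$subject, ds$strokes[[1]]$skill, sep = ":")
  direct <- trajectory_distance(rep$trajectory, lib$cells[[own]]$summary)
  expect_equal(rep$distances$distance[rep$distances$cell == own], direct,
               tolerance = 1e-12)
  # empty library errors
  empty <- bundle; empty$library$cells <- list()
  expect_error(coach_compare(ds$strokes[[1]], empty), "empty")
  # mismatched bundle errors
  clf2 <- lstm_classifier(ds, "bi", hidden = 4, epochs = 2, batch_size = 20,
                          seed = 5)
  expect_error(coaching_bundle(clf2, dmf, lib), "mismatch")
})

test_that("trajectory rendering writes one deterministic panel per cell", {
  set.seed(26)
  trs <- unlist(lapply(c("coach", "beginner"), function(su)
    lapply(label_spec()$skills, function(sk)
      list(random_traj(6, subject = su, skill = sk, split = "train"),
           random_traj(6, subject = su, skill = sk, split = "test")))),
    recursive = FALSE)
  trs <- unlist(trs, recursive = FALSE)
  dir1 <- file.path(tempdir(), "figs1")
  files <- render_trajectories(trs, dir1)
  expect_length(files, 10)  # 2 subjects x 5 skills
  expect_true(all(file.exists(files)))
  dir2 <- file.path(tempdir(), "figs2")
  files2 <- render_trajectories(trs, dir2)
  expect_identical(unname(tools::md5sum(files)), unname(tools::md5sum(files2)))
  unlink(c(dir1, dir2), recursive = TRUE)
})
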