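# Frozen settings for the default synthetic benchmark, shared by the test
# suite and the acceptance script so both evaluate the same conditions.

#' Training configuration for the default classification benchmark
#'
#' The settings used when the stacked LSTM classifiers are benchmarked on
#' the default synthetic dataset: full-batch Adam (the training set is
#' only 70 strokes), moderate L2, and a hidden size of 16.
#'
#' @return named list of \code{\link{lstm_classifier}} arguments.
#' @export
classifier_benchmark_config <- function() {
  list(hidden = 16, epochs = 1000, batch_size = 70, learning_rate = 5e-3,
       l2 = 1e-3, eval_every = 500)
}

#' Retraining settings used after pruning in the benchmark
#'
#' Gentle fine-tuning: a lower learning rate than the dense training so
#' the sparse network stays near the dense optimum instead of
#' re-converging to a different (slightly worse-generalizing) solution.
#'
#' @return named list of \code{\link{retrain_pruned}} arguments.
#' @export
pruning_retrain_config <- function() {
  list(epochs = 1000, learning_rate = 1e-3)
}

#' Deep-Markov-model epochs used in the coaching benchmark
#' @return integer epoch count.
#' @export
dmm_benchmark_epochs <- function() 400

#' Fresh evaluation set for a benchmark generator seed
#'
#' Generates additional strokes from the same skill templates and subject
#' styles as the benchmark dataset for \code{seed}, but from disjoint
#' random substreams, all labelled test. The design's own holdout has only
#' 30 strokes (3.3 accuracy points per stroke), so architecture
#' comparisons use this larger set to escape that granularity.
#'
#' @param seed the benchmark generator seed being enlarged.
#' @param reps_per_cell strokes per (subject, skill) cell (default 20,
#'   giving 200 strokes).
#' @return a \code{\link{stroke_dataset}} of test strokes.
#' @export
benchmark_eval_set <- function(seed, reps_per_cell = 20) {
  gcfg <- generator_config(seed = seed)
  templates <- build_templates(gcfg)
  ecfg <- generator_config(seed = seed + 20000,
                           reps_per_cell = reps_per_cell, train_reps = 0)
  synth_dataset(ecfg, templates = templates)
}

#' Closed-loop improvement harness
#'
#' Emulates a practice loop: a beginner whose execution style is stepped
#' from the default beginner jitter toward the coach's values. At each
#' step a fresh batch of beginner strokes of one skill is generated,
#' embedded through the frozen classifier, mapped to latent trajectories,
#' and its median distance to the coach's reference trajectory for that
#' skill recorded. Improving style should move the trajectories toward
#' the coach's.
#'
#' @param classifier frozen \code{\link{lstm_classifier}}.
#' @param dmm_fit trained \code{\link{dmm}} on that classifier's
#'   embeddings.
#' @param library \code{\link{build_reference_library}} result holding
#'   the coach references.
#' @param skill which skill is practiced (default "forehand_drive").
#' @param n_steps number of interpolation steps from beginner to coach
#'   style (default 6).
#' @param n_strokes strokes generated per step (default 10).
#' @param seed integer seed.
#' @return data.frame with columns step, mix (0 = beginner default,
#'   1 = coach), and median_distance to the coach reference.
#' @export
closed_loop_distances <- function(classifier, dmm_fit, library,
                                  skill = "forehand_drive", n_steps = 6,
                                  n_strokes = 10, seed = 1L) {
  cfg <- generator_config(seed = seed)
  templates <- build_templates(cfg)
  ki <- match(skill, cfg$labels$skills)
  if (is.na(ki)) stop("unknown skill: ", skill, call. = FALSE)
  styles <- default_styles(cfg$labels)
  coach_ref <- library$cells[[paste0("coach:", skill)]]
  if (is.null(coach_ref))
    stop("library has no coach reference for ", skill, call. = FALSE)
  mixes <- seq(0, 1, length.out = n_steps)
  out <- lapply(seq_along(mixes), function(si) {
    w <- mixes[si]
    lerp <- function(field)
      (1 - w) * styles$beginner[[field]] + w * styles$coach[[field]]
    st <- subject_style("beginner", lerp("amplitude_jitter_sd"),
                        lerp("timing_jitter_sd"), lerp("noise_sd"),
                        amplitude_scale = lerp("amplitude_scale"),
                        timing_offset_s = lerp("timing_offset_s"),
                        timing_decay_rate = lerp("timing_decay_rate"))
    # common random numbers: stroke r reuses the same substream at every
    # step, so the style interpolation is a paired comparison
    dists <- vapply(seq_len(n_strokes), function(r) {
      s <- synth_stroke(templates[[ki]], st, cfg,
                        seed = derive_seed(seed, 5000 + r),
                        rep_index = r, split = "test")
      emb <- embed_sequences(classifier,
                             stroke_dataset(list(s), cfg$labels))
      traj <- infer_trajectory(dmm_fit,
                               matrix(emb$x[1, , ], dim(emb$x)[2]))
      trajectory_distance(traj, coach_ref$summary)
    }, 0)
    data.frame(step = si, mix = w, median_distance = stats::median(dists))
  })
  do.call(rbind, out)
}
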