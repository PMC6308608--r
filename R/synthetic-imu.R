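# Synthetic IMU stroke generator.
#
# Emulates the factorial data-collection design: 2 subjects (coach, beginner)
# x 5 skills x 10 repetitions, each stroke a 5.4 s window sampled at 5 Hz
# (27 time points) on 18 channels (3 modules x {tri-axial accelerometer,
# tri-axial gyroscope}). Skills are smooth per-channel motion templates;
# subject style adds amplitude/timing jitter and sensor noise.

#' Generator configuration for the synthetic stroke benchmark
#'
#' @param n_skills number of skills (default 5).
#' @param reps_per_cell repetitions per (subject, skill) cell (default 10).
#' @param train_reps how many of the repetitions go to the training split
#'   (default 7; the remainder are test).
#' @param n_modules number of IMU modules (default 3; each has 6 channels).
#' @param sample_rate_hz sampling frequency (default 5 Hz).
#' @param duration_s stroke window length (default 5.4 s, giving 27 samples).
#' @param seed master integer seed; every stroke derives its own substream.
#' @param separation minimum pairwise mean-squared channel difference
#'   required between skill templates.
#' @param labels a \code{\link{label_spec}}; its skill count must match.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n_skills = 5, reps_per_cell = 10, train_reps = 7,
                             n_modules = 3, sample_rate_hz = 5,
                             duration_s = 5.4, seed = 1L, separation = 0.1,
                             labels = label_spec()) {
  stopifnot(n_skills == length(labels$skills),
            reps_per_cell >= 0, train_reps >= 0, train_reps <= reps_per_cell,
            n_modules >= 1, sample_rate_hz > 0, duration_s > 0,
            separation >= 0)
  cfg <- list(n_subjects = length(labels$subjects), n_skills = n_skills,
              reps_per_cell = reps_per_cell, train_reps = train_reps,
              n_modules = n_modules, n_channels = n_modules * 6L,
              sample_rate_hz = sample_rate_hz, duration_s = duration_s,
              samples_per_stroke = round(duration_s * sample_rate_hz),
              seed = as.integer(seed), separation = separation,
              labels = labels)
  structure(cfg, class = "generator_config")
}

#' Per-subject execution style
#'
#' Encodes how a subject deviates from the ideal skill template: a
#' systematic component (damped amplitude, habitual timing lag) and a
#' stochastic component (per-channel amplitude jitter, per-module timing
#' jitter, execution tremor). The coach default is the ideal execution;
#' the beginner default is damped, lagged and noticeably more variable.
#'
#' @param subject_id subject name.
#' @param amplitude_jitter_sd relative (unitless) SD of the per-channel
#'   amplitude factor.
#' @param timing_jitter_sd SD in seconds of the per-module timing shifts.
#' @param noise_sd SD of additive i.i.d. Gaussian noise (sensor units),
#'   modelling execution tremor plus sensor noise.
#' @param amplitude_scale systematic multiplicative amplitude factor
#'   (1 = full range of motion; beginners typically < 1).
#' @param timing_offset_s systematic timing lag in seconds added to every
#'   module's shift.
#' @param timing_decay_rate recovery rate (per second) of the timing
#'   shifts over the stroke: the effective shift at time t is
#'   shift * exp(-rate * t). 0 keeps the shift constant; a positive rate
#'   models a player who starts late or early and catches up, so the
#'   timing cue concentrates at the stroke onset.
#' @return An object of class \code{subject_style}.
#' @export
subject_style <- function(subject_id, amplitude_jitter_sd = 0.05,
                          timing_jitter_sd = 0.05, noise_sd = 0.05,
                          amplitude_scale = 1, timing_offset_s = 0,
                          timing_decay_rate = 0) {
  stopifnot(amplitude_jitter_sd >= 0, timing_jitter_sd >= 0, noise_sd >= 0,
            amplitude_scale > 0, timing_decay_rate >= 0)
  structure(list(subject_id = subject_id,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 timing_jitter_sd = timing_jitter_sd,
                 noise_sd = noise_sd,
                 amplitude_scale = amplitude_scale,
                 timing_offset_s = timing_offset_s,
                 timing_decay_rate = timing_decay_rate),
            class = "subject_style")
}

#' Default coach/beginner style pair
#'
#' The beginner executes the same skill templates as the coach but with a
#' damped amplitude (80\% range of motion), a habitual 0.15 s lag, and
#' larger amplitude/timing jitter and tremor. Classification difficulty
#' is tunable: shrinking the systematic gap and the jitter ratios toward
#' the coach values makes the subjects progressively harder to tell
#' apart.
#'
#' @param labels a \code{\link{label_spec}} naming the two subjects.
#' @return named list of two \code{\link{subject_style}} objects.
#' @export
default_styles <- function(labels = label_spec()) {
  st <- list(
    subject_style(labels$subjects[1], amplitude_jitter_sd = 0.05,
                  timing_jitter_sd = 0.05, noise_sd = 0.05,
                  amplitude_scale = 1, timing_offset_s = 0),
    subject_style(labels$subjects[2], amplitude_jitter_sd = 0.30,
                  timing_jitter_sd = 0.25, noise_sd = 0.15,
                  amplitude_scale = 0.8, timing_offset_s = 0.15,
                  timing_decay_rate = 1))
  names(st) <- labels$subjects[1:2]
  st
}

#' Build skill motion templates
#'
#' Each skill template is, per channel, a sum of \code{n_bumps} Gaussian
#' bumps with random amplitudes, centers and widths — smooth, stroke-like
#' curves. Templates are redrawn (up to \code{max_tries} times) until every
#' pair of skills differs by at least \code{config$separation} in mean
#' squared channel value at the sample times.
#'
#' @param config a \code{\link{generator_config}}.
#' @param seed integer seed (defaults to the config seed).
#' @param n_bumps Gaussian bumps per channel (default 3).
#' @param max_tries redraw attempts before giving up.
#' @return list of \code{motion_template} objects, one per skill.
#' @export
build_templates <- function(config, seed = config$seed, n_bumps = 3,
                            max_tries = 20) {
  C <- config$n_channels
  times <- stroke_times(config$duration_s, config$sample_rate_hz)
  set.seed(as.integer(derive_seed(seed, 1)))
  for (try in seq_len(max_tries)) {
    tmpl <- lapply(seq_len(config$n_skills), function(s) {
      structure(list(
        skill_id = config$labels$skills[s],
        amplitudes = matrix(stats::runif(C * n_bumps, -2, 2), C, n_bumps),
        centers = matrix(stats::runif(C * n_bumps, 0.1 * config$duration_s,
                                      0.9 * config$duration_s), C, n_bumps),
        widths = matrix(stats::runif(C * n_bumps, 0.3, 0.9), C, n_bumps)),
        class = "motion_template")
    })
    seps <- utils::combn(config$n_skills, 2, function(ij) {
      a <- eval_template(tmpl[[ij[1]]], times)
      b <- eval_template(tmpl[[ij[2]]], times)
      mean((a - b)^2)
    })
    if (min(seps) >= config$separation) return(tmpl)
  }
  stop("could not draw skill templates with pairwise separation >= ",
       config$separation, " in ", max_tries, " tries; lower `separation`",
       call. = FALSE)
}

#' Evaluate a motion template at given times
#'
#' @param template a \code{motion_template}.
#' @param times numeric vector of times in seconds.
#' @return length(times) x n_channels matrix.
#' @export
eval_template <- function(template, times) {
  C <- nrow(template$amplitudes)
  K <- ncol(template$amplitudes)
  out <- matrix(0, length(times), C)
  for (k in seq_len(K)) {
    # outer over time x channel for bump k
    d <- outer(times, template$centers[, k], "-")
    out <- out + exp(-d^2 / (2 * rep(template$widths[, k]^2, each = length(times)))) *
      rep(template$amplitudes[, k], each = length(times))
  }
  out
}

#' Synthesize one stroke from a template and a subject style
#'
#' The stroke is the template evaluated at jittered sample times — one
#' independent timing shift per sensor module, so sloppy execution
#' desynchronizes the hand, wrist and arm modules — scaled per channel by
#' (1 + amplitude jitter), plus i.i.d. Gaussian sensor noise. With all
#' style SDs zero the output is exactly the noiseless template evaluation.
#'
#' @param template a \code{motion_template}.
#' @param style a \code{\link{subject_style}}.
#' @param config a \code{\link{generator_config}}.
#' @param seed integer seed for this stroke's substream.
#' @param rep_index,split stroke bookkeeping labels.
#' @return a \code{\link{stroke_sequence}}.
#' @export
synth_stroke <- function(template, style, config, seed,
                         rep_index = 1L, split = "train") {
  set.seed(as.integer(seed))
  times <- stroke_times(config$duration_s, config$sample_rate_hz)
  off <- style$timing_offset_s %||% 0
  if (style$timing_jitter_sd > 0 || off != 0) {
    shifts <- off + if (style$timing_jitter_sd > 0)
      stats::rnorm(config$n_modules, 0, style$timing_jitter_sd)
    else numeric(config$n_modules)
    decay <- exp(-(style$timing_decay_rate %||% 0) * times)
    x <- matrix(0, length(times), config$n_channels)
    for (m in seq_len(config$n_modules)) {
      cols <- (m - 1) * 6 + 1:6
      x[, cols] <- eval_template(template, times - shifts[m] * decay)[, cols]
    }
  } else x <- eval_template(template, times)
  C <- ncol(x)
  scale <- style$amplitude_scale %||% 1
  if (style$amplitude_jitter_sd > 0) {
    amp <- scale * (1 + stats::rnorm(C, 0, style$amplitude_jitter_sd))
    x <- sweep(x, 2, amp, "*")
  } else if (scale != 1) x <- x * scale
  if (style$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, style$noise_sd), nrow(x), C)
  stroke_sequence(x, style$subject_id, template$skill_id, rep_index,
                  split, config$sample_rate_hz)
}

#' Generate a full balanced synthetic stroke dataset
#'
#' Produces \code{reps_per_cell} strokes per (subject, skill) cell, the
#' first \code{train_reps} labelled train and the rest test. Per-stroke
#' random substreams are derived from the master seed by counter, so the
#' dataset is reproducible stroke-by-stroke.
#'
#' @param config a \code{\link{generator_config}}.
#' @param styles named list of \code{\link{subject_style}}s (default
#'   \code{\link{default_styles}}).
#' @param templates optional pre-built template list.
#' @return a \code{\link{stroke_dataset}}.
#' @export
synth_dataset <- function(config = generator_config(),
                          styles = default_styles(config$labels),
                          templates = build_templates(config)) {
  # force the defaults now: template construction uses the RNG, and it must
  # not run lazily inside a stroke's dedicated substream
  force(styles)
  force(templates)
  labels <- config$labels
  strokes <- list()
  counter <- 1L
  for (si in seq_along(labels$subjects)) {
    for (ki in seq_len(config$n_skills)) {
      for (r in seq_len(config$reps_per_cell)) {
        split <- if (r <= config$train_reps) "train" else "test"
        seed_k <- derive_seed(config$seed, 1000 + counter)
        strokes[[counter]] <- synth_stroke(
          templates[[ki]], styles[[labels$subjects[si]]], config,
          seed = seed_k, rep_index = r, split = split)
        counter <- counter + 1L
      }
    }
  }
  stroke_dataset(strokes, labels)
}

#' Nearest-template skill assignment (generator oracle)
#'
#' Assigns each stroke to the skill whose noiseless template evaluation is
#' closest in mean squared error. As style jitter and noise go to zero this
#' assignment is exact, which pins down the generator's separability.
#'
#' @param ds a \code{stroke_dataset}.
#' @param templates template list from \code{\link{build_templates}}.
#' @param config the matching \code{\link{generator_config}}.
#' @return character vector of assigned skill names.
#' @export
nearest_template_skill <- function(ds, templates, config) {
  times <- stroke_times(config$duration_s, config$sample_rate_hz)
  ref <- lapply(templates, eval_template, times = times)
  vapply(ds$strokes, function(s) {
    mse <- vapply(ref, function(r) mean((s$samples - r)^2), 0)
    templates[[which.min(mse)]]$skill_id
  }, "")
}
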