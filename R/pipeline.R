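# End-to-end pipeline: generate/load data, train and optionally prune the
# classifier, fit the augmented state-space network, validate latent
# trajectories by holdout, render coach plots and run the comparison
# harness. Every stage's output is serialized under the output directory
# and listed, with md5 hashes, in a manifest.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "strokecoach-run",
    generator = list(separation = 0.1, reps_per_cell = 10L, train_reps = 7L,
                     beginner_amplitude_jitter_sd = 0.30,
                     beginner_timing_jitter_sd = 0.25,
                     beginner_noise_sd = 0.15,
                     beginner_amplitude_scale = 0.8,
                     beginner_timing_offset_s = 0.15,
                     beginner_timing_decay_rate = 1,
                     coach_amplitude_jitter_sd = 0.05,
                     coach_timing_jitter_sd = 0.05,
                     coach_noise_sd = 0.05),
    classifier = list(direction = "bi", hidden = 38L, epochs = 300L,
                      batch_size = 10L, learning_rate = 1e-3, l2 = 1e-4),
    pruning = list(sparsity = 0, retrain_epochs = 100L),
    dmm = list(latent_dim = 2L, epochs = 500L, learning_rate = 1e-2,
               trans_width = 32L, emis_width = 32L, q_width = 32L,
               summary_dim = 32L),
    coaching = list(method = "euclidean", min_pass_cells = 9L,
                    max_rounds = 3L))
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown config key: ", paste0(path, nm), call. = FALSE)
    if (is.list(defaults[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults and overrides with the supplied named
#' values; unknown keys are rejected. The configuration is a plain nested
#' list, round-trippable through YAML.
#'
#' @param ... named overrides, e.g. \code{seed = 3},
#'   \code{classifier = list(direction = "uni")}.
#' @param file optional YAML file of overrides applied before \code{...}.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file))
  over <- list(...)
  if (length(over)) cfg <- merge_config(cfg, over)
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Serialize model parameters to a JSON named-array container
#'
#' Writes every parameter array with its dimensions plus an architecture
#' manifest, at full double precision, as plain text.
#'
#' @param model an \code{\link{lstm_classifier}} or \code{\link{dmm}}.
#' @param path output .json file.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(model, path) {
  arrays <- lapply(model$params, function(p)
    list(dim = if (is.null(dim(p))) length(p) else dim(p),
         data = as.vector(p)))
  obj <- list(class = class(model)[1], arch = model$arch, arrays = arrays)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a parameter container written by \code{\link{write_params}}
#'
#' @param path .json file path.
#' @return list with \code{class}, \code{arch} and the named parameter
#'   list \code{params}.
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$arrays, function(a) {
    d <- unlist(a$dim)
    if (length(d) > 1) array(a$data, d) else as.numeric(a$data)
  })
  list(class = obj$class, arch = obj$arch, params = params)
}

#' Run the full coaching pipeline from one configuration
#'
#' Executes, in order: synthetic data generation with train/test split;
#' classifier training (and optional magnitude pruning with retraining);
#' embedding and deep-Markov-model training; holdout validation of the
#' latent trajectories (repeated with a fresh seed up to
#' \code{coaching$max_rounds} times if unsatisfactory); reference
#' trajectory plots; and the per-test-stroke comparison harness. All
#' artifacts are written under \code{config$out_dir} with a hash
#' manifest.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param verbose print stage progress.
#' @return list with \code{status} ("ok" or "unsatisfactory"),
#'   \code{rounds} used, the fitted objects, the validation table and the
#'   manifest path.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  artifacts <- character(0)
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  # steps 1-2: training and test data
  gcfg <- generator_config(seed = config$seed,
                           separation = config$generator$separation,
                           reps_per_cell = config$generator$reps_per_cell,
                           train_reps = config$generator$train_reps)
  styles <- list(
    subject_style("coach", config$generator$coach_amplitude_jitter_sd,
                  config$generator$coach_timing_jitter_sd,
                  config$generator$coach_noise_sd),
    subject_style("beginner", config$generator$beginner_amplitude_jitter_sd,
                  config$generator$beginner_timing_jitter_sd,
                  config$generator$beginner_noise_sd,
                  amplitude_scale = config$generator$beginner_amplitude_scale,
                  timing_offset_s = config$generator$beginner_timing_offset_s,
                  timing_decay_rate =
                    config$generator$beginner_timing_decay_rate))
  names(styles) <- gcfg$labels$subjects
  say("generating strokes")
  ds <- synth_dataset(gcfg, styles)
  write_stroke_table(ds, keep(file.path(out, "strokes.csv")))

  round_status <- "unsatisfactory"
  rounds_used <- 0L
  clf <- dmf <- lib <- validation <- NULL
  max_rounds <- max(1L, config$coaching$max_rounds)
  for (round in seq_len(max_rounds)) {
    rounds_used <- round
    seed_r <- as.integer(derive_seed(config$seed, 100 + round))
    # step 3: train (and optionally prune) the classifier, then fix it
    say("training classifier (round ", round, ")")
    clf <- lstm_classifier(ds, direction = config$classifier$direction,
                           hidden = config$classifier$hidden,
                           epochs = config$classifier$epochs,
                           batch_size = config$classifier$batch_size,
                           learning_rate = config$classifier$learning_rate,
                           l2 = config$classifier$l2, seed = seed_r)
    if (config$pruning$sparsity > 0) {
      say("pruning to sparsity ", config$pruning$sparsity)
      mask <- compute_mask(clf, config$pruning$sparsity)
      clf <- retrain_pruned(clf, mask, ds,
                            epochs = config$pruning$retrain_epochs)
    }
    # step 4: augmented network on the frozen classifier's embeddings
    say("training state-space model (round ", round, ")")
    emb_train <- embed_sequences(clf, dataset_split(ds, "train"))
    dmf <- dmm(emb_train, latent_dim = config$dmm$latent_dim,
               epochs = config$dmm$epochs,
               learning_rate = config$dmm$learning_rate,
               trans_width = config$dmm$trans_width,
               emis_width = config$dmm$emis_width,
               q_width = config$dmm$q_width,
               summary_dim = config$dmm$summary_dim, seed = seed_r)
    train_trajs <- infer_trajectories(dmf, emb_train)
    lib <- build_reference_library(train_trajs)
    # step 5: holdout validation
    emb_test <- embed_sequences(clf, dataset_split(ds, "test"))
    test_trajs <- infer_trajectories(dmf, emb_test)
    validation <- holdout_validate(lib, test_trajs,
                                   method = config$coaching$method)
    if (sum(validation$pass) >= config$coaching$min_pass_cells) {
      round_status <- "ok"
      break
    }
    say("validation unsatisfactory (", sum(validation$pass), " cells pass)")
  }
  write_params(clf, keep(file.path(out, "classifier.json")))
  utils::write.csv(clf$history, keep(file.path(out, "learning_curves.csv")),
                   row.names = FALSE)
  write_params(dmf, keep(file.path(out, "dmm.json")))
  utils::write.csv(validation, keep(file.path(out, "validation.csv")),
                   row.names = FALSE)
  # step 6: plots of the latent trajectories
  emb_all <- embed_sequences(clf, ds)
  all_trajs <- infer_trajectories(dmf, emb_all)
  figs <- render_trajectories(all_trajs, file.path(out, "figures"))
  artifacts <- c(artifacts, figs)
  write_trajectory_table(all_trajs,
                         keep(file.path(out, "latent_trajectories.csv")))
  # step 7: comparison harness over test strokes
  bundle <- coaching_bundle(clf, dmf, lib)
  te <- dataset_split(ds, "test")
  reports <- lapply(te$strokes, coach_compare, bundle = bundle,
                    method = config$coaching$method)
  comp <- do.call(rbind, lapply(reports, function(r)
    data.frame(subject = r$query$subject, skill = r$query$skill,
               rep = r$query$rep, closest = r$closest,
               classifier_subject = r$classifier_prediction$subject[1],
               classifier_skill = r$classifier_prediction$skill[1],
               stringsAsFactors = FALSE)))
  utils::write.csv(comp, keep(file.path(out, "comparisons.csv")),
                   row.names = FALSE)
  # manifest
  hashes <- tools::md5sum(artifacts)
  manifest <- data.frame(file = basename(names(hashes)), md5 = unname(hashes),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  list(status = round_status, rounds = rounds_used, dataset = ds,
       classifier = clf, dmm = dmf, library = lib,
       validation = validation, comparisons = comp, bundle = bundle,
       manifest = file.path(out, "manifest.csv"))
}

#' Write latent trajectories as delimited text
#'
#' Long format: stroke metadata plus one row per time step with the
#' latent coordinates.
#'
#' @param trajectories list of labelled \code{latent_trajectory} objects.
#' @param path output csv path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_table <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    lb <- attr(tr, "labels")
    z <- unclass(tr); attr(z, "labels") <- NULL
    df <- data.frame(subject = lb$subject %||% NA,
                     skill = lb$skill %||% NA, rep = lb$rep %||% NA,
                     split = lb$split %||% NA, t_index = seq_len(nrow(z)))
    cbind(df, stats::setNames(as.data.frame(z),
                              paste0("z", seq_len(ncol(z)))))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
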