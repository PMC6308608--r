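# Coaching utilities: reference latent-trajectory libraries, holdout
# validation, and similarity scoring of a new stroke against the library.

#' Linearly resample a trajectory onto a common time grid
#'
#' @param z T x L matrix.
#' @param n_out number of output time points.
#' @return n_out x L matrix interpolated on normalized time [0, 1].
#' @export
resample_trajectory <- function(z, n_out) {
  z <- as.matrix(z)
  if (nrow(z) == n_out) return(z)
  if (nrow(z) == 1) return(matrix(z, n_out, ncol(z), byrow = TRUE))
  t_in <- seq(0, 1, length.out = nrow(z))
  t_out <- seq(0, 1, length.out = n_out)
  apply(z, 2, function(col) stats::approx(t_in, col, xout = t_out)$y)
}

#' Distance between two latent trajectories
#'
#' Default metric: mean pointwise Euclidean distance after linear
#' resampling to a common length (the longer of the two). Symmetric,
#' non-negative, zero iff the trajectories coincide after resampling, and
#' for equal-length trajectories a true metric. The "dtw" option uses a
#' dynamic-time-warping alignment (path-length-normalized) for elastic
#' comparison.
#'
#' @param a,b latent trajectories (T x L matrices) with equal latent_dim.
#' @param method "euclidean" (default) or "dtw".
#' @return scalar distance.
#' @export
trajectory_distance <- function(a, b, method = c("euclidean", "dtw")) {
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("latent dimensions differ: ", ncol(a), " vs ", ncol(b),
         call. = FALSE)
  if (method == "euclidean") {
    n <- max(nrow(a), nrow(b))
    ra <- resample_trajectory(a, n)
    rb <- resample_trajectory(b, n)
    return(mean(sqrt(rowSums((ra - rb)^2))))
  }
  # dynamic time warping with Euclidean local cost, normalized by path length
  na <- nrow(a); nb <- nrow(b)
  local <- outer(seq_len(na), seq_len(nb),
                 Vectorize(function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))))
  D <- matrix(Inf, na + 1, nb + 1); D[1, 1] <- 0
  steps <- matrix(0L, na + 1, nb + 1)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    prev <- rbind(c(i, j + 1), c(i + 1, j), c(i, j))
    opts <- D[prev]
    k <- which.min(opts)
    D[i + 1, j + 1] <- local[i, j] + opts[k]
    steps[i + 1, j + 1] <- steps[prev][k] + 1L
  }
  D[na + 1, nb + 1] / steps[na + 1, nb + 1]
}

traj_cell <- function(tr) {
  lb <- attr(tr, "labels")
  paste(lb$subject, lb$skill, sep = ":")
}

#' Build a reference library of latent trajectories
#'
#' Groups training trajectories by (subject, skill) cell and stores, per
#' cell, the individual trajectories plus a summary trajectory (their
#' pointwise mean after resampling to a common length).
#'
#' @param trajectories list of labelled \code{latent_trajectory} objects
#'   (e.g. from \code{\link{infer_trajectories}} on training embeddings).
#' @return An object of class \code{reference_library}.
#' @export
build_reference_library <- function(trajectories) {
  if (!length(trajectories)) stop("no trajectories supplied", call. = FALSE)
  cells <- vapply(trajectories, traj_cell, "")
  n_common <- max(vapply(trajectories, nrow, 0L))
  lib <- lapply(split(trajectories, factor(cells, levels = unique(cells))),
                function(trs) {
                  rs <- lapply(trs, resample_trajectory, n_out = n_common)
                  list(trajectories = trs,
                       summary = Reduce(`+`, rs) / length(rs))
                })
  structure(list(cells = lib, n_common = n_common,
                 latent_dim = ncol(trajectories[[1]])),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat("<reference_library> ", length(x$cells), " (subject, skill) cells, ",
      "latent dim ", x$latent_dim, "\n", sep = "")
  for (nm in names(x$cells))
    cat("  ", nm, ": ", length(x$cells[[nm]]$trajectories),
        " trajectories\n", sep = "")
  invisible(x)
}

#' Holdout validation of latent trajectories against a reference library
#'
#' For each (subject, skill) cell with test trajectories: computes the
#' mean distance from the cell's test trajectories to its own summary
#' trajectory and to every other cell's summary. A cell passes when its
#' own-cell distance is smaller than the distance to every other cell;
#' the margin is (best other-cell distance) - (own-cell distance).
#'
#' @param library a \code{\link{build_reference_library}} result.
#' @param test_trajectories list of labelled test
#'   \code{latent_trajectory} objects.
#' @param method distance method passed to
#'   \code{\link{trajectory_distance}}.
#' @return data.frame with one row per cell: own_distance,
#'   best_other_distance, margin, pass.
#' @export
holdout_validate <- function(library, test_trajectories,
                             method = "euclidean") {
  cells <- vapply(test_trajectories, traj_cell, "")
  out <- list()
  for (nm in names(library$cells)) {
    idx <- which(cells == nm)
    if (!length(idx)) {
      warning("no test trajectories for cell ", nm, "; skipped",
              call. = FALSE)
      next
    }
    dists <- vapply(names(library$cells), function(other) {
      mean(vapply(test_trajectories[idx], trajectory_distance,
                  0, b = library$cells[[other]]$summary, method = method))
    }, 0)
    own <- dists[[nm]]
    other <- dists[names(dists) != nm]
    out[[nm]] <- data.frame(cell = nm, own_distance = own,
                            best_other_distance = min(other),
                            margin = min(other) - own,
                            pass = own < min(other),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bundle the fitted pipeline stages for coaching queries
#'
#' @param classifier a trained \code{\link{lstm_classifier}} (carries its
#'   scaler).
#' @param dmm_fit a \code{\link{dmm}} trained on this classifier's
#'   embeddings.
#' @param library a \code{\link{build_reference_library}} result.
#' @return An object of class \code{coaching_bundle}.
#' @export
coaching_bundle <- function(classifier, dmm_fit, library) {
  if (dmm_fit$arch$obs_dim != classifier$arch$feature)
    stop("bundle mismatch: DMM expects observation dim ",
         dmm_fit$arch$obs_dim, " but the classifier produces ",
         classifier$arch$feature, call. = FALSE)
  if (library$latent_dim != dmm_fit$arch$latent_dim)
    stop("bundle mismatch: library latent dim ", library$latent_dim,
         " vs DMM latent dim ", dmm_fit$arch$latent_dim, call. = FALSE)
  structure(list(classifier = classifier, dmm = dmm_fit, library = library),
            class = "coaching_bundle")
}

#' Compare a query stroke against the reference library
#'
#' Runs the full evaluative-feedback chain on one stroke: min-max scale,
#' embed through the frozen classifier, infer the posterior-mean latent
#' trajectory, and rank the distances to every (subject, skill) summary
#' trajectory. The classifier's own prediction is reported alongside as a
#' cross-check.
#'
#' @param stroke a \code{\link{stroke_sequence}}.
#' @param bundle a \code{\link{coaching_bundle}}.
#' @param method distance method for \code{\link{trajectory_distance}}.
#' @return A \code{similarity_report}: ranked data.frame of distances,
#'   the closest (subject, skill) identity, the query labels, and the
#'   classifier prediction.
#' @export
coach_compare <- function(stroke, bundle, method = "euclidean") {
  if (!length(bundle$library$cells)) stop("empty reference library",
                                          call. = FALSE)
  ds <- stroke_dataset(list(stroke), bundle$classifier$labels)
  emb <- embed_sequences(bundle$classifier, ds)
  traj <- infer_trajectory(bundle$dmm, matrix(emb$x[1, , ], dim(emb$x)[2]),
                           labels = list(subject = stroke$subject,
                                         skill = stroke$skill))
  dists <- vapply(bundle$library$cells, function(cell)
    trajectory_distance(traj, cell$summary, method = method), 0)
  ranked <- data.frame(cell = names(dists), distance = unname(dists),
                       stringsAsFactors = FALSE)
  ranked <- ranked[order(ranked$distance), ]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  pred <- predict(bundle$classifier, ds, type = "label")
  structure(list(query = list(subject = stroke$subject, skill = stroke$skill,
                              rep = stroke$rep_index, split = stroke$split),
                 distances = ranked, closest = ranked$cell[1],
                 classifier_prediction = pred, trajectory = traj),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report> query: ", x$query$subject, ":", x$query$skill,
      " (rep ", x$query$rep, ")\n", sep = "")
  cat("  closest reference: ", x$closest, "\n", sep = "")
  cat("  classifier predicts: ", x$classifier_prediction$subject[1], ":",
      x$classifier_prediction$skill[1], "\n", sep = "")
  print(utils::head(x$distances, 5))
  invisible(x)
}

#' Render latent trajectories, one panel per (subject, skill) cell
#'
#' Training trajectories are drawn as dashed blue lines, test
#' trajectories as solid red lines — the holdout-overlay view. One file
#' per cell with deterministic names
#' \code{latent_<subject>_<skill>.png}.
#'
#' @param trajectories list of labelled \code{latent_trajectory} objects
#'   (train and/or test).
#' @param dir output directory (created if needed).
#' @param width,height device size in pixels.
#' @return character vector of written file paths, invisibly.
#' @export
render_trajectories <- function(trajectories, dir, width = 480,
                                height = 480) {
  if (!length(trajectories)) stop("no trajectories to render", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- vapply(trajectories, traj_cell, "")
  files <- character(0)
  for (nm in unique(cells)) {
    trs <- trajectories[cells == nm]
    splits <- vapply(trs, function(tr) attr(tr, "labels")$split %||% "train",
                     "")
    fname <- file.path(dir, paste0("latent_", gsub(":", "_", nm), ".png"))
    grDevices::png(fname, width = width, height = height)
    xs <- unlist(lapply(trs, function(z) z[, 1]))
    ys <- unlist(lapply(trs, function(z) if (ncol(z) > 1) z[, 2] else
      seq_len(nrow(z))))
    graphics::plot(NA, xlim = range(xs), ylim = range(ys),
                   xlab = "latent 1",
                   ylab = if (ncol(trs[[1]]) > 1) "latent 2" else "time",
                   main = nm)
    for (i in seq_along(trs)) {
      z <- trs[[i]]
      y <- if (ncol(z) > 1) z[, 2] else seq_len(nrow(z))
      if (splits[i] == "test")
        graphics::lines(z[, 1], y, col = "red", lty = 1)
      else graphics::lines(z[, 1], y, col = "blue", lty = 2)
    }
    grDevices::dev.off()
    files <- c(files, fname)
  }
  invisible(files)
}
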