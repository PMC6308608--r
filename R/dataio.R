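# Stroke-table text interchange and min-max scaling.
#
# On-disk schema: optional '#' comment lines, then a header row
#   subject,skill,rep,split,t_index,<channel names...>
# followed by one row per time sample per stroke. UTF-8, '.' decimal.

default_channel_names <- function(n_modules = 3) {
  unlist(lapply(seq_len(n_modules), function(m)
    paste0("m", m, "_", rep(c("acc", "gyr"), each = 3), "_", c("x", "y", "z"))))
}

#' Write a stroke dataset as a delimited stroke table
#'
#' One row per time sample, with metadata columns subject, skill, rep,
#' split, t_index followed by one column per channel. Values are written
#' with 15 significant digits so a round trip preserves at least 12.
#'
#' @param ds a \code{\link{stroke_dataset}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stroke_table <- function(ds, path) {
  n <- length(ds)
  C <- if (n) ncol(ds$strokes[[1]]$samples) else 18L
  chn <- if (C == 18) default_channel_names(3) else paste0("ch", seq_len(C))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  rate <- if (n) ds$strokes[[1]]$sample_rate_hz else 5
  writeLines(c("# stroke table",
               paste0("# sample_rate_hz=", format(rate, digits = 15)),
               paste(c("subject", "skill", "rep", "split", "t_index", chn),
                     collapse = ",")), con)
  for (s in ds$strokes) {
    Tn <- nrow(s$samples)
    vals <- apply(s$samples, 1, function(r)
      paste(sprintf("%.15g", r), collapse = ","))
    writeLines(paste(s$subject, s$skill, s$rep_index, s$split,
                     seq_len(Tn), vals, sep = ","), con)
  }
  invisible(path)
}

#' Read a stroke table written by \code{\link{write_stroke_table}}
#'
#' Parse errors (missing header, ragged strokes, unknown split labels,
#' non-numeric samples) are reported with the offending stroke or line.
#'
#' @param path file path.
#' @param labels \code{\link{label_spec}} used to validate subject/skill
#'   names; pass NULL to build one from the names found in the file.
#' @return a \code{\link{stroke_dataset}}.
#' @export
read_stroke_table <- function(path, labels = label_spec()) {
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  lines <- raw[keep]
  rate <- 5
  m <- grep("^# sample_rate_hz=", raw, value = TRUE)
  if (length(m)) rate <- as.numeric(sub("^# sample_rate_hz=", "", m[1]))
  if (!length(lines)) stop("empty stroke table: ", path, call. = FALSE)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  need <- c("subject", "skill", "rep", "split", "t_index")
  if (length(hdr) < 6 || !identical(hdr[1:5], need))
    stop("malformed stroke-table header at line ", lineno[1],
         ": expected columns ", paste(need, collapse = ","),
         ",<channels...>", call. = FALSE)
  C <- length(hdr) - 5L
  body <- lines[-1]
  if (!length(body)) stop("stroke table has a header but no data rows",
                          call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(hdr)))
    stop("ragged row at line ", lineno[-1][which(nf != length(hdr))[1]],
         ": expected ", length(hdr), " fields, found ",
         nf[which(nf != length(hdr))[1]], call. = FALSE)
  meta <- t(vapply(parts, function(p) p[1:4], character(4)))
  tidx <- as.integer(vapply(parts, `[[`, "", 5))
  vals <- matrix(as.numeric(unlist(lapply(parts, `[`, -(1:5)))),
                 ncol = C, byrow = TRUE)
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    stop("non-numeric sample value at line ", lineno[-1][bad], call. = FALSE)
  }
  bad_split <- !(meta[, 4] %in% c("train", "test"))
  if (any(bad_split))
    stop("unknown split label '", meta[which(bad_split)[1], 4],
         "' at line ", lineno[-1][which(bad_split)[1]], call. = FALSE)
  key <- paste(meta[, 1], meta[, 2], meta[, 3], sep = "\r")
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  Ts <- lengths(groups)
  if (length(unique(Ts)) > 1) {
    ref <- as.integer(names(sort(table(Ts), decreasing = TRUE))[1])
    off <- which(Ts != ref)[1]
    km <- strsplit(names(groups)[off], "\r", fixed = TRUE)[[1]]
    stop("ragged stroke (subject=", km[1], ", skill=", km[2], ", rep=",
         km[3], "): has ", Ts[off], " rows where others have ", ref,
         call. = FALSE)
  }
  strokes <- lapply(groups, function(idx) {
    idx <- idx[order(tidx[idx])]
    if (!identical(tidx[idx], seq_along(idx)))
      stop("non-contiguous t_index for stroke (subject=", meta[idx[1], 1],
           ", skill=", meta[idx[1], 2], ", rep=", meta[idx[1], 3], ")",
           call. = FALSE)
    stroke_sequence(vals[idx, , drop = FALSE], meta[idx[1], 1],
                    meta[idx[1], 2], as.integer(meta[idx[1], 3]),
                    meta[idx[1], 4], rate)
  })
  names(strokes) <- NULL
  if (is.null(labels))
    labels <- label_spec(unique(meta[, 1]), unique(meta[, 2]))
  stroke_dataset(strokes, labels)
}

#' Fit a per-channel min-max scaler on the training split
#'
#' Only strokes with \code{split == "train"} contribute, so no information
#' leaks from the test split into preprocessing.
#'
#' @param ds a \code{\link{stroke_dataset}} containing a training split.
#' @return An object of class \code{scaler_params} with per-channel min/max.
#' @export
fit_scaler <- function(ds) {
  tr <- dataset_split(ds, "train")
  if (!length(tr)) stop("no training strokes to fit the scaler on")
  x <- dataset_array(tr)
  mins <- apply(x, 3, min)
  maxs <- apply(x, 3, max)
  structure(list(min = mins, max = maxs), class = "scaler_params")
}

#' Apply a fitted min-max scaler to every stroke of a dataset
#'
#' Scaled value = (x - min_c) / (max_c - min_c) per channel c. Training
#' values land in [0, 1]; test values may fall outside (no clipping).
#' Constant channels (max == min) map to 0 with a warning.
#'
#' @param sp a \code{scaler_params} from \code{\link{fit_scaler}}.
#' @param ds a \code{\link{stroke_dataset}}.
#' @return A scaled \code{stroke_dataset}.
#' @export
apply_scaler <- function(sp, ds) {
  rng <- sp$max - sp$min
  flat <- which(rng == 0)
  if (length(flat)) {
    warning("constant channel(s) ", paste(flat, collapse = ", "),
            " mapped to 0 (max == min in training data)", call. = FALSE)
    rng[flat] <- 1
  }
  strokes <- lapply(ds$strokes, function(s) {
    x <- sweep(sweep(s$samples, 2, sp$min, "-"), 2, rng, "/")
    if (length(flat)) x[, flat] <- 0
    s$samples <- x
    s
  })
  stroke_dataset(strokes, ds$labels)
}

scale_array <- function(sp, x) {
  rng <- sp$max - sp$min
  rng[rng == 0] <- 1
  for (c in seq_len(dim(x)[3]))
    x[, , c] <- (x[, , c] - sp$min[c]) / rng[c]
  x
}
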