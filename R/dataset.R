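#' Label specification for the two-subject, five-skill design
#'
#' Defines the subject and skill vocabularies and the joint 10-class label
#' used by the classifiers: joint index = subject_index * n_skills +
#' skill_index (0-based), so labels 1..5 are the first subject's skills and
#' 6..10 the second subject's.
#'
#' @param subjects character vector of subject names (default coach, beginner).
#' @param skills character vector of skill names (default the five
#'   table-tennis strokes: forehand stroke/drive/cut, backhand drive/short).
#' @return An object of class \code{label_spec}.
#' @export
label_spec <- function(subjects = c("coach", "beginner"),
                       skills = c("forehand_stroke", "forehand_drive",
                                  "forehand_cut", "backhand_drive",
                                  "backhand_short")) {
  stopifnot(length(subjects) >= 1, length(skills) >= 1,
            !anyDuplicated(subjects), !anyDuplicated(skills))
  structure(list(subjects = subjects, skills = skills,
                 n_classes = length(subjects) * length(skills)),
            class = "label_spec")
}

#' Joint class index of a (subject, skill) pair
#'
#' @param spec a \code{\link{label_spec}}.
#' @param subject,skill names present in the spec.
#' @return 1-based joint class index.
#' @export
joint_label <- function(spec, subject, skill) {
  si <- match(subject, spec$subjects)
  ki <- match(skill, spec$skills)
  if (anyNA(si)) stop("unknown subject: ", paste(subject[is.na(si)], collapse = ", "))
  if (anyNA(ki)) stop("unknown skill: ", paste(skill[is.na(ki)], collapse = ", "))
  (si - 1L) * length(spec$skills) + ki
}

#' Recover (subject, skill) names from a joint class index
#'
#' Inverse of \code{\link{joint_label}} by integer division / modulo.
#'
#' @param spec a \code{\link{label_spec}}.
#' @param index 1-based joint class index.
#' @return data.frame with columns subject, skill.
#' @export
split_label <- function(spec, index) {
  stopifnot(all(index >= 1), all(index <= spec$n_classes))
  k <- length(spec$skills)
  data.frame(subject = spec$subjects[(index - 1L) %/% k + 1L],
             skill = spec$skills[(index - 1L) %% k + 1L],
             stringsAsFactors = FALSE)
}

#' One-hot encode a (subject, skill) label
#'
#' @inheritParams joint_label
#' @return numeric vector of length \code{n_classes} with a single 1.
#' @export
one_hot <- function(spec, subject, skill) {
  v <- numeric(spec$n_classes)
  v[joint_label(spec, subject, skill)] <- 1
  v
}

#' Construct a single stroke sequence
#'
#' One executed stroke: a T x C matrix of sensor samples (rows = time,
#' columns = channels) plus its design labels.
#'
#' @param samples numeric T x C matrix, all finite.
#' @param subject,skill label names.
#' @param rep_index integer repetition number within the (subject, skill) cell.
#' @param split "train" or "test".
#' @param sample_rate_hz sampling frequency in Hz.
#' @return An object of class \code{stroke_sequence}.
#' @export
stroke_sequence <- function(samples, subject, skill, rep_index,
                            split = c("train", "test"), sample_rate_hz = 5) {
  split <- match.arg(split)
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stop("a stroke needs at least one time sample")
  stopifnot_finite(samples, "stroke samples")
  structure(list(samples = samples, subject = subject, skill = skill,
                 rep_index = as.integer(rep_index), split = split,
                 sample_rate_hz = sample_rate_hz),
            class = "stroke_sequence")
}

#' Bundle stroke sequences into a dataset
#'
#' @param strokes list of \code{\link{stroke_sequence}} objects sharing
#'   dimensions T and C.
#' @param labels a \code{\link{label_spec}} covering all labels present.
#' @return An object of class \code{stroke_dataset}.
#' @export
stroke_dataset <- function(strokes, labels = label_spec()) {
  if (length(strokes)) {
    dims <- vapply(strokes, function(s) dim(s$samples), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all strokes must share the same T and number of channels")
    subs <- vapply(strokes, `[[`, "", "subject")
    sks <- vapply(strokes, `[[`, "", "skill")
    joint_label(labels, subs, sks)  # validates names
  }
  structure(list(strokes = strokes, labels = labels), class = "stroke_dataset")
}

#' @export
length.stroke_dataset <- function(x) length(x$strokes)

#' Design metadata of a stroke dataset
#'
#' @param ds a \code{stroke_dataset}.
#' @return data.frame with one row per stroke: subject, skill, rep, split,
#'   and the joint class index.
#' @export
dataset_meta <- function(ds) {
  if (!length(ds$strokes))
    return(data.frame(subject = character(), skill = character(),
                      rep = integer(), split = character(), class = integer(),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    subject = vapply(ds$strokes, `[[`, "", "subject"),
    skill = vapply(ds$strokes, `[[`, "", "skill"),
    rep = vapply(ds$strokes, `[[`, 0L, "rep_index"),
    split = vapply(ds$strokes, `[[`, "", "split"),
    stringsAsFactors = FALSE)
  df$class <- joint_label(ds$labels, df$subject, df$skill)
  df
}

#' Stack a stroke dataset into an N x T x C array
#'
#' @param ds a \code{stroke_dataset}.
#' @return numeric array with dimensions (strokes, time, channels).
#' @export
dataset_array <- function(ds) {
  n <- length(ds$strokes)
  if (!n) return(array(0, c(0, 0, 0)))
  d <- dim(ds$strokes[[1]]$samples)
  out <- array(0, c(n, d[1], d[2]))
  for (i in seq_len(n)) out[i, , ] <- ds$strokes[[i]]$samples
  out
}

#' Subset a stroke dataset by split
#'
#' @param ds a \code{stroke_dataset}.
#' @param split "train" or "test".
#' @return A \code{stroke_dataset} with only the requested split.
#' @export
dataset_split <- function(ds, split = c("train", "test")) {
  split <- match.arg(split)
  keep <- vapply(ds$strokes, function(s) s$split == split, TRUE)
  stroke_dataset(ds$strokes[keep], ds$labels)
}

#' Count single-axis training sequences
#'
#' Each stroke contributes one sequence per sensor channel (axis), so the
#' count is (number of training strokes) x (number of channels). Under the
#' default design (2 subjects x 5 skills x 7 training reps x 18 channels)
#' this is 1260.
#'
#' @param ds a \code{stroke_dataset}.
#' @return integer count.
#' @export
count_training_sequences <- function(ds) {
  tr <- dataset_split(ds, "train")
  if (!length(tr)) return(0L)
  length(tr) * ncol(tr$strokes[[1]]$samples)
}

#' @export
print.stroke_dataset <- function(x, ...) {
  meta <- dataset_meta(x)
  cat("<stroke_dataset> ", length(x), " strokes", sep = "")
  if (length(x)) {
    d <- dim(x$strokes[[1]]$samples)
    cat(", ", d[1], " samples x ", d[2], " channels each\n", sep = "")
    cat("  subjects: ", paste(x$labels$subjects, collapse = ", "), "\n", sep = "")
    cat("  skills:   ", paste(x$labels$skills, collapse = ", "), "\n", sep = "")
    cat("  split:    ", sum(meta$split == "train"), " train / ",
        sum(meta$split == "test"), " test\n", sep = "")
  } else cat("\n")
  invisible(x)
}
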