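#' Construct a trial set
#'
#' A trial set holds single-cycle angle waveforms in long format: one row per
#' time sample, labelled by subject, condition, side and trial index, with one
#' numeric column per angle. It is the common input of the feature-matrix and
#' symmetry stages.
#'
#' @param data Data frame with columns `subject`, `condition`, `side`
#'   (`"L"`/`"R"`), `trial`, `time_index`, and one column per angle.
#' @param angles Character vector of angle column names (default the nine
#'   canonical sagittal angles, see [angle_names()]).
#' @param meta Optional list of metadata: `sex` (named character vector per
#'   subject, `"F"`/`"M"`), `speed` (data frame `subject`, `condition`, `side`,
#'   `trial`, `speed` in m/s), `seed`, `source`.
#'
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, angles = angle_names(), meta = list()) {
  stopifnot(is.data.frame(data))
  req <- c("subject", "condition", "side", "trial", "time_index", angles)
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L) {
    stop("trial data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(data$side %in% c("L", "R"))) {
    stop("`side` must be \"L\" or \"R\"", call. = FALSE)
  }
  vals <- as.matrix(data[angles])
  if (!all(is.finite(vals))) {
    bad <- which(rowSums(!is.finite(vals)) > 0L)
    stop("non-finite angle values in data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  key <- interaction(data$subject, data$condition, data$side, data$trial,
                     data$time_index, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, condition, side, trial, time_index) rows",
         call. = FALSE)
  }
  data$subject <- as.character(data$subject)
  data$condition <- as.character(data$condition)
  data$trial <- as.integer(data$trial)
  data$time_index <- as.integer(data$time_index)
  structure(list(data = data[c(req)], angles = angles, meta = meta),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  k <- trial_keys(x)
  cat("<trial_set> ", nrow(k), " trials, ",
      length(unique(k$subject)), " subjects, ",
      length(unique(k$condition)), " conditions, ",
      length(x$angles), " angles\n", sep = "")
  invisible(x)
}

#' Unique trial keys of a trial set
#'
#' @param trials A `trial_set`.
#' @return Data frame with one row per trial: `subject`, `condition`, `side`,
#'   `trial`, in order of first appearance.
#' @export
trial_keys <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  d <- trials$data
  unique(d[c("subject", "condition", "side", "trial")])
}

#' Number of trials in a trial set
#'
#' @param trials A `trial_set`.
#' @return Integer count of distinct (subject, condition, side, trial) keys.
#' @export
n_trials <- function(trials) nrow(trial_keys(trials))

#' Write a trial set to delimited text
#'
#' Long CSV layout: `subject, condition, side, trial, time_index` followed by
#' the nine angle columns; optional `sex` and `speed` columns are appended
#' when the metadata is present.
#'
#' @param trials A `trial_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "trial_set"))
  d <- trials$data
  if (!is.null(trials$meta$sex)) {
    d$sex <- unname(trials$meta$sex[d$subject])
  }
  if (!is.null(trials$meta$speed)) {
    sp <- trials$meta$speed
    key_d <- paste(d$subject, d$condition, d$side, d$trial, sep = "\r")
    key_s <- paste(sp$subject, sp$condition, sp$side, sp$trial, sep = "\r")
    d$speed <- sp$speed[match(key_d, key_s)]
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial set from delimited text
#'
#' Reads the long CSV layout written by [write_trials()]. All nine canonical
#' angle columns must be present; rows with non-finite angle values or
#' duplicate (subject, condition, side, trial, time_index) keys are reported
#' with their file line numbers. `sex` and `speed` columns, if present, are
#' lifted into the trial-set metadata.
#'
#' @param path CSV file path.
#' @param angles Expected angle columns (default the canonical nine).
#' @return A `trial_set`.
#' @export
read_trials <- function(path, angles = angle_names()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "condition", "side", "trial", "time_index", angles)
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols) > 0L) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(d[angles])
  bad <- which(rowSums(!is.finite(vals)) > 0L)
  if (length(bad) > 0L) {
    stop("malformed angle values in ", path, " at line(s) ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "),
         call. = FALSE)  # +1 for the header line
  }
  key <- paste(d$subject, d$condition, d$side, d$trial, d$time_index,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate trial key in ", path, " at line(s) ",
         paste(utils::head(dup + 1L, 10L), collapse = ", "), call. = FALSE)
  }
  meta <- list(source = path)
  if ("sex" %in% names(d)) {
    sx <- unique(d[c("subject", "sex")])
    meta$sex <- stats::setNames(as.character(sx$sex), sx$subject)
  }
  if ("speed" %in% names(d)) {
    sp <- unique(d[c("subject", "condition", "side", "trial", "speed")])
    meta$speed <- sp[stats::complete.cases(sp), , drop = FALSE]
    rownames(meta$speed) <- NULL
  }
  trial_set(d[req], angles = angles, meta = meta)
}
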