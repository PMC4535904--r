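#' Time-normalize a waveform to a fixed number of cycle points
#'
#' Resamples one sampled waveform onto `n_time` equidistant points spanning
#' the closed interval 0-100% of the cycle. Interpolation is cubic spline
#' (piecewise polynomial) for series of four or more samples, with a linear
#' fallback for shorter series; endpoints are preserved exactly.
#'
#' @param waveform Numeric vector, length >= 2, finite.
#' @param n_time Number of output samples (default 201).
#' @return Numeric vector of length `n_time`.
#' @export
time_normalize <- function(waveform, n_time = 201L) {
  if (!is.numeric(n_time) || length(n_time) != 1L || n_time < 2L) {
    stop("`n_time` must be a single integer >= 2", call. = FALSE)
  }
  n_time <- as.integer(n_time)
  n <- length(waveform)
  if (n < 2L) stop("waveform must have length >= 2", call. = FALSE)
  if (!all(is.finite(waveform))) {
    stop("waveform contains non-finite values", call. = FALSE)
  }
  if (n == n_time) return(as.numeric(waveform))
  x <- seq(0, 1, length.out = n)
  xout <- seq(0, 1, length.out = n_time)
  if (n >= 4L) {
    stats::spline(x, waveform, xout = xout, method = "fmm")$y
  } else {
    stats::approx(x, waveform, xout = xout)$y
  }
}

#' Assemble the trials-by-variables feature matrix
#'
#' One row per trial; columns are the nine angle blocks in the fixed order
#' foot, ankle, knee, hip, pelvis, spine, thorax, neck, head, each block
#' being the `n_time` time-normalized samples of that angle (9 x 201 = 1809
#' columns by default).
#'
#' @param trials A [trial_set()].
#' @param n_time Samples per cycle after time normalization (default 201).
#' @return A numeric matrix of class `feature_matrix` with attributes
#'   `row_labels` (data frame `subject`, `condition`, `side`, `trial`),
#'   `angles` and `n_time`.
#' @export
build_feature_matrix <- function(trials, n_time = 201L) {
  stopifnot(inherits(trials, "trial_set"))
  angles <- trials$angles
  keys <- trial_keys(trials)
  d <- trials$data
  key_all <- paste(d$subject, d$condition, d$side, d$trial, sep = "\r")
  key_u <- paste(keys$subject, keys$condition, keys$side, keys$trial,
                 sep = "\r")
  idx_by_trial <- split(seq_len(nrow(d)), factor(key_all, levels = key_u))
  m <- matrix(NA_real_, nrow(keys), length(angles) * n_time)
  for (i in seq_along(idx_by_trial)) {
    rows <- idx_by_trial[[i]]
    rows <- rows[order(d$time_index[rows])]
    m[i, ] <- unlist(lapply(angles, function(a) {
      time_normalize(d[[a]][rows], n_time)
    }), use.names = FALSE)
  }
  colnames(m) <- paste(rep(angles, each = n_time),
                       sprintf("t%03d", seq_len(n_time) - 1L), sep = "_")
  rownames(keys) <- NULL
  structure(m, row_labels = keys, angles = angles, n_time = n_time,
            class = c("feature_matrix", "matrix", "array"))
}

#' Row labels of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @return Data frame with columns `subject`, `condition`, `side`, `trial`.
#' @export
row_labels <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  attr(fm, "row_labels")
}

# column indices of one angle block
block_index <- function(a, n_time) ((a - 1L) * n_time + 1L):(a * n_time)

#' Standardize a feature matrix
#'
#' Subtracts the per-column mean (the mean of each angle at each time point
#' over all trials, conditions, sides and subjects). The centered columns are
#' then divided by a single pooled scale per angle block — the sample
#' standard deviation of all centered entries of that block — so each
#' variable set (one angle over its time points) has zero mean and unit
#' pooled standard deviation while keeping the time-dependent shape of its
#' variability. `sd_mode = "column"` divides by per-column standard
#' deviations instead.
#'
#' @param fm A `feature_matrix`.
#' @param sd_mode `"block"` (default, one pooled scale per angle block) or
#'   `"column"`.
#' @return A list with elements `matrix` (the standardized `feature_matrix`)
#'   and `params` (a `normalization_params` for [inverse_standardize()]).
#' @export
standardize <- function(fm, sd_mode = c("block", "column")) {
  stopifnot(inherits(fm, "feature_matrix"))
  sd_mode <- match.arg(sd_mode)
  if (nrow(fm) < 2L) stop("standardize needs >= 2 rows", call. = FALSE)
  n_time <- attr(fm, "n_time")
  angles <- attr(fm, "angles")
  cm <- colMeans(fm)
  x <- sweep(unclass(fm), 2L, cm)
  if (sd_mode == "block") {
    block_sds <- vapply(seq_along(angles), function(a) {
      v <- x[, block_index(a, n_time)]
      sqrt(sum(v^2) / (length(v) - 1L))
    }, numeric(1L))
    names(block_sds) <- angles
    if (any(block_sds < 1e-12)) {
      stop("degenerate data: zero-variance angle block(s): ",
           paste(angles[block_sds < 1e-12], collapse = ", "), call. = FALSE)
    }
    scales <- rep(block_sds, each = n_time)
  } else {
    scales <- apply(x, 2L, stats::sd)
    block_sds <- NULL
    if (any(scales < 1e-12)) {
      stop("degenerate data: zero-variance column(s)", call. = FALSE)
    }
  }
  xs <- sweep(x, 2L, scales, "/")
  out <- structure(xs, row_labels = attr(fm, "row_labels"), angles = angles,
                   n_time = n_time,
                   class = c("feature_matrix", "matrix", "array"))
  params <- structure(list(column_means = cm, scales = unname(scales),
                           block_sds = block_sds, sd_mode = sd_mode,
                           angles = angles, n_time = n_time),
                      class = "normalization_params")
  list(matrix = out, params = params)
}

#' Map a standardized profile back to angle space
#'
#' Exact inverse of the affine standardization: multiplies by the stored
#' scales and adds back the column means, returning values in degrees. A
#' zero vector maps to the grand-mean movement profile.
#'
#' @param vector Numeric vector (length = number of feature columns) or a
#'   matrix with that many columns.
#' @param params `normalization_params` from [standardize()].
#' @return Numeric vector or matrix in angle space.
#' @export
inverse_standardize <- function(vector, params) {
  stopifnot(inherits(params, "normalization_params"))
  p <- length(params$column_means)
  if (is.matrix(vector)) {
    if (ncol(vector) != p) stop("column count does not match params",
                                call. = FALSE)
    return(sweep(sweep(vector, 2L, params$scales, "*"), 2L,
                 params$column_means, "+"))
  }
  if (length(vector) != p) {
    stop("profile length (", length(vector),
         ") does not match params (", p, ")", call. = FALSE)
  }
  as.numeric(vector) * params$scales + params$column_means
}

#' Reshape a feature-matrix profile into per-angle waveforms
#'
#' @param profile Numeric vector of length `n_angles * n_time`.
#' @param params A `normalization_params` (or any list with `angles` and
#'   `n_time`).
#' @return Numeric matrix, `n_time` x `n_angles`.
#' @export
profile_by_angle <- function(profile, params) {
  n_time <- params$n_time
  angles <- params$angles
  stopifnot(length(profile) == n_time * length(angles))
  matrix(profile, nrow = n_time, ncol = length(angles),
         dimnames = list(NULL, angles))
}
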