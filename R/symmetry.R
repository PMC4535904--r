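#' Left/right symmetry index of a trial group
#'
#' The mean waveform of the left-side trials is subtracted from the mean
#' waveform of the right-side trials, each time point is divided by the
#' pooled standard deviation of the two sides at that point, the normalized
#' differences are summed over all time points (and angle blocks) and the
#' absolute value is taken. The index is dimensionless; 0 means perfectly
#' symmetric. Pooling is the equal-weight root-mean of the two sides' sample
#' variances. `sum_mode = "absolute"` sums absolute normalized differences
#' instead (no cancellation between time points).
#'
#' @param left,right Numeric matrices, one row per trial (>= 2 each), one
#'   column per waveform sample; the same column layout on both sides.
#' @param sum_mode `"signed"` (default) or `"absolute"`.
#' @param sd_tol Time points whose pooled SD falls below this tolerance are
#'   excluded from the sum, with a warning (default 1e-9).
#' @return A single non-negative number.
#' @export
symmetry_index <- function(left, right, sum_mode = c("signed", "absolute"),
                           sd_tol = 1e-9) {
  sum_mode <- match.arg(sum_mode)
  left <- as.matrix(left)
  right <- as.matrix(right)
  if (ncol(left) != ncol(right)) {
    stop("left and right must have the same column layout", call. = FALSE)
  }
  if (nrow(left) < 2L || nrow(right) < 2L) {
    stop("insufficient data: need >= 2 trials per side for the pooled SD",
         call. = FALSE)
  }
  d <- colMeans(right) - colMeans(left)
  pooled <- sqrt((apply(left, 2L, stats::var) +
                    apply(right, 2L, stats::var)) / 2)
  keep <- pooled > sd_tol
  if (!all(keep)) {
    warning(sum(!keep), " time point(s) with pooled SD below ", sd_tol,
            " excluded from the symmetry sum")
  }
  z <- d[keep] / pooled[keep]
  if (sum_mode == "signed") abs(sum(z)) else sum(abs(z))
}

#' Symmetry table per subject and condition
#'
#' Computes the left/right [symmetry_index()] for every subject x condition
#' cell of a trial set, using the full concatenated nine-angle waveform of
#' each trial (time-normalized to `n_time` points). Cells missing a side or
#' with fewer than two trials on a side are marked `NA` with a warning.
#'
#' @param trials A [trial_set()].
#' @param n_time Samples per cycle (default 201).
#' @param sum_mode Passed to [symmetry_index()].
#' @return Data frame of class `symmetry_table` with columns `subject`,
#'   `condition`, `symmetry`, and `sex` when available; per-condition
#'   medians via [condition_medians()].
#' @export
symmetry_table <- function(trials, n_time = 201L,
                           sum_mode = c("signed", "absolute")) {
  sum_mode <- match.arg(sum_mode)
  stopifnot(inherits(trials, "trial_set"))
  fm <- build_feature_matrix(trials, n_time = n_time)
  rl <- row_labels(fm)
  subjects <- unique(rl$subject)
  conditions <- unique(rl$condition)
  out <- expand.grid(subject = subjects, condition = conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$subject, subjects)), , drop = FALSE]
  rownames(out) <- NULL
  out$symmetry <- NA_real_
  for (i in seq_len(nrow(out))) {
    li <- rl$subject == out$subject[i] & rl$condition == out$condition[i] &
      rl$side == "L"
    ri <- rl$subject == out$subject[i] & rl$condition == out$condition[i] &
      rl$side == "R"
    if (sum(li) < 2L || sum(ri) < 2L) {
      warning("subject ", out$subject[i], ", condition ", out$condition[i],
              ": fewer than 2 trials on a side; symmetry marked missing")
      next
    }
    out$symmetry[i] <- symmetry_index(unclass(fm)[li, , drop = FALSE],
                                      unclass(fm)[ri, , drop = FALSE],
                                      sum_mode = sum_mode)
  }
  if (!is.null(trials$meta$sex)) {
    out$sex <- unname(trials$meta$sex[out$subject])
  }
  class(out) <- c("symmetry_table", "data.frame")
  out
}

#' Per-condition medians of a symmetry table
#'
#' @param st A `symmetry_table`.
#' @return Named numeric vector of median symmetry per condition.
#' @export
condition_medians <- function(st) {
  stopifnot(inherits(st, "symmetry_table"))
  meds <- tapply(st$symmetry, st$condition, stats::median, na.rm = TRUE)
  meds[unique(st$condition)]
}
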