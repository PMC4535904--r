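# linear maximal-margin separator via e1071; labels must be a 2-level factor
fit_linear_margin <- function(x, labels, cost) {
  e1071::svm(x, labels, type = "C-classification", kernel = "linear",
             cost = cost, scale = FALSE)
}

# predict with a deterministic tie rule: a decision value of exactly zero is
# assigned to the first (positive-side) class
predict_linear_margin <- function(model, newx) {
  p <- predict(model, newx, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  pair <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
  ifelse(drop(dv) >= 0, pair[1L], pair[2L])
}

#' Critical count for a better-than-chance classification rate
#'
#' Smallest number of correct classifications `c` out of `n` for which the
#' one-sided binomial tail probability `P(X >= c)` under chance (success
#' probability `p`) does not exceed `alpha`. Returns `NA` when no count up
#' to `n` reaches significance (small samples).
#'
#' @param n Number of classified trials.
#' @param p Chance success probability (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @return Integer critical count, or `NA_integer_`.
#' @export
binomial_critical_count <- function(n, p = 0.5, alpha = 0.05) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    stop("`p` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  cc <- 0:n
  tail <- stats::pbinom(cc - 1L, n, p, lower.tail = FALSE)
  ok <- which(tail <= alpha)
  if (length(ok) == 0L) return(NA_integer_)
  as.integer(cc[ok[1L]])
}

#' Leave-one-out classification of two groups
#'
#' For every row, a maximal-margin linear separator is trained on all other
#' rows and used to predict the held-out row; the classification rate
#' `r_class` is the fraction of correct predictions. Significance is the
#' one-sided exact binomial criterion against chance 0.5 (see
#' [binomial_critical_count()]). Deterministic given the data.
#'
#' @param x Numeric matrix, rows from both groups.
#' @param labels Two-level grouping (factor or character), one per row; the
#'   first level is the reference group and wins prediction ties.
#' @param cost Margin penalty of the linear separator (default 1).
#' @param alpha Significance level for the binomial criterion.
#' @return An object of class `comparison_result`: `group_a`, `group_b`,
#'   `n_trials`, `n_correct`, `r_class`, `alpha`, `critical_count`,
#'   `significant`.
#' @export
loo_classify <- function(x, labels, cost = 1, alpha = 0.05) {
  x <- unclass(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) {
    stop("labels must contain exactly two groups", call. = FALSE)
  }
  if (min(table(labels)) < 2L) {
    stop("each group needs >= 2 rows for leave-one-out", call. = FALSE)
  }
  n <- nrow(x)
  correct <- 0L
  for (i in seq_len(n)) {
    m <- fit_linear_margin(x[-i, , drop = FALSE], labels[-i], cost)
    pred <- predict_linear_margin(m, x[i, , drop = FALSE])
    if (pred == as.character(labels[i])) correct <- correct + 1L
  }
  crit <- binomial_critical_count(n, 0.5, alpha)
  structure(list(group_a = levels(labels)[1L], group_b = levels(labels)[2L],
                 n_trials = n, n_correct = correct, r_class = correct / n,
                 alpha = alpha, critical_count = crit,
                 significant = !is.na(crit) && correct >= crit),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$group_a, " vs ", x$group_b, ": r_class = ",
      signif(x$r_class, 3), " (", x$n_correct, "/", x$n_trials, ")",
      if (isTRUE(x$significant)) " *" else "", "\n", sep = "")
  invisible(x)
}

comparison_row <- function(res, ...) {
  data.frame(..., group_a = res$group_a, group_b = res$group_b,
             n_trials = res$n_trials, n_correct = res$n_correct,
             r_class = res$r_class, critical_count = res$critical_count,
             significant = res$significant, stringsAsFactors = FALSE)
}

#' All pairwise subject comparisons
#'
#' Leave-one-out classification of every unordered pair of subjects, using
#' all their trials (both sides, all conditions). Subjects with fewer than
#' two rows are excluded with a warning.
#'
#' @param fm Standardized `feature_matrix`.
#' @param cost,alpha Passed to [loo_classify()].
#' @return Data frame with one row per subject pair (`group_a`, `group_b`,
#'   `n_trials`, `n_correct`, `r_class`, `critical_count`, `significant`),
#'   with attributes `n_comparisons` and `n_significant`.
#' @export
pairwise_subject_comparisons <- function(fm, cost = 1, alpha = 0.05) {
  rl <- row_labels(fm)
  counts <- table(rl$subject)
  usable <- names(counts)[counts >= 2L]
  if (length(usable) < length(counts)) {
    warning("excluding subject(s) with < 2 trials: ",
            paste(setdiff(names(counts), usable), collapse = ", "))
  }
  if (length(usable) < 2L) stop("need >= 2 usable subjects", call. = FALSE)
  pairs <- utils::combn(sort(usable), 2L)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    idx <- rl$subject %in% pairs[, j]
    res <- loo_classify(unclass(fm)[idx, , drop = FALSE],
                        factor(rl$subject[idx], levels = pairs[, j]),
                        cost = cost, alpha = alpha)
    out[[j]] <- comparison_row(res)
  }
  out <- do.call(rbind, out)
  attr(out, "n_comparisons") <- nrow(out)
  attr(out, "n_significant") <- sum(out$significant)
  out
}

#' Condition comparisons across subjects
#'
#' Classifies the reference condition against each other condition with all
#' subjects' trials pooled, testing for a subject-independent condition
#' effect on the movement pattern.
#'
#' @param fm Standardized `feature_matrix`.
#' @param reference Reference condition label (default `"Neutral"`).
#' @param conditions Conditions to compare against the reference; default
#'   all non-reference conditions present. An explicitly requested condition
#'   that is absent from the data is an error.
#' @param cost,alpha Passed to [loo_classify()].
#' @return Data frame with one row per comparison.
#' @export
condition_comparisons_across <- function(fm, reference = "Neutral",
                                         conditions = NULL, cost = 1,
                                         alpha = 0.05) {
  rl <- row_labels(fm)
  present <- unique(rl$condition)
  if (!reference %in% present) {
    stop("reference condition \"", reference, "\" not present",
         call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- setdiff(present, reference)
  } else if (!all(conditions %in% present)) {
    stop("condition(s) not present: ",
         paste(setdiff(conditions, present), collapse = ", "),
         call. = FALSE)
  }
  if (length(conditions) == 0L) {
    stop("no conditions to compare against the reference", call. = FALSE)
  }
  out <- lapply(conditions, function(cond) {
    idx <- rl$condition %in% c(reference, cond)
    res <- loo_classify(unclass(fm)[idx, , drop = FALSE],
                        factor(rl$condition[idx],
                               levels = c(reference, cond)),
                        cost = cost, alpha = alpha)
    comparison_row(res)
  })
  do.call(rbind, out)
}

#' Within-subject condition comparisons
#'
#' For every subject and every non-reference condition, classifies that
#' subject's reference-condition trials against their trials under the
#' condition (both sides included as separate rows). Cells where either
#' group has fewer than two rows are marked missing. The mean
#' classification rate per comparison across subjects is attached.
#'
#' @param fm Standardized `feature_matrix`.
#' @param reference Reference condition label (default `"Neutral"`).
#' @param cost,alpha Passed to [loo_classify()].
#' @return Data frame with one row per subject x comparison (`subject`,
#'   `comparison`, `n_trials`, `n_correct`, `r_class`, `critical_count`,
#'   `significant`; `NA` for missing cells), with attribute `mean_rates`
#'   (named mean `r_class` per comparison).
#' @export
condition_comparisons_within <- function(fm, reference = "Neutral", cost = 1,
                                         alpha = 0.05) {
  rl <- row_labels(fm)
  if (!reference %in% rl$condition) {
    stop("reference condition \"", reference, "\" not present",
         call. = FALSE)
  }
  subjects <- sort(unique(rl$subject))
  conditions <- setdiff(unique(rl$condition), reference)
  out <- list()
  for (cond in conditions) {
    for (s in subjects) {
      idx <- rl$subject == s & rl$condition %in% c(reference, cond)
      labs <- factor(rl$condition[idx], levels = c(reference, cond))
      cmp <- paste(reference, "vs", cond)
      if (sum(labs == reference) < 2L || sum(labs == cond) < 2L) {
        warning("insufficient trials for subject ", s, ", ", cmp,
                "; cell marked missing")
        out[[length(out) + 1L]] <- data.frame(
          subject = s, comparison = cmp, group_a = reference, group_b = cond,
          n_trials = NA_integer_, n_correct = NA_integer_,
          r_class = NA_real_, critical_count = NA_integer_,
          significant = NA, stringsAsFactors = FALSE)
        next
      }
      res <- loo_classify(unclass(fm)[idx, , drop = FALSE], labs,
                          cost = cost, alpha = alpha)
      out[[length(out) + 1L]] <- comparison_row(res, subject = s,
                                                comparison = cmp)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  means <- tapply(out$r_class, out$comparison, mean, na.rm = TRUE)
  attr(out, "mean_rates") <- means
  out
}

#' Reshape within-subject results to a comparisons-by-subjects table
#'
#' @param within Result of [condition_comparisons_within()].
#' @return Data frame: one row per comparison, one column per subject holding
#'   `r_class` (a `*` suffix marks significant cells), plus a `mean` column.
#' @export
within_subject_table <- function(within) {
  comps <- unique(within$comparison)
  subjects <- sort(unique(within$subject))
  rows <- lapply(comps, function(cmp) {
    d <- within[within$comparison == cmp, ]
    cells <- vapply(subjects, function(s) {
      r <- d[d$subject == s, ]
      if (nrow(r) == 0L || is.na(r$r_class)) return(NA_character_)
      paste0(format(round(r$r_class, 2), nsmall = 2),
             if (isTRUE(r$significant)) "*" else "")
    }, character(1L))
    out <- data.frame(comparison = cmp, stringsAsFactors = FALSE)
    out[subjects] <- as.list(cells)
    out$mean <- round(mean(d$r_class, na.rm = TRUE), 3)
    out
  })
  do.call(rbind, rows)
}

#' Variables with large discriminant loadings (2-SD rule)
#'
#' Selects the indices whose absolute weight exceeds twice the standard
#' deviation of all weights — the variables driving the separation of the
#' two groups.
#'
#' @param weights Numeric weight vector.
#' @return Integer indices with `|w| > 2 * sd(w)`.
#' @export
select_important_variables <- function(weights) {
  unname(which(abs(weights) > 2 * stats::sd(weights)))
}

#' Extract and back-project the discriminant between two groups
#'
#' Fits the maximal-margin linear separator on all rows of the two groups,
#' normalizes its weight vector to unit length, applies the 2-SD
#' variable-selection rule, and maps the group mean profiles back to angle
#' space (degrees) through the inverse standardization; the discriminant
#' direction is back-projected through the same scales. Selected time
#' regions are reported per angle.
#'
#' @param x Standardized numeric matrix, rows of the two groups only.
#' @param labels Two-level grouping, one per row.
#' @param params `normalization_params` from [standardize()].
#' @param cost Margin penalty (default 1).
#' @return An object of class `discriminant_profile`: `weights` (unit norm),
#'   `threshold` (2 x SD of weights), `selected_columns`, `group_a/b`,
#'   `angle_profiles` (list of `n_time` x `n_angles` matrices `mean_a`,
#'   `mean_b` in degrees and `discriminant`), `selected_by_angle`.
#' @export
extract_discriminant <- function(x, labels, params, cost = 1) {
  stopifnot(inherits(params, "normalization_params"))
  x <- unclass(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) {
    stop("labels must contain exactly two groups", call. = FALSE)
  }
  m <- fit_linear_margin(x, labels, cost)
  w <- drop(t(m$coefs) %*% m$SV)
  nrm <- sqrt(sum(w^2))
  if (!is.finite(nrm) || nrm < 1e-12) {
    stop("degenerate separator: zero weight vector", call. = FALSE)
  }
  w <- w / nrm
  thr <- 2 * stats::sd(w)
  selected <- select_important_variables(w)
  mean_a <- colMeans(x[labels == levels(labels)[1L], , drop = FALSE])
  mean_b <- colMeans(x[labels == levels(labels)[2L], , drop = FALSE])
  profiles <- list(
    mean_a = profile_by_angle(inverse_standardize(mean_a, params), params),
    mean_b = profile_by_angle(inverse_standardize(mean_b, params), params),
    discriminant = profile_by_angle(w * params$scales, params))
  n_time <- params$n_time
  sel_by_angle <- lapply(seq_along(params$angles), function(a) {
    idx <- selected[selected %in% block_index(a, n_time)]
    idx - (a - 1L) * n_time  # time index within the angle block
  })
  names(sel_by_angle) <- params$angles
  structure(list(weights = w, threshold = thr, selected_columns = selected,
                 group_a = levels(labels)[1L], group_b = levels(labels)[2L],
                 angle_profiles = profiles,
                 selected_by_angle = sel_by_angle),
            class = "discriminant_profile")
}

#' @export
print.discriminant_profile <- function(x, ...) {
  cat("<discriminant_profile> ", x$group_a, " vs ", x$group_b, ": ",
      length(x$selected_columns), " variables beyond 2 SD (threshold ",
      signif(x$threshold, 3), ")\n", sep = "")
  invisible(x)
}
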