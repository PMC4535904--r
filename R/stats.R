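stat_test_result <- function(test, statistic, df, n, p, effect_size_r = NA,
                             effect_label = NA_character_) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), n = n, p = unname(p),
                 effect_size_r = effect_size_r, effect_label = effect_label),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat("<stat_test_result> ", x$test, ": statistic = ",
      signif(x$statistic, 4), ", df = ", x$df, ", n = ", x$n,
      ", p = ", signif(x$p, 3), sep = "")
  if (!is.na(x$effect_size_r)) {
    cat(", r = ", signif(x$effect_size_r, 3), " (", x$effect_label, ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

# Rosenthal effect-size labels: 0.1 / 0.3 / 0.5 = low / medium / large
effect_size_label <- function(r) {
  as.character(cut(r, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf),
                   labels = c("sub-low", "low", "medium", "large"),
                   right = FALSE))
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on
#' `length(groups) - 1` degrees of freedom.
#'
#' @param groups List of two or more numeric vectors.
#' @return A `stat_test_result` (`statistic` = H, `df`, `n` = total
#'   observations, `p`).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  }
  if (any(lengths(groups) < 1L)) {
    stop("each group needs at least one value", call. = FALSE)
  }
  n <- sum(lengths(groups))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(stat_test_result("kruskal_wallis", statistic = 0,
                            df = length(groups) - 1L, n = n, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  stat_test_result("kruskal_wallis", statistic = kt$statistic,
                   df = kt$parameter, n = n, p = kt$p.value)
}

#' Friedman test on a subjects-by-conditions table
#'
#' Rank test for consistent condition differences across complete blocks
#' (subjects). Incomplete blocks (rows with missing values) are dropped with
#' a warning.
#'
#' @param blocked Numeric matrix or data frame, one row per subject, one
#'   column per condition.
#' @return A `stat_test_result` (`statistic` = chi-square, `df` =
#'   conditions - 1, `n` = complete blocks, `p`).
#' @export
friedman <- function(blocked) {
  m <- as.matrix(blocked)
  if (ncol(m) < 2L) stop("need >= 2 conditions", call. = FALSE)
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sum(!complete), " incomplete block(s) dropped")
    m <- m[complete, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need >= 2 complete blocks", call. = FALSE)
  if (all(apply(m, 1L, function(r) length(unique(r)) == 1L))) {
    return(stat_test_result("friedman", statistic = 0, df = ncol(m) - 1L,
                            n = nrow(m), p = 1))
  }
  ft <- stats::friedman.test(m)
  stat_test_result("friedman", statistic = ft$statistic, df = ft$parameter,
                   n = nrow(m), p = ft$p.value)
}

#' Mann-Whitney U test with Rosenthal effect size
#'
#' Rank-sum comparison of two independent samples: the U statistic, its
#' tie-corrected normal approximation Z, the two-sided p-value, and the
#' Rosenthal effect size `r = |Z| / sqrt(n_x + n_y)` labelled by the
#' 0.1 / 0.3 / 0.5 thresholds (low / medium / large; below 0.1 is
#' "sub-low").
#'
#' @param x,y Numeric samples.
#' @return A `stat_test_result` (`statistic` = U, `n`, `p`,
#'   `effect_size_r`, `effect_label`; `df` holds Z).
#' @export
mann_whitney_effect <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (u - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  es <- abs(z) / sqrt(n)
  structure(list(test = "mann_whitney", statistic = u, df = NA, z = z,
                 n = n, p = p, effect_size_r = es,
                 effect_label = effect_size_label(es)),
            class = "stat_test_result")
}

#' Holm step-down multiple-testing correction
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param alpha Family-wise error level (default 0.05).
#' @return Data frame with columns `p`, `p_adjusted` (monotone Holm-adjusted
#'   values) and `reject`.
#' @export
holm_correct <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "holm")
  data.frame(p = p_values, p_adjusted = adj, reject = adj <= alpha)
}

#' Compare running speed across conditions
#'
#' Checks normality (Lilliefors / Kolmogorov-Smirnov on the within-cell
#' centered speeds), runs a one-way repeated-measures ANOVA of the
#' per-subject mean speed across conditions, and follows up with paired
#' t-tests under Holm correction. When the per-subject condition means are
#' identical (no condition effect at all) the ANOVA p-value is 1 by
#' definition.
#'
#' @param speed Data frame with columns `subject`, `condition`, `speed`
#'   (m/s, one row per trial), e.g. the `speed` metadata of a synthetic
#'   cohort.
#' @return List of class `speed_comparison`: `normality_p`, `anova` (a
#'   `stat_test_result` with the F statistic) and `pairwise` (paired t
#'   results with Holm-adjusted p-values).
#' @export
compare_running_speed <- function(speed) {
  req <- c("subject", "condition", "speed")
  if (!all(req %in% names(speed))) {
    stop("`speed` needs columns subject, condition, speed", call. = FALSE)
  }
  agg <- stats::aggregate(speed ~ subject + condition, data = speed,
                          FUN = mean)
  cell_mean <- stats::ave(speed$speed,
                          interaction(speed$subject, speed$condition),
                          FUN = mean)
  resid <- speed$speed - cell_mean
  normality_p <- if (length(resid) >= 5L && stats::sd(resid) > 1e-12) {
    nortest::lillie.test(resid)$p.value
  } else {
    NA_real_
  }
  wide <- stats::reshape(agg, idvar = "subject", timevar = "condition",
                         direction = "wide")
  conds <- unique(agg$condition)
  m <- as.matrix(wide[paste0("speed.", conds)])
  if (max(apply(m, 1L, function(r) diff(range(r)))) < 1e-12) {
    # no within-subject condition differences at all
    an <- stat_test_result("anova", statistic = 0,
                           df = c(length(conds) - 1L,
                                  (nrow(m) - 1L) * (length(conds) - 1L)),
                           n = nrow(m), p = 1)
  } else {
    agg$subject <- factor(agg$subject)
    agg$condition <- factor(agg$condition)
    fit <- stats::aov(speed ~ condition + Error(subject), data = agg)
    tab <- summary(fit)[["Error: Within"]][[1L]]
    an <- stat_test_result("anova", statistic = tab["condition", "F value"],
                           df = tab$Df, n = nrow(m),
                           p = tab["condition", "Pr(>F)"])
  }
  pairs <- utils::combn(conds, 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- m[, paste0("speed.", pairs[1L, j])]
    b <- m[, paste0("speed.", pairs[2L, j])]
    if (stats::sd(a - b) < 1e-12) {
      data.frame(condition_a = pairs[1L, j], condition_b = pairs[2L, j],
                 t = 0, p = 1, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(condition_a = pairs[1L, j], condition_b = pairs[2L, j],
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  pw <- do.call(rbind, pw)
  hc <- holm_correct(pw$p)
  pw$p_adjusted <- hc$p_adjusted
  pw$reject <- hc$reject
  structure(list(normality_p = normality_p, anova = an, pairwise = pw),
            class = "speed_comparison")
}

#' Gender subgroup analysis of a symmetry table
#'
#' Runs a Friedman test within each sex subgroup (complete subject blocks
#' across conditions) and a between-sex Mann-Whitney comparison with
#' Rosenthal effect size for every condition. A secondary analysis, reported
#' without alpha correction.
#'
#' @param st A `symmetry_table` carrying a `sex` column.
#' @return List with `friedman_by_sex` (named list of `stat_test_result`)
#'   and `mann_whitney_by_condition` (named list of `stat_test_result`).
#' @export
gender_subgroup_analysis <- function(st) {
  stopifnot(inherits(st, "symmetry_table"))
  if (is.null(st$sex)) stop("symmetry table carries no sex metadata",
                            call. = FALSE)
  conds <- unique(st$condition)
  fr <- lapply(split(st, st$sex), function(d) {
    wide <- stats::reshape(d[c("subject", "condition", "symmetry")],
                           idvar = "subject", timevar = "condition",
                           direction = "wide")
    m <- as.matrix(wide[paste0("symmetry.", conds)])
    if (sum(stats::complete.cases(m)) < 2L) {
      warning("subgroup with < 2 complete subjects; Friedman test skipped")
      return(NULL)
    }
    friedman(m)
  })
  mw <- lapply(conds, function(cond) {
    d <- st[st$condition == cond & !is.na(st$symmetry), ]
    xf <- d$symmetry[d$sex == "F"]
    xm <- d$symmetry[d$sex == "M"]
    if (length(xf) == 0L || length(xm) == 0L) {
      warning("condition ", cond, " lacks one sex; comparison skipped")
      return(NULL)
    }
    mann_whitney_effect(xf, xm)
  })
  names(mw) <- conds
  list(friedman_by_sex = fr, mann_whitney_by_condition = mw)
}
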