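test_that("leave-one-out classification separates separable groups and is chance-level on noise", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0, 0.5), ncol = 4L),
             matrix(rnorm(40, 6, 0.5), ncol = 4L))
  labs <- rep(c("a", "b"), each = 10L)
  res <- loo_classify(x, labs)
  expect_equal(res$r_class, 1.0)
  expect_true(res$significant)
  expect_equal(res$n_trials, 20L)

  # permuted labels on pure noise: mean rate near chance
  set.seed(2)
  rates <- replicate(20, {
    xn <- matrix(rnorm(40 * 10), ncol = 10L)
    loo_classify(xn, sample(rep(c("a", "b"), each = 20L)))$r_class
  })
  expect_gt(mean(rates), 0.35)
  expect_lt(mean(rates), 0.65)

  expect_error(loo_classify(x, rep("a", 20L)), "two groups")
  expect_error(loo_classify(x[1:11, ], c(rep("a", 10L), "b")), ">= 2 rows")
})

test_that("binomial critical counts match exact tail sums", {
  expect_equal(binomial_critical_count(5), 5L)
  expect_true(is.na(binomial_critical_count(4)))
  expect_equal(binomial_critical_count(20), 15L)
  # spot-check the defining property on a spread of n
  for (n in c(1L, 7L, 20L, 33L, 60L)) {
    crit <- binomial_critical_count(n)
    if (!is.na(crit)) {
      expect_lte(brute_force_binom_tail(crit, n, 0.5), 0.05)
      if (crit > 0L) {
        expect_gt(brute_force_binom_tail(crit - 1L, n, 0.5), 0.05)
      }
    } else {
      expect_gt(brute_force_binom_tail(n, n, 0.5), 0.05)
    }
  }
  expect_error(binomial_critical_count(0), "n")
  expect_error(binomial_critical_count(10, p = 1.2), "p")
  expect_error(binomial_critical_count(10, alpha = 0), "alpha")
})

test_that("pairwise subject comparisons cover every pair and detect distinct subjects", {
  co <- tiny_cohort(n_subjects = 4L, n_trials = 2L, seed = 21L,
                    conditions = c("Neutral", "Max"))
  std <- standardize(build_feature_matrix(co$trials))
  pw <- pairwise_subject_comparisons(std$matrix)
  expect_equal(nrow(pw), choose(4L, 2L))
  # subject patterns dominate (sigma_subject >> sigma_trial): all significant
  expect_true(all(pw$significant))
  expect_equal(attr(pw, "n_significant"), 6L)
})

test_that("across- and within-subject condition schemes have the expected shape", {
  co <- tiny_cohort(n_subjects = 3L, n_trials = 2L, seed = 22L)
  std <- standardize(build_feature_matrix(co$trials))
  across <- condition_comparisons_across(std$matrix)
  expect_equal(nrow(across), 3L)
  expect_equal(across$group_a, rep("Neutral", 3L))
  expect_setequal(across$group_b, c("Centric", "DPS", "Max"))
  expect_error(condition_comparisons_across(std$matrix, reference = "None"),
               "reference")
  expect_error(condition_comparisons_across(std$matrix,
                                            conditions = "Hyper"),
               "not present")

  within <- condition_comparisons_within(std$matrix)
  expect_equal(nrow(within), 3L * 3L)
  expect_equal(length(attr(within, "mean_rates")), 3L)
  tab <- within_subject_table(within)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("comparison", "S01", "S02", "S03", "mean") %in%
                    names(tab)))
})

test_that("an injected consistent condition shift makes the within-subject rate 1", {
  co <- tiny_cohort(n_subjects = 2L, n_trials = 3L, seed = 23L,
                    conditions = c("Neutral", "Max"), delta_cond = 0)
  d <- co$trials$data
  d$knee[d$condition == "Max"] <- d$knee[d$condition == "Max"] + 15
  std <- standardize(build_feature_matrix(trial_set(d,
                                                    meta = co$trials$meta)))
  within <- condition_comparisons_within(std$matrix)
  expect_true(all(within$r_class == 1))
})

test_that("the 2-SD rule selects exactly the large-loading variables", {
  # groups differing in a single column: that column is the sole selection
  set.seed(3)
  base <- matrix(rnorm(12 * 6, sd = 1), ncol = 6L)
  x <- base
  x[7:12, 4L] <- x[7:12, 4L] + 50
  params <- structure(list(column_means = rep(0, 6L), scales = rep(1, 6L),
                           block_sds = NULL, sd_mode = "block",
                           angles = c("a1", "a2"), n_time = 3L),
                      class = "normalization_params")
  dp <- extract_discriminant(x, rep(c("g1", "g2"), each = 6L), params)
  expect_equal(dp$selected_columns, 4L)
  expect_equal(sqrt(sum(dp$weights^2)), 1, tolerance = 1e-9)

  # standard-normal weights: ~4.6% of values lie beyond two SDs
  set.seed(4)
  frac <- replicate(50, length(select_important_variables(rnorm(1809))) /
                      1809)
  expect_gt(mean(frac), 0.046 - 0.015)
  expect_lt(mean(frac), 0.046 + 0.015)
})

test_that("discriminant back-projection recovers the raw group mean waveforms", {
  co <- tiny_cohort(n_subjects = 2L, n_trials = 3L, seed = 24L,
                    conditions = c("Neutral", "Centric"))
  fm <- build_feature_matrix(co$trials)
  std <- standardize(fm)
  rl <- row_labels(fm)
  dp <- extract_discriminant(unclass(std$matrix), rl$subject, std$params)
  raw_a <- colMeans(unclass(fm)[rl$subject == "S01", ])
  expect_equal(as.numeric(dp$angle_profiles$mean_a),
               unname(raw_a), tolerance = 1e-10)
  raw_b <- colMeans(unclass(fm)[rl$subject == "S02", ])
  expect_equal(as.numeric(dp$angle_profiles$mean_b),
               unname(raw_b), tolerance = 1e-10)
  expect_equal(dim(dp$angle_profiles$discriminant), c(201L, 9L))
  expect_named(dp$selected_by_angle, angle_names())
})
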