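test_that("time normalization preserves constants, linear ramps and endpoints", {
  expect_equal(time_normalize(rep(5, 17)), rep(5, 201))
  ramp <- time_normalize(seq(0, 10, length.out = 11))
  expect_equal(length(ramp), 201L)
  expect_equal(ramp[101L], 5.0, tolerance = 1e-9)
  expect_equal(ramp[c(1L, 201L)], c(0, 10))
  expect_error(time_normalize(1:10, n_time = 1), "n_time")
  expect_error(time_normalize(3), "length")
})

test_that("cubic resampling of a sine stays within 1e-3 of the closed form", {
  x <- sin(2 * pi * seq(0, 1, length.out = 50))
  y <- time_normalize(x, 201)
  expect_lt(max(abs(y - sin(2 * pi * seq(0, 1, length.out = 201)))), 1e-3)
})

test_that("trial CSV files round-trip and malformed files are rejected", {
  co <- tiny_cohort(n_subjects = 2L, n_trials = 1L, seed = 8L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(co$trials, path)
  back <- read_trials(path)
  expect_equal(back$data, co$trials$data, tolerance = 1e-8)
  expect_equal(back$meta$sex, co$trials$meta$sex)
  expect_equal(back$meta$speed$speed, co$trials$meta$speed$speed,
               tolerance = 1e-8)

  # missing angle column -> schema error
  d <- utils::read.csv(path)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d[setdiff(names(d), "thorax")], p2, row.names = FALSE)
  expect_error(read_trials(p2), "thorax")

  # duplicate trial key -> duplicate error with line numbers
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rbind(d, d[1L, ]), p3, row.names = FALSE)
  expect_error(read_trials(p3), "duplicate")

  # non-finite angle -> malformed row with line number
  d2 <- d
  d2$knee[3L] <- NA
  p4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d2, p4, row.names = FALSE)
  expect_error(read_trials(p4), "line")
})

test_that("a fixture with 2 subjects x 1 condition x 1 trial x 2 sides reads as 4 trials", {
  co <- generate_cohort(synth_config(n_subjects = 2L,
                                     conditions = "Neutral",
                                     n_trials = 1L, seed = 4L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(co$trials, path)
  expect_equal(n_trials(read_trials(path)), 4L)
})

test_that("feature matrix has nine contiguous angle blocks in canonical order", {
  co <- tiny_cohort(n_subjects = 2L, n_trials = 2L, seed = 6L)
  fm <- build_feature_matrix(co$trials)
  expect_equal(ncol(fm), 9L * 201L)
  expect_equal(nrow(fm), n_trials(co$trials))

  # single-trial matrix row equals the concatenated waveforms
  d <- co$trials$data
  one <- d[d$subject == "S01" & d$condition == "Neutral" & d$side == "L" &
             d$trial == 1L, ]
  one <- one[order(one$time_index), ]
  fm1 <- build_feature_matrix(trial_set(one))
  expect_equal(dim(fm1), c(1L, 1809L))
  expect_equal(as.numeric(fm1[1L, ]),
               unlist(one[angle_names()], use.names = FALSE))
  rl <- row_labels(fm)
  expect_equal(nrow(rl), nrow(fm))
})

test_that("standardization zeroes column means and gives unit pooled SD per angle block", {
  co <- tiny_cohort(n_subjects = 3L, n_trials = 2L, seed = 13L)
  fm <- build_feature_matrix(co$trials)
  std <- standardize(fm)
  x <- unclass(std$matrix)
  expect_lt(max(abs(colMeans(x))), 1e-12)
  for (a in seq_len(9L)) {
    block <- x[, ((a - 1L) * 201L + 1L):(a * 201L)]
    pooled <- sqrt(sum(block^2) / (length(block) - 1L))
    expect_equal(pooled, 1, tolerance = 1e-12)
  }
})

test_that("hand-computed toy standardization and its inverse agree", {
  # one angle, two time points, three trials: rows (0,0), (1,2), (2,4)
  m <- matrix(c(0, 0, 1, 2, 2, 4), nrow = 3L, byrow = TRUE)
  fm <- structure(m, row_labels = data.frame(subject = c("a", "b", "c"),
                                             condition = "Neutral",
                                             side = "L", trial = 1L),
                  angles = "knee", n_time = 2L,
                  class = c("feature_matrix", "matrix", "array"))
  std <- standardize(fm)
  # column means (1, 2); centered entries (-1,-2),(0,0),(1,2);
  # pooled SD = sqrt((1+4+0+0+1+4)/5) = sqrt(2)
  expect_equal(std$params$column_means, c(1, 2), ignore_attr = TRUE)
  expect_equal(std$params$block_sds[["knee"]], sqrt(2))
  expected <- (m - rep(c(1, 2), each = 3L)) / sqrt(2)
  expect_equal(unclass(std$matrix), expected, ignore_attr = TRUE)
  for (j in 1:3) {
    expect_equal(inverse_standardize(unclass(std$matrix)[j, ], std$params),
                 m[j, ], tolerance = 1e-12)
  }
  # the zero vector back-projects to the column-mean profile
  expect_equal(inverse_standardize(c(0, 0), std$params), c(1, 2))
  expect_error(inverse_standardize(c(0, 0, 0), std$params), "length")
})

test_that("standardization round-trips random rows and is row-order equivariant", {
  co <- tiny_cohort(n_subjects = 2L, n_trials = 2L, seed = 14L)
  fm <- build_feature_matrix(co$trials)
  std <- standardize(fm)
  i <- 5L
  expect_lt(max(abs(inverse_standardize(unclass(std$matrix)[i, ],
                                        std$params) -
                      unclass(fm)[i, ])), 1e-10)

  perm <- rev(seq_len(nrow(fm)))
  fmp <- structure(unclass(fm)[perm, ],
                   row_labels = row_labels(fm)[perm, ],
                   angles = attr(fm, "angles"), n_time = attr(fm, "n_time"),
                   class = class(fm))
  stdp <- standardize(fmp)
  expect_equal(unclass(stdp$matrix), unclass(std$matrix)[perm, ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("degenerate zero-variance blocks are refused", {
  m <- matrix(rnorm(8), nrow = 4L)
  m[, 1:2] <- 3  # constant angle block
  fm <- structure(m, row_labels = data.frame(subject = letters[1:4],
                                             condition = "Neutral",
                                             side = "L", trial = 1L),
                  angles = c("foot", "ankle"), n_time = 1L,
                  class = c("feature_matrix", "matrix", "array"))
  expect_error(standardize(fm), "degenerate")
})
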