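test_that("k-means recovers well-separated blobs and matches the exhaustive optimum", {
  set.seed(1)
  blob <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2L),
                matrix(rnorm(20, 10, 0.1), ncol = 2L))
  cr <- kmeans_cluster(blob, 2L, seed = 1L, restarts = 10L)
  expect_equal(length(unique(cr$assignments[1:10])), 1L)
  expect_equal(length(unique(cr$assignments[11:20])), 1L)
  expect_false(cr$assignments[1L] == cr$assignments[11L])
  expect_gt(cr$mean_silhouette, 0.9)

  # 10 one-dimensional points, k = 2: inertia equals the exhaustive minimum
  set.seed(2)
  x <- matrix(sort(rnorm(10)), ncol = 1L)
  cr2 <- kmeans_cluster(x, 2L, seed = 3L, restarts = 20L,
                        compute_silhouette = FALSE)
  expect_equal(cr2$inertia, brute_force_inertia(x, 2L), tolerance = 1e-10)

  # k = rows: every row its own cluster, inertia zero
  crn <- suppressWarnings(kmeans_cluster(x, 10L, seed = 1L, restarts = 2L))
  expect_equal(sort(crn$assignments), 1:10)
  expect_equal(crn$inertia, 0)
  expect_equal(crn$silhouette, rep(0, 10))

  expect_error(kmeans_cluster(x, 1L), "k")
  expect_error(kmeans_cluster(x, 11L), "k")
})

test_that("restarts never increase the best inertia", {
  set.seed(3)
  x <- matrix(rnorm(60), ncol = 2L)
  in1 <- kmeans_cluster(x, 4L, seed = 5L, restarts = 1L,
                        compute_silhouette = FALSE)$inertia
  in10 <- kmeans_cluster(x, 4L, seed = 5L, restarts = 10L,
                         compute_silhouette = FALSE)$inertia
  expect_lte(in10, in1 + 1e-12)
})

test_that("silhouette values match the direct a(i)/b(i) definition", {
  set.seed(4)
  x <- matrix(rnorm(12), ncol = 2L)
  cl <- c(1L, 1L, 1L, 2L, 2L, 2L)
  s <- silhouette_values(x, cl)
  expect_equal(s$values, brute_force_silhouette(x, cl), tolerance = 1e-12)
  expect_true(all(s$values >= -1 & s$values <= 1))

  # deliberately swapped points in tight blobs get negative widths
  y <- rbind(matrix(rnorm(10, 0, 0.05), ncol = 1L),
             matrix(rnorm(10, 8, 0.05), ncol = 1L))
  bad <- c(rep(1L, 9L), 2L, rep(2L, 9L), 1L)
  sb <- silhouette_values(y, bad)
  expect_lt(sb$values[10L], 0)
  expect_lt(sb$values[20L], 0)

  expect_error(silhouette_values(x, rep(1L, 6L)), "2 clusters")
})

test_that("silhouette model selection finds three separated blobs", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2L),
             matrix(rnorm(40, 6, 0.3), ncol = 2L),
             cbind(rnorm(20, 0, 0.3), rnorm(20, 12, 0.3)))
  hits <- 0L
  for (seed in 1:10) {
    ks <- suppressMessages(select_k(x, 2:6, seed = seed, restarts = 10L))
    if (ks$best_k == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 6L)  # majority over seeds

  # a single blob has no structure: low silhouettes, warning raised
  z <- matrix(rnorm(300), ncol = 10L)
  expect_warning(suppressMessages(select_k(z, 2:5, seed = 1L,
                                           restarts = 5L)),
                 "little cluster structure")
  expect_error(select_k(x, integer(0)), "empty")
  expect_error(select_k(x, c(2, 500)), "candidates")
})

test_that("distance matrix is symmetric, zero-diagonal and matches the pairwise formula", {
  set.seed(6)
  x <- matrix(rnorm(25), ncol = 5L)
  d <- distance_matrix(x)
  expect_equal(diag(d), rep(0, 5L), ignore_attr = TRUE)
  expect_equal(d, t(d))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)), tolerance = 1e-12)
  }
  # unit difference in one column -> distance one
  y <- rbind(rep(0, 4L), c(1, 0, 0, 0))
  expect_equal(distance_matrix(y)[1L, 2L], 1)
})

test_that("merge tree agglomerates nearest sets first with nondecreasing heights", {
  x <- matrix(c(0, 1, 10), ncol = 1L)
  tr <- merge_tree(x, linkage = "single")
  expect_equal(sort(tr$merge[1L, ]), c(-2L, -1L))  # {0,1} merge first
  expect_true(all(diff(tr$heights) >= -1e-12))

  # single-linkage merge heights equal a naive nearest-pair agglomeration
  set.seed(7)
  y <- matrix(rnorm(12), ncol = 2L)
  tr2 <- merge_tree(y, linkage = "single")
  naive_heights <- local({
    groups <- as.list(seq_len(6L))
    d <- as.matrix(dist(y))
    hs <- numeric(0L)
    while (length(groups) > 1L) {
      best <- c(Inf, 0L, 0L)
      for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (i < j) {
          lnk <- min(d[groups[[i]], groups[[j]]])
          if (lnk < best[1L]) best <- c(lnk, i, j)
        }
      }
      hs <- c(hs, best[1L])
      groups[[best[2L]]] <- c(groups[[best[2L]]], groups[[best[3L]]])
      groups[[best[3L]]] <- NULL
    }
    hs
  })
  expect_equal(tr2$heights, naive_heights, tolerance = 1e-12)

  nwk <- as_newick(tr2)
  expect_match(nwk, "^\\(")
  expect_match(nwk, ";$")
})

test_that("loading rates count trials per group and sum to one", {
  labels <- data.frame(subject = rep(c("S1", "S2"), each = 4L),
                       condition = rep(c("Neutral", "Max"), 4L),
                       side = rep(c("L", "R"), each = 2L, times = 2L))
  assign <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L)  # S1 split 3/1, S2 all in 2
  lr <- loading_rates(assign, labels, "subject")
  expect_equal(unname(lr$rates["S1", ]), c(0.75, 0.25))
  expect_equal(unname(lr$max_rate["S1"]), 0.75)
  expect_equal(unname(lr$max_rate["S2"]), 1.0)
  expect_equal(lr$n_full, 1L)
  expect_equal(unname(rowSums(lr$rates)), rep(1, 2L))

  lrc <- loading_rates(assign, labels, "condition")
  expect_equal(unname(rowSums(lrc$rates)), rep(1, 2L))
  lrs <- loading_rates(assign, labels, "subject_condition_side")
  expect_equal(unname(rowSums(lrs$rates)), rep(1, lrs$n_groups))
})
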