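#' K-means clustering of a feature matrix
#'
#' K-means with the squared-Euclidean objective, restarted `restarts` times
#' from spread-out (kmeans++-style) initial centers drawn under a fixed seed;
#' the restart with the lowest within-cluster sum of squares (inertia) is
#' kept, so results are deterministic given the seed.
#'
#' @param fm Numeric matrix (typically a standardized `feature_matrix`).
#' @param k Number of clusters, `2 <= k <= nrow(fm)`.
#' @param seed Integer RNG seed.
#' @param restarts Number of random restarts (default 25).
#' @param compute_silhouette Attach per-row silhouette values (default TRUE).
#' @param d Optional precomputed `dist` object for the silhouette.
#' @return An object of class `cluster_result`: `k`, `assignments`,
#'   `silhouette`, `mean_silhouette`, `inertia`, `centers`, `seed`,
#'   `restarts`.
#' @export
kmeans_cluster <- function(fm, k, seed = 1L, restarts = 25L,
                           compute_silhouette = TRUE, d = NULL) {
  x <- unclass(fm)
  n <- nrow(x)
  if (!is.numeric(k) || length(k) != 1L || k < 2L || k > n) {
    stop("`k` must satisfy 2 <= k <= nrow(fm)", call. = FALSE)
  }
  k <- as.integer(k)
  if (k == n) {
    # every row its own cluster: inertia 0 by definition
    sil <- if (compute_silhouette) {
      silhouette_values(x, seq_len(n), d = d)
    } else {
      list(values = rep(NA_real_, n), mean = NA_real_)
    }
    return(structure(list(k = k, assignments = seq_len(n),
                          silhouette = sil$values,
                          mean_silhouette = sil$mean, inertia = 0,
                          centers = x, seed = as.integer(seed),
                          restarts = as.integer(restarts)),
                     class = "cluster_result"))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- x[kmeanspp_init(x, k), , drop = FALSE]
      km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                           iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  sil <- list(values = rep(NA_real_, n), mean = NA_real_)
  if (compute_silhouette) {
    sil <- silhouette_values(x, best$cluster, d = d)
  }
  structure(list(k = k, assignments = as.integer(best$cluster),
                 silhouette = sil$values, mean_silhouette = sil$mean,
                 inertia = best$tot.withinss, centers = best$centers,
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "cluster_result")
}

# kmeans++-style seeding: first center uniform, then each next center drawn
# with probability proportional to the squared distance to the nearest
# already-chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2L, x[centers[1L], ])^2)
  for (j in 2L:k) {
    if (all(d2 <= 0)) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[j], ])^2))
  }
  centers
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k =", x$k, " inertia =", signif(x$inertia, 6),
      " mean silhouette =", signif(x$mean_silhouette, 4), "\n")
  invisible(x)
}

#' Silhouette values of a clustering
#'
#' Standard silhouette widths under Euclidean distance: for each row,
#' (b - a) / max(a, b) where a is the mean distance to its own cluster and b
#' the mean distance to the nearest other cluster. Rows in singleton
#' clusters get width 0 by convention; an all-singleton clustering returns 0
#' for every row with a warning.
#'
#' @param fm Numeric matrix.
#' @param assignments Integer cluster ids, one per row.
#' @param d Optional precomputed `dist` object.
#' @return List with `values` (per row) and `mean`.
#' @export
silhouette_values <- function(fm, assignments, d = NULL) {
  x <- unclass(fm)
  n <- nrow(x)
  stopifnot(length(assignments) == n)
  if (length(unique(assignments)) < 2L) {
    stop("silhouette needs at least 2 clusters", call. = FALSE)
  }
  if (all(tabulate(match(assignments, unique(assignments))) == 1L)) {
    warning("all clusters are singletons; silhouette defined as 0")
    return(list(values = rep(0, n), mean = 0))
  }
  if (is.null(d)) d <- stats::dist(x)
  s <- cluster::silhouette(as.integer(assignments), d)
  vals <- as.numeric(s[, "sil_width"])
  list(values = vals, mean = mean(vals))
}

#' Select the number of clusters by mean silhouette
#'
#' Runs [kmeans_cluster()] for each candidate K and keeps the K with the
#' highest mean silhouette; ties are broken toward the smaller K. A message
#' records the chosen K and a warning is raised when even the best mean
#' silhouette is low (< 0.25), indicating little cluster structure.
#'
#' @param fm Numeric matrix.
#' @param k_candidates Candidate cluster counts (default `2:40`, clipped
#'   below `nrow(fm)`).
#' @param seed Integer RNG seed.
#' @param restarts Restarts per K.
#' @return An object of class `k_selection`: `best_k`, `silhouette_by_k`
#'   (data frame `k`, `mean_silhouette`), and `best` (the winning
#'   `cluster_result`).
#' @export
select_k <- function(fm, k_candidates = 2:40, seed = 1L, restarts = 25L) {
  n <- nrow(fm)
  if (length(k_candidates) == 0L) {
    stop("empty candidate set", call. = FALSE)
  }
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (any(k_candidates < 2L) || any(k_candidates > n - 1L)) {
    stop("k candidates must lie in 2..nrow(fm)-1", call. = FALSE)
  }
  d <- stats::dist(unclass(fm))
  results <- vector("list", length(k_candidates))
  sil <- numeric(length(k_candidates))
  for (i in seq_along(k_candidates)) {
    results[[i]] <- kmeans_cluster(fm, k_candidates[i], seed = seed + i - 1L,
                                   restarts = restarts, d = d)
    sil[i] <- results[[i]]$mean_silhouette
  }
  best_i <- which.max(sil)  # candidates ascending => ties go to smaller k
  if (sil[best_i] < 0.25) {
    warning("best mean silhouette is ", signif(sil[best_i], 3),
            "; little cluster structure detected")
  }
  message("select_k: best k = ", k_candidates[best_i],
          " (mean silhouette ", signif(sil[best_i], 4), ") over candidates ",
          k_candidates[1L], "..", k_candidates[length(k_candidates)])
  structure(list(best_k = k_candidates[best_i],
                 silhouette_by_k = data.frame(
                   k = k_candidates, mean_silhouette = sil),
                 best = results[[best_i]]),
            class = "k_selection")
}

#' Pairwise Euclidean distance matrix between trials
#'
#' @param fm Numeric matrix, one row per trial.
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(fm) {
  as.matrix(stats::dist(unclass(fm)))
}

#' Agglomerative merge tree of the trials
#'
#' Full hierarchical agglomeration of the rows under Euclidean distance.
#' The default linkage is Ward (consistent with the K-means variance
#' objective); single, complete and average linkage are available.
#'
#' @param fm Numeric matrix.
#' @param linkage One of `"ward.D2"`, `"single"`, `"complete"`, `"average"`.
#' @return An object of class `merge_tree`: the underlying `hclust`, merge
#'   `heights`, `merge` order and leaf `order`.
#' @export
merge_tree <- function(fm, linkage = c("ward.D2", "single", "complete",
                                       "average")) {
  linkage <- match.arg(linkage)
  x <- unclass(fm)
  if (nrow(x) < 2L) stop("merge tree needs >= 2 rows", call. = FALSE)
  hc <- stats::hclust(stats::dist(x), method = linkage)
  structure(list(hclust = hc, heights = hc$height, merge = hc$merge,
                 order = hc$order, linkage = linkage),
            class = "merge_tree")
}

#' Export a merge tree as Newick text
#'
#' @param tree A `merge_tree`.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
as_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "merge_tree"))
  hc <- tree$hclust
  if (is.null(hc$labels)) hc$labels <- paste0("t", seq_len(nrow(tree$merge) + 1L))
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Cluster loading rates per group
#'
#' For a grouping of the trials (by subject, by condition, or by subject x
#' condition x side), the loading rate of a group in a cluster is the number
#' of the group's trials in that cluster divided by the group's total trial
#' count; rates over clusters sum to 1 for every group. The per-group
#' maximum rate summarizes how concentrated the group is (a group entirely
#' in one cluster has maximum rate 1).
#'
#' @param assignments Integer cluster ids per row.
#' @param labels Row-label data frame (`subject`, `condition`, `side`).
#' @param grouping `"subject"`, `"condition"` or `"subject_condition_side"`.
#' @return An object of class `loading_rate_table`: `rates` (groups x
#'   clusters matrix), `max_rate`, `n_groups`, `n_full` (groups at rate 1)
#'   and `median_max`.
#' @export
loading_rates <- function(assignments, labels,
                          grouping = c("subject", "condition",
                                       "subject_condition_side")) {
  grouping <- match.arg(grouping)
  stopifnot(length(assignments) == nrow(labels))
  group <- switch(grouping,
    subject = factor(labels$subject),
    condition = factor(labels$condition),
    subject_condition_side = interaction(labels$subject, labels$condition,
                                         labels$side, drop = TRUE,
                                         sep = "_"))
  group <- droplevels(group)
  tab <- table(group, cluster = factor(assignments,
                                       levels = sort(unique(assignments))))
  rates <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  max_rate <- apply(rates, 1L, max)
  structure(list(grouping = grouping, rates = rates,
                 max_rate = max_rate, n_groups = nrow(rates),
                 n_full = sum(max_rate >= 1),
                 median_max = stats::median(max_rate)),
            class = "loading_rate_table")
}

#' @export
print.loading_rate_table <- function(x, ...) {
  cat("<loading_rate_table> grouping =", x$grouping, "\n",
      x$n_groups, "groups;", x$n_full, "at loading rate 1; median max rate",
      signif(x$median_max, 4), "\n")
  invisible(x)
}
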