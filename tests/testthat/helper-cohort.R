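# Small cohorts and independent oracles shared across the test files.

tiny_cohort <- function(n_subjects = 3L, n_trials = 2L, seed = 1L, ...) {
  generate_cohort(synth_config(n_subjects = n_subjects, n_trials = n_trials,
                               seed = seed, ...))
}

# Exhaustive K-means oracle: minimum within-cluster sum of squares over all
# assignments of n points to k labels (all k^n label vectors).
brute_force_inertia <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  idx <- rep(1L, n)
  repeat {
    if (length(unique(idx)) == k) {
      ss <- 0
      for (c in unique(idx)) {
        xc <- x[idx == c, , drop = FALSE]
        ss <- ss + sum(sweep(xc, 2L, colMeans(xc))^2)
      }
      best <- min(best, ss)
    }
    j <- 1L
    while (j <= n && idx[j] == k) { idx[j] <- 1L; j <- j + 1L }
    if (j > n) break
    idx[j] <- idx[j] + 1L
  }
  best
}

# Silhouette widths straight from the a(i)/b(i) definition.
brute_force_silhouette <- function(x, cl) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  n <- nrow(x)
  vapply(seq_len(n), function(i) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0L) return(0)  # singleton convention
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(c) {
      mean(d[i, cl == c])
    }, numeric(1L)))
    (b - a) / max(a, b)
  }, numeric(1L))
}

# Kruskal-Wallis H from the rank formula with tie correction.
brute_force_kw <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / sizes) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Friedman chi-square from within-block ranks (average ranks for ties).
brute_force_friedman <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1L, rank))
  rj <- colSums(r)
  num <- (k - 1) * sum((rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  num / den
}

# Mann-Whitney U and its exact permutation mean/SD (enumerating all splits).
brute_force_mw <- function(x, y) {
  n1 <- length(x)
  values <- c(x, y)
  r <- rank(values)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- combn(length(values), n1)
  us <- apply(splits, 2L, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  list(u = u_obs, z = (u_obs - mean(us)) / sd_pop(us))
}

sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

# Holm step-down applied literally: order p, compare p_(i) to alpha/(m-i+1),
# stop at the first failure.
brute_force_holm <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE else break
  }
  reject
}

# Exact upper binomial tail by direct summation of the pmf.
brute_force_binom_tail <- function(c, n, p) {
  if (c > n) return(0)
  sum(choose(n, c:n) * p^(c:n) * (1 - p)^(n - (c:n)))
}
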