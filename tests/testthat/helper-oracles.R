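# Brute-force / closed-form oracles, kept deliberately independent of the
# package's implementations: plain scans over all indices and exhaustive
# enumerations, used to pin down the fast paths.

# every interior index strictly above both neighbors; leftmost index of a
# plateau flanked by strictly lower values
oracle_local_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (y[i] <= y[i - 1]) next
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1
    if (j < n && y[j + 1] < y[i]) out <- c(out, i)
  }
  out
}

# topographic prominence straight from the definition: on each side find the
# minimum between the peak and the nearest strictly higher point (or the
# signal edge); prominence = height - max of the two side minima
oracle_prominence <- function(y, i) {
  n <- length(y)
  lo_l <- Inf
  for (j in (i - 1):1) {
    if (y[j] > y[i]) break
    lo_l <- min(lo_l, y[j])
  }
  lo_r <- Inf
  for (j in (i + 1):n) {
    if (y[j] > y[i]) break
    lo_r <- min(lo_r, y[j])
  }
  y[i] - max(lo_l, lo_r)
}

# nearest flanking local minima by plain scan (plateau pushed to far edge)
oracle_bounds <- function(y, i) {
  n <- length(y)
  left <- 1L
  for (j in (i - 1):1) {
    if (j > 1 && j < n && y[j] <= y[j - 1] && y[j] <= y[j + 1]) {
      while (j > 1 && y[j - 1] == y[j]) j <- j - 1L
      left <- j
      break
    }
  }
  right <- n
  for (j in (i + 1):n) {
    if (j > 1 && j < n && y[j] <= y[j - 1] && y[j] <= y[j + 1]) {
      while (j < n && y[j + 1] == y[j]) j <- j + 1L
      right <- j
      break
    }
  }
  c(left, right)
}

# trapezoid area by independent summation
oracle_area <- function(rt, y, l, r) {
  s <- 0
  for (j in l:(r - 1)) s <- s + (rt[j + 1] - rt[j]) * (y[j] + y[j + 1]) / 2
  s
}

# exhaustive k-means optimum: enumerate every assignment of n points to k
# labels, keep those using all k, return the minimum within-cluster SS
oracle_kmeans_optimum <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < k) next
    ss <- 0
    for (c in seq_len(k)) {
      pts <- x[a == c, , drop = FALSE]
      ss <- ss + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    best <- min(best, ss)
  }
  best
}

# ARI straight from the pair-counting formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); sa <- sum(ch2(rowSums(tab))); sb <- sum(ch2(colSums(tab)))
  e <- sa * sb / ch2(length(a))
  (sij - e) / ((sa + sb) / 2 - e)
}

# isotropic Gaussian blobs at mutually well-separated centers (>= 6
# within-class SDs apart: centers on scaled coordinate axes)
make_blobs <- function(K, n_per = 10, d = 10, sep = 8, seed = 1) {
  stopifnot(K <= d)
  with_seed_test(seed, {
    x <- do.call(rbind, lapply(seq_len(K), function(j) {
      center <- numeric(d); center[j] <- sep
      sweep(matrix(stats::rnorm(n_per * d), n_per, d), 2, -center)
    }))
    list(x = x, labels = rep(seq_len(K) - 1L, each = n_per))
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

random_trace <- function(n, seed) {
  with_seed_test(seed, cumsum(stats::rnorm(n)) + 2 * sin(seq_len(n) / 3))
}

# small scenario used by fast pipeline tests: 3 classes x 3 samples on a
# short axis, with band, abundance and width orders decoupled so the three
# class centroids sit well apart in every feature group
mini_scenario <- function(seed = 5L, noise_sd = 50) {
  shared <- list(peak_spec("shared-a", 2, 30000, 0.01, 0.02, 0.04),
                 peak_spec("shared-b", 6, 20000, 0.01, 0.02, 0.04))
  mk <- function(nm, rt, h, w) peak_spec(nm, rt, h, 0.01, 0.02, w)
  t1 <- class_template(0L, 3L, shared, list(mk("u1", 3.3, 50000, 0.05),
                                            mk("u2", 4.3, 60000, 0.05)))
  t2 <- class_template(1L, 3L, shared, list(mk("u3", 6.8, 90000, 0.035),
                                            mk("u4", 7.8, 75000, 0.035)))
  t3 <- class_template(2L, 3L, shared, list(mk("u5", 9.0, 30000, 0.042),
                                            mk("u6", 9.9, 40000, 0.042)))
  cohort_scenario(list(t1, t2, t3), rt_start = 0.5, rt_end = 10.5,
                  sampling_rate = 100, baseline_level = 1000,
                  baseline_drift_slope = 10, noise_sd = noise_sd, seed = seed,
                  name = "mini")
}
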