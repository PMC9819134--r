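# Stage-two clustering: k-means (++ seeding, Lloyd via stats::kmeans),
# normalized spectral clustering, DBSCAN, Ward agglomerative; elbow-based k
# selection; adjusted Rand index for evaluation against planted truth.

cluster_result <- function(algorithm, labels, k = NA_integer_,
                           seed = NA_integer_, inertia = NA_real_) {
  structure(list(algorithm = algorithm, k = as.integer(k),
                 labels = as.integer(labels), seed = seed, inertia = inertia),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sz <- cluster_sizes(x)
  cat(sprintf("<cluster_result> %s: n = %d, sizes %s%s\n", x$algorithm,
              length(x$labels), paste(sz$sizes, collapse = "/"),
              if (sz$noise > 0) sprintf(" (+%d noise)", sz$noise) else ""))
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center drawn with probability proportional to squared distance
# to the nearest chosen center. RNG state of the caller is used.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in 2:k) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

lloyd_once <- function(x, centers) {
  centers <- unique(centers)
  fit <- suppressWarnings(
    stats::kmeans(x, centers = centers, iter.max = 300L, algorithm = "Lloyd"))
  list(labels = fit$cluster - 1L, inertia = fit$tot.withinss,
       centers = fit$centers)
}

#' k-means clustering of a profile matrix
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ seedings, keeping
#' the best inertia over `n_restarts` restarts; deterministic given `seed`.
#'
#' @param x numeric matrix, samples in rows.
#' @param k number of clusters, `1 <= k <= nrow(x)`.
#' @param seed RNG seed.
#' @param n_restarts number of k-means++ restarts (default 10).
#' @param extra_inits optional list of center matrices tried in addition to
#'   the random restarts.
#' @return A `"cluster_result"` with 0-based `labels` and the achieved
#'   `inertia` (total within-cluster sum of squares).
#' @export
kmeans_cluster <- function(x, k, seed = 1L, n_restarts = 10L,
                           extra_inits = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is_count(k) || k < 1 || k > n)
    stop_fmt("k must lie in 1..%d", n)
  if (k == n) {  # every point its own cluster; inertia exactly 0
    res <- cluster_result("kmeans", seq_len(n) - 1L, k, seed, 0)
    res$centers <- x
    return(res)
  }
  if (k == 1L) {  # closed form: grand centroid
    res <- cluster_result("kmeans", rep(0L, n), 1L, seed,
                          sum(sweep(x, 2, colMeans(x))^2))
    res$centers <- matrix(colMeans(x), 1L, ncol(x))
    return(res)
  }
  best <- NULL
  with_seed(seed, {
    inits <- c(lapply(seq_len(n_restarts), function(r) kmeanspp_centers(x, k)),
               extra_inits)
    for (cen in inits) {
      fit <- lloyd_once(x, cen)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  u <- unique(best$labels)  # raw 0-based ids in first-appearance order
  res <- cluster_result("kmeans", match(best$labels, u) - 1L,
                        k, seed, best$inertia)
  res$centers <- best$centers[u + 1L, , drop = FALSE]  # rows follow new ids
  res
}

# relabel so cluster ids appear in order of first appearance (0-based)
relabel_first_appearance <- function(labels) {
  u <- unique(labels)
  match(labels, u) - 1L
}

#' k-means inertia curve over k = 1..k_max
#'
#' For each k the best-of-restarts k-means inertia is computed; each k > 1
#' additionally tries an initialization that splits the previous solution's
#' widest cluster, which guarantees the curve is non-increasing.
#'
#' @inheritParams kmeans_cluster
#' @param k_max largest k (<= `nrow(x)`).
#' @return An object of class `"inertia_curve"`: data.frame with columns
#'   `k`, `inertia`.
#' @export
inertia_curve <- function(x, k_max, seed = 1L, n_restarts = 10L) {
  x <- as.matrix(x)
  if (!is_count(k_max) || k_max < 1 || k_max > nrow(x))
    stop_fmt("k_max must lie in 1..%d", nrow(x))
  inertias <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    extra <- NULL
    if (!is.null(prev) && k <= nrow(x)) {
      # split init: previous centers plus the point farthest from its center
      d2 <- rowSums((x - prev$centers[prev$labels + 1L, , drop = FALSE])^2)
      extra <- list(rbind(prev$centers, x[which.max(d2), ]))
    }
    fit <- kmeans_cluster(x, k, seed = substream_seed(seed, k),
                          n_restarts = n_restarts, extra_inits = extra)
    inertias[k] <- fit$inertia
    prev <- if (k < nrow(x)) fit else NULL
    if (!is.null(prev) && is.null(prev$centers))
      prev <- NULL
  }
  structure(data.frame(k = seq_len(k_max), inertia = inertias),
            class = c("inertia_curve", "data.frame"))
}

#' Elbow-criterion selection of the number of clusters
#'
#' Formalizes the visual elbow as the k maximizing the second forward
#' difference of the inertia curve, d(k) = (I(k-1) - I(k)) - (I(k) - I(k+1)),
#' over k = 2..k_max-1 — the point where the curve bends from steep descent
#' to flat. Ties break toward the smaller k.
#'
#' @param curve an [inertia_curve()] (or data.frame with `k`, `inertia`)
#'   covering at least k = 1..3.
#' @return The selected k, integer.
#' @examples
#' select_k_elbow(data.frame(k = 1:6, inertia = c(1000, 600, 300, 50, 45, 42)))
#' @export
select_k_elbow <- function(curve) {
  I <- curve$inertia
  if (length(I) < 3) stop_fmt("inertia curve must cover at least k = 1..3")
  ks <- 2:(length(I) - 1)
  d <- (I[ks - 1] - I[ks]) - (I[ks] - I[ks + 1])
  as.integer(curve$k[ks[which.max(d)]])
}

#' Normalized spectral clustering
#'
#' The standard normalized recipe: RBF affinity
#' `A_ij = exp(-gamma * ||x_i - x_j||^2)` with the median heuristic
#' `gamma = 1 / (2 * median(pairwise squared distances))`, symmetric
#' normalized Laplacian `L = I - D^(-1/2) A D^(-1/2)`, row-unit-normalized
#' eigenvectors of the k smallest eigenvalues, then k-means in that
#' embedding.
#'
#' @inheritParams kmeans_cluster
#' @param k number of clusters, `2 <= k <= nrow(x)`.
#' @return A `"cluster_result"` with 0-based labels.
#' @export
spectral_cluster <- function(x, k, seed = 1L, n_restarts = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is_count(k) || k < 2 || k > n) stop_fmt("k must lie in 2..%d", n)
  d2 <- as.matrix(stats::dist(x))^2
  med <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(med) || med == 0)
    stop_fmt("degenerate affinity: all points coincide")
  A <- exp(-d2 / (2 * med))
  dg <- rowSums(A)
  Dinv <- 1 / sqrt(dg)
  L <- diag(n) - (Dinv %o% Dinv) * A
  eig <- eigen(L, symmetric = TRUE)
  U <- eig$vectors[, seq.int(n, n - k + 1L), drop = FALSE]  # k smallest
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  km <- kmeans_cluster(U, k, seed = seed, n_restarts = n_restarts)
  cluster_result("spectral", km$labels, k, seed, km$inertia)
}

#' DBSCAN density-based clustering
#'
#' Standard DBSCAN: points with at least `min_samples` neighbors within
#' `eps` (self included) are core points; clusters grow by
#' density-reachability from cores in row order (deterministic); border
#' points join the first core cluster that reaches them; the rest are noise,
#' labeled -1.
#'
#' @param x numeric matrix, samples in rows.
#' @param eps neighborhood radius (> 0).
#' @param min_samples core-point threshold (>= 1), self included.
#' @return A `"cluster_result"` with labels in `{-1, 0, 1, ...}`.
#' @export
dbscan_cluster <- function(x, eps, min_samples = 3L) {
  if (eps <= 0) stop_fmt("eps must be > 0")
  if (!is_count(min_samples) || min_samples < 1)
    stop_fmt("min_samples must be a count >= 1")
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_samples
  labels <- rep(-2L, n)  # -2 = unvisited, -1 = noise
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == -2L || labels[j] == -1L) {
        newly <- labels[j] == -2L
        labels[j] <- cl
        if (core[j] && newly)
          queue <- c(queue, setdiff(nbrs[[j]], which(labels != -2L)))
      }
    }
  }
  labels[labels == -2L] <- -1L
  cluster_result("dbscan", labels, if (cl >= 0L) cl + 1L else 0L)
}

# median distance to the m-th nearest neighbor: the conventional eps default
#' @rdname dbscan_cluster
#' @param m neighbor rank used by the `eps` heuristic.
#' @export
dbscan_eps_heuristic <- function(x, m = 3L) {
  d <- as.matrix(stats::dist(as.matrix(x)))
  knn <- apply(d, 1, function(r) sort(r)[m + 1L])
  stats::median(knn)
}

#' Ward agglomerative clustering
#'
#' Bottom-up merging under Ward's minimum-variance criterion on Euclidean
#' distances ([stats::hclust()] `"ward.D2"`), cut at `k` clusters. Labels are
#' 0-based in order of first appearance.
#'
#' @inheritParams kmeans_cluster
#' @return A `"cluster_result"`.
#' @export
agglomerative_cluster <- function(x, k) {
  x <- as.matrix(x)
  if (!is_count(k) || k < 1 || k > nrow(x))
    stop_fmt("k must lie in 1..%d", nrow(x))
  if (k == nrow(x))
    return(cluster_result("agglomerative", seq_len(nrow(x)) - 1L, k))
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(hc, k = k) - 1L
  cluster_result("agglomerative", relabel_first_appearance(labels), k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions
#' (up to relabeling), approximately 0 for independent random ones.
#'
#' @param labels_a,labels_b label vectors of equal length >= 2.
#' @return ARI in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_fmt("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2) stop_fmt("need at least 2 samples")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Cluster sizes of a clustering result
#'
#' @param result a `"cluster_result"`.
#' @return A list: `sizes` (named integer vector, counts per label in label
#'   order) and `noise` (count of DBSCAN noise points, 0 otherwise).
#' @export
cluster_sizes <- function(result) {
  labs <- result$labels
  noise <- sum(labs == -1L)
  pos <- labs[labs >= 0L]
  sizes <- if (length(pos)) {
    t <- table(factor(pos, levels = sort(unique(pos))))
    stats::setNames(as.integer(t), names(t))
  } else integer(0)
  list(sizes = sizes, noise = noise)
}
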