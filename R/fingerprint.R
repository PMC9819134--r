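#' Fit the full breath-fingerprinting pipeline
#'
#' Runs the two-stage analysis end to end on a cohort of chromatograms:
#' (1) per-sample peak detection with the significance filter and
#' reverse-biorthogonal DWT confirmation; (2) ten-feature profiling,
#' column standardization, elbow-based selection of the number of clusters
#' from the k-means inertia curve, and clustering with the chosen algorithm.
#'
#' @param chromatograms list of [chromatogram()]s (e.g.
#'   `generate_cohort(default_scenario())$chromatograms`).
#' @param params a [peak_params()].
#' @param algorithm clustering algorithm: `"spectral"` (default),
#'   `"kmeans"`, `"agglomerative"` or `"dbscan"`.
#' @param k number of clusters, or `"auto"` (default) to select by the elbow
#'   criterion; ignored by dbscan.
#' @param k_max largest k scanned by the inertia curve (default 10).
#' @param seed seed driving k-means restarts and spectral embedding k-means.
#' @param standardize_profiles z-score the feature columns before clustering
#'   (default TRUE).
#' @param confirm run DWT peak confirmation (default TRUE).
#' @param drop_unconfirmed drop peaks failing confirmation instead of merely
#'   flagging them (default FALSE).
#' @param eps,min_samples DBSCAN parameters; `eps = NULL` uses the median
#'   3-NN distance heuristic.
#' @return An object of class `"breath_fingerprint"`: list with elements
#'   `peak_tables`, `profiles` (raw matrix), `profiles_std`, `curve`
#'   (inertia curve, unless dbscan), `k`, `result` (a `cluster_result`),
#'   `labels` (named, 0-based), `params`, `algorithm`, `seed`, `call`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(default_scenario())
#' fit <- breath_fingerprint(cohort$chromatograms, seed = 7)
#' fit
#' adjusted_rand_index(fit$labels, cohort$labels)
#' }
#' @export
breath_fingerprint <- function(chromatograms,
                               params = peak_params(),
                               algorithm = c("spectral", "kmeans",
                                             "agglomerative", "dbscan"),
                               k = "auto", k_max = 10L, seed = 1L,
                               standardize_profiles = TRUE,
                               confirm = TRUE, drop_unconfirmed = FALSE,
                               eps = NULL, min_samples = 3L) {
  algorithm <- match.arg(algorithm)
  if (!length(chromatograms)) stop_fmt("no chromatograms supplied")
  rng <- range(unlist(lapply(chromatograms, function(c) range(c$rt))))
  peak_tables <- lapply(chromatograms, function(ch) {
    pt <- detect_peaks(ch, params)
    if (confirm) pt <- confirm_peaks(pt, ch, params)
    if (drop_unconfirmed) pt <- pt[pt$confirmed, , drop = FALSE]
    pt
  })
  profiles <- assemble_matrix(lapply(peak_tables, build_profile,
                                     rt_axis_range = rng))
  mat <- if (standardize_profiles) standardize(profiles) else profiles
  curve <- NULL
  if (algorithm != "dbscan") {
    if (identical(k, "auto")) {
      k_max <- min(k_max, nrow(mat))
      curve <- inertia_curve(mat, k_max, seed = seed)
      k <- select_k_elbow(curve)
    }
    k <- as.integer(k)
  }
  result <- switch(algorithm,
    spectral = spectral_cluster(mat, k, seed = seed),
    kmeans = kmeans_cluster(mat, k, seed = seed),
    agglomerative = agglomerative_cluster(mat, k),
    dbscan = {
      if (is.null(eps)) eps <- dbscan_eps_heuristic(mat, min_samples)
      dbscan_cluster(mat, eps, min_samples)
    })
  structure(list(peak_tables = peak_tables, profiles = profiles,
                 profiles_std = mat, curve = curve,
                 k = if (algorithm == "dbscan") result$k else k,
                 result = result,
                 labels = stats::setNames(result$labels, rownames(mat)),
                 params = params, algorithm = algorithm, seed = seed,
                 call = match.call()),
            class = "breath_fingerprint")
}

#' @export
print.breath_fingerprint <- function(x, ...) {
  sz <- cluster_sizes(x$result)
  n_peaks <- sum(vapply(x$peak_tables, nrow, integer(1)))
  cat("Breath-metabolome fingerprint\n")
  cat(sprintf("  samples: %d   significant peaks: %d (filter %s >= %g)\n",
              length(x$peak_tables), n_peaks, x$params$intensity_basis,
              x$params$min_intensity))
  cat(sprintf("  clustering: %s, k = %d   cluster sizes: %s%s\n",
              x$algorithm, x$k, paste(sz$sizes, collapse = "/"),
              if (sz$noise > 0) sprintf(" (+%d noise)", sz$noise) else ""))
  invisible(x)
}

#' @export
summary.breath_fingerprint <- function(object, ...) {
  x <- object
  sz <- cluster_sizes(x$result)
  counts <- vapply(x$peak_tables, nrow, integer(1))
  confirmed <- vapply(x$peak_tables, function(t) sum(t$confirmed), integer(1))
  print(x)
  cat(sprintf("  peaks/sample: median %g (range %d-%d); %.0f%% DWT-confirmed\n",
              stats::median(counts), min(counts), max(counts),
              100 * sum(confirmed) / max(1, sum(counts))))
  if (!is.null(x$curve)) {
    cat("  inertia curve:\n")
    print(x$curve, row.names = FALSE)
  }
  invisible(x)
}

#' Plot aspects of a fitted breath fingerprint
#'
#' @param x a `"breath_fingerprint"`.
#' @param type `"elbow"` (inertia curve), `"map"` (sample-to-cluster
#'   mapping), or `"profiles"` (parallel coordinates of the standardized
#'   features colored by cluster).
#' @param ... passed to the underlying base-graphics calls.
#' @return `x`, invisibly.
#' @export
plot.breath_fingerprint <- function(x, type = c("elbow", "map", "profiles"),
                                    ...) {
  type <- match.arg(type)
  if (type == "elbow") {
    if (is.null(x$curve)) stop_fmt("no inertia curve stored (k was fixed)")
    graphics::plot(x$curve$k, x$curve$inertia, type = "b", pch = 19,
                   xlab = "number of clusters k", ylab = "inertia", ...)
    graphics::abline(v = x$k, lty = 2)
  } else if (type == "map") {
    n <- length(x$labels)
    cols <- grDevices::hcl.colors(max(x$k, 2), "Dark 3")
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, n + 1), axes = FALSE,
                   xlab = "", ylab = "", ...)
    y_right <- (x$labels + 1) * n / (x$k + 1)
    graphics::segments(0, seq_len(n), 1, y_right, col = cols[x$labels + 1])
    graphics::text(0, seq_len(n), names(x$labels), pos = 2, cex = 0.6, xpd = NA)
    graphics::text(1, unique(y_right), paste("cluster", unique(x$labels)),
                   pos = 4, xpd = NA)
  } else {
    m <- x$profiles_std
    cols <- grDevices::hcl.colors(max(x$k, 2), "Dark 3")
    graphics::matplot(t(m), type = "l", lty = 1, col = cols[x$labels + 1],
                      xlab = "feature", ylab = "standardized value",
                      xaxt = "n", ...)
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  }
  invisible(x)
}
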