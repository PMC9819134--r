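#' Ten-feature profile of one chromatogram's peaks
#'
#' Condenses a sample's detected peaks into the fixed ten-feature
#' characteristic used for clustering:
#' \describe{
#'   \item{f0}{peak count}
#'   \item{f1}{mean peak height}
#'   \item{f2}{max peak height}
#'   \item{f3}{mean prominence}
#'   \item{f4}{mean width (min)}
#'   \item{f5}{total area}
#'   \item{f6}{mean area/intensity ratio}
#'   \item{f7}{retention time of the tallest peak (min)}
#'   \item{f8}{SD of peak retention times (min; population SD, 0 for a single peak)}
#'   \item{f9}{fraction of peaks eluting in the first half of the rt axis}
#' }
#' An empty peak table maps to the all-zero profile, keeping degenerate
#' samples clusterable.
#'
#' @param peak_table a peak table from [detect_peaks()].
#' @param rt_axis_range `c(lo, hi)` of the retention axis, minutes; must
#'   cover every peak rt.
#' @return Named numeric vector of length 10 with attribute `sample_id`.
#' @export
build_profile <- function(peak_table, rt_axis_range) {
  sid <- if (nrow(peak_table)) peak_table$sample_id[1] else "empty"
  if (nrow(peak_table) &&
      (any(peak_table$rt < rt_axis_range[1]) ||
       any(peak_table$rt > rt_axis_range[2])))
    stop_fmt("peak rt outside the axis range [%g, %g]",
             rt_axis_range[1], rt_axis_range[2])
  f <- if (nrow(peak_table) == 0) numeric(10) else {
    mid <- mean(rt_axis_range)
    n <- nrow(peak_table)
    c(n,
      mean(peak_table$height),
      max(peak_table$height),
      mean(peak_table$prominence),
      mean(peak_table$width),
      sum(peak_table$area),
      mean(peak_table$ratio),
      peak_table$rt[which.max(peak_table$height)],
      sqrt(sum((peak_table$rt - mean(peak_table$rt))^2) / n),
      mean(peak_table$rt <= mid))
  }
  names(f) <- paste0("f", 0:9)
  attr(f, "sample_id") <- sid
  f
}

#' Assemble per-sample profiles into a cohort matrix
#'
#' @param profiles list of [build_profile()] outputs with unique sample ids.
#' @return An object of class `"profile_matrix"`: numeric matrix (samples x
#'   10 features, rownames = sample ids) with attribute
#'   `standardized = FALSE`.
#' @export
assemble_matrix <- function(profiles) {
  if (!length(profiles)) stop_fmt("no profiles supplied")
  ids <- vapply(profiles, function(p) attr(p, "sample_id"), character(1))
  if (anyDuplicated(ids))
    stop_fmt("duplicate sample_id '%s'", ids[duplicated(ids)][1])
  m <- do.call(rbind, lapply(profiles, as.numeric))
  dimnames(m) <- list(ids, paste0("f", 0:9))
  structure(m, standardized = FALSE, class = c("profile_matrix", "matrix", "array"))
}

#' Column z-score a profile matrix
#'
#' Each feature column is centered and scaled to unit population SD; a
#' zero-variance column maps to all zeros (it carries no clustering
#' information either way). Distance-based clustering is meaningless on the
#' raw features, which span orders of magnitude (peak counts vs. areas), so
#' the pipeline standardizes by default.
#'
#' @param m a `"profile_matrix"` with `standardized = FALSE`.
#' @return The standardized matrix, `standardized = TRUE`.
#' @export
standardize <- function(m) {
  if (isTRUE(attr(m, "standardized")))
    stop_fmt("matrix is already standardized")
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(sweep(m, 2, mu)^2))
  out <- sweep(m, 2, mu)
  nz <- sdv > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sdv[nz], "/")
  out[, !nz] <- 0
  structure(out, standardized = TRUE,
            class = c("profile_matrix", "matrix", "array"))
}
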