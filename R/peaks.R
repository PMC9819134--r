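#' Peak-detection parameters
#'
#' Bundles the stage-one tuning knobs: the 10,000-unit significance filter,
#' which per-peak quantity that filter (and the area ratio) uses, the width
#' measurement height, and the wavelet-confirmation settings.
#'
#' The filter quantity deserves a note: a chromatographic "intensity"
#' threshold can be read as raw peak height or as topographic prominence
#' (how much the peak stands out relative to its surroundings). Prominence is
#' the default basis because it is invariant to baseline level; raw height is
#' available via `intensity_basis = "height"`. Both are recorded per peak.
#'
#' @param min_intensity significance filter, detector units (default 10000).
#' @param intensity_basis `"prominence"` (default) or `"height"`; the
#'   quantity compared against `min_intensity` and used as the denominator of
#'   the area/intensity ratio.
#' @param width_rel_height fraction of prominence below the apex at which
#'   peak width is measured (default 0.5 = half prominence).
#' @param wavelet_member reverse-biorthogonal member for confirmation
#'   (default `"rbio2.2"`).
#' @param confirm_levels DWT levels whose approximations must co-locate a
#'   maximum with the peak (default `c(1, 2)`).
#' @param confirm_rt_tol co-location tolerance in minutes (default 0.1).
#' @param confirm_min_retention fraction of the peak's height the co-located
#'   approximation maximum must retain (default 0.5): a genuine peak, wider
#'   than the wavelet filter support, passes through the lowpass nearly
#'   intact, while a single-sample spike loses most of its amplitude to the
#'   detail bands.
#' @return An object of class `"peak_params"`.
#' @export
peak_params <- function(min_intensity = 10000,
                        intensity_basis = c("prominence", "height"),
                        width_rel_height = 0.5,
                        wavelet_member = "rbio2.2",
                        confirm_levels = c(1L, 2L),
                        confirm_rt_tol = 0.1,
                        confirm_min_retention = 0.5) {
  intensity_basis <- match.arg(intensity_basis)
  if (min_intensity <= 0) stop_fmt("min_intensity must be > 0")
  if (width_rel_height <= 0 || width_rel_height >= 1)
    stop_fmt("width_rel_height must lie in (0, 1)")
  if (confirm_rt_tol <= 0) stop_fmt("confirm_rt_tol must be > 0")
  if (!all(confirm_levels %in% c(1L, 2L)))
    stop_fmt("confirm_levels must be a subset of {1, 2}")
  if (confirm_min_retention < 0 || confirm_min_retention > 1)
    stop_fmt("confirm_min_retention must lie in [0, 1]")
  structure(list(min_intensity = min_intensity,
                 intensity_basis = intensity_basis,
                 width_rel_height = width_rel_height,
                 wavelet_member = wavelet_member,
                 confirm_levels = as.integer(sort(unique(confirm_levels))),
                 confirm_rt_tol = confirm_rt_tol,
                 confirm_min_retention = confirm_min_retention),
            class = "peak_params")
}

#' Find local maxima of an intensity trace
#'
#' An interior index is a maximum when it exceeds both neighbors; a plateau
#' of equal values flanked by strictly lower values counts once, at its
#' leftmost index. Endpoints are never maxima.
#'
#' @param intensity numeric vector, length >= 3.
#' @return Integer vector of 1-based maxima positions.
#' @examples
#' find_local_maxima(c(0, 1, 0, 5, 0))
#' @export
find_local_maxima <- function(intensity) {
  n <- length(intensity)
  if (n < 3) stop_fmt("need at least 3 points to find local maxima")
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (intensity[i] > intensity[i - 1L]) {
      j <- i
      while (j < n && intensity[j + 1L] == intensity[i]) j <- j + 1L
      if (j < n && intensity[j + 1L] < intensity[i]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Topographic prominence of a peak
#'
#' Height of the peak above the higher of the two valley minima that separate
#' it from nearer higher terrain on each side (or from the signal edge where
#' no higher terrain exists).
#'
#' @param intensity numeric trace.
#' @param peak_index 1-based index of a local maximum of `intensity`.
#' @return Prominence in detector units.
#' @examples
#' prominence_of(c(0, 6, 2, 10, 0), 2)  # 4: the valley at 2 separates it
#' @export
prominence_of <- function(intensity, peak_index) {
  assert_local_max(intensity, peak_index)
  h <- intensity[peak_index]
  n <- length(intensity)
  left <- intensity[seq_len(peak_index - 1L)]
  higher_l <- which(left > h)
  lo_l <- if (length(higher_l)) min(left[seq.int(max(higher_l), peak_index - 1L)])
          else min(left)
  right <- intensity[seq.int(peak_index + 1L, n)]
  higher_r <- which(right > h)
  lo_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))])
          else min(right)
  h - max(lo_l, lo_r)
}

assert_local_max <- function(intensity, peak_index) {
  n <- length(intensity)
  if (peak_index <= 1L || peak_index >= n)
    stop_fmt("index %d is not an interior point", peak_index)
  # allow the leftmost index of a plateau maximum
  j <- peak_index
  while (j < n && intensity[j + 1L] == intensity[peak_index]) j <- j + 1L
  ok <- intensity[peak_index] > intensity[peak_index - 1L] &&
    j < n && intensity[j + 1L] < intensity[peak_index]
  if (!ok) stop_fmt("index %d is not a local maximum", peak_index)
  invisible(TRUE)
}

#' Integration bounds of a peak
#'
#' The nearest local minima flanking the peak: on each side, the first index
#' whose value does not exceed either of its neighbors; the signal edge is
#' used where no such minimum exists. On a flat valley the bound extends to
#' the far edge of the plateau (leftmost on the left flank, rightmost on the
#' right), keeping bounds deterministic.
#'
#' @inheritParams prominence_of
#' @return Integer vector `c(left_index, right_index)`, 1-based.
#' @examples
#' integration_bounds(c(0, 1, 0, 3, 0, 2, 0), 4)  # c(3, 5)
#' @export
integration_bounds <- function(intensity, peak_index) {
  assert_local_max(intensity, peak_index)
  n <- length(intensity)
  is_min <- function(i) i > 1L && i < n &&
    intensity[i] <= intensity[i - 1L] && intensity[i] <= intensity[i + 1L]
  left <- 1L
  for (i in seq.int(peak_index - 1L, 1L)) {
    if (is_min(i)) {
      while (i > 1L && intensity[i - 1L] == intensity[i]) i <- i - 1L
      left <- i; break
    }
  }
  right <- n
  for (i in seq.int(peak_index + 1L, n)) {
    if (is_min(i)) {
      while (i < n && intensity[i + 1L] == intensity[i]) i <- i + 1L
      right <- i; break
    }
  }
  c(left, right)
}

#' Area under a peak
#'
#' Trapezoidal integral of intensity over retention time between the two
#' integration bounds; no baseline is subtracted.
#'
#' @param chrom a [chromatogram()].
#' @param left_index,right_index 1-based grid bounds, `left < right`.
#' @return Area in detector units x minutes.
#' @export
peak_area <- function(chrom, left_index, right_index) {
  if (left_index >= right_index) stop_fmt("reversed integration bounds")
  if (left_index < 1L || right_index > length(chrom$rt))
    stop_fmt("integration bounds outside the grid")
  idx <- seq.int(left_index, right_index)
  x <- chrom$rt[idx]; y <- chrom$intensity[idx]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# width at `rel` of prominence below the apex, linear interpolation on both
# flanks, clipped at the integration bounds (scipy peak_widths convention)
peak_width_at <- function(chrom, peak_index, prominence, left_index,
                          right_index, rel) {
  y <- chrom$intensity; x <- chrom$rt
  target <- y[peak_index] - prominence * rel
  li <- peak_index
  while (li > left_index && y[li - 1L] > target) li <- li - 1L
  left_x <- if (li == left_index && y[li] > target) x[li] else if (y[li - 1L] == y[li]) x[li - 1L] else
    x[li - 1L] + (x[li] - x[li - 1L]) * (target - y[li - 1L]) / (y[li] - y[li - 1L])
  ri <- peak_index
  while (ri < right_index && y[ri + 1L] > target) ri <- ri + 1L
  right_x <- if (ri == right_index && y[ri] > target) x[ri] else if (y[ri + 1L] == y[ri]) x[ri + 1L] else
    x[ri] + (x[ri + 1L] - x[ri]) * (target - y[ri]) / (y[ri] - y[ri + 1L])
  right_x - left_x
}

empty_peak_table <- function(sample_id = character(0)) {
  df <- data.frame(sample_id = character(0), index = integer(0),
                   rt = double(0), height = double(0), prominence = double(0),
                   width = double(0), left_index = integer(0),
                   right_index = integer(0), left_rt = double(0),
                   right_rt = double(0), area = double(0), ratio = double(0),
                   confirmed = logical(0), stringsAsFactors = FALSE)
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Detect significant peaks in a chromatogram
#'
#' Stage-one peak detection: local maxima are found, their topographic
#' prominence computed, peaks whose filter quantity (prominence by default)
#' falls below `min_intensity` are discarded, and each surviving peak gets
#' its neighboring-local-minima integration bounds, trapezoidal area,
#' area/intensity ratio and interpolated width. The `confirmed` flag starts
#' `FALSE`; see [confirm_peaks()].
#'
#' @param chrom a [chromatogram()].
#' @param params a [peak_params()].
#' @return A `peak_table` data.frame sorted by retention time with columns
#'   `sample_id`, `index`, `rt`, `height`, `prominence`, `width`,
#'   `left_index`, `right_index`, `left_rt`, `right_rt`, `area`, `ratio`,
#'   `confirmed`.
#' @examples
#' rt <- seq(0, 5, by = 0.01)
#' ch <- chromatogram(rt, 20000 * exp(-(rt - 2)^2 / (2 * 0.05^2)))
#' detect_peaks(ch)
#' @export
detect_peaks <- function(chrom, params = peak_params()) {
  validate_chromatogram(chrom)
  maxima <- find_local_maxima(chrom$intensity)
  if (!length(maxima)) return(empty_peak_table())
  rows <- lapply(maxima, function(i) {
    prom <- prominence_of(chrom$intensity, i)
    basis <- if (params$intensity_basis == "prominence") prom
             else chrom$intensity[i]
    if (basis < params$min_intensity) return(NULL)
    b <- integration_bounds(chrom$intensity, i)
    area <- peak_area(chrom, b[1], b[2])
    data.frame(sample_id = chrom$sample_id, index = i, rt = chrom$rt[i],
               height = chrom$intensity[i], prominence = prom,
               width = peak_width_at(chrom, i, prom, b[1], b[2],
                                     params$width_rel_height),
               left_index = b[1], right_index = b[2],
               left_rt = chrom$rt[b[1]], right_rt = chrom$rt[b[2]],
               area = area, ratio = area / basis, confirmed = FALSE,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_peak_table())
  out <- do.call(rbind, rows)
  out <- out[order(out$rt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Confirm peaks against DWT approximations
#'
#' A detected peak is confirmed when, at every requested decomposition level,
#' the lowpass approximation of the chromatogram has a local maximum within
#' `confirm_rt_tol` minutes of the peak's retention time whose value retains
#' at least `confirm_min_retention` of the peak's height. Genuine
#' chromatographic peaks are wider than the wavelet filter support and
#' survive the lowpass nearly intact; single-sample spikes lose most of
#' their amplitude to the detail bands and fail the retention condition.
#' Unconfirmed peaks are flagged, not dropped.
#'
#' @param peak_table output of [detect_peaks()] for `chrom`.
#' @param chrom the [chromatogram()] the table derives from.
#' @param params a [peak_params()].
#' @return The peak table with its `confirmed` column filled in.
#' @export
confirm_peaks <- function(peak_table, chrom, params = peak_params()) {
  if (nrow(peak_table) == 0) return(peak_table)
  if (!all(peak_table$sample_id == chrom$sample_id))
    stop_fmt("peak table (%s) does not belong to chromatogram (%s)",
             peak_table$sample_id[1], chrom$sample_id)
  ok <- rep(TRUE, nrow(peak_table))
  for (lev in params$confirm_levels) {
    approx <- dwt_approximation(chrom$intensity, lev, params$wavelet_member)
    apx_ix <- find_local_maxima(approx)
    apx_rt <- chrom$rt[apx_ix]
    ok <- ok & vapply(seq_len(nrow(peak_table)), function(j) {
      r <- peak_table$rt[j]
      near <- which(abs(apx_rt - r) <= params$confirm_rt_tol)
      length(near) > 0 &&
        max(approx[apx_ix[near]]) >=
          params$confirm_min_retention * peak_table$height[j]
    }, logical(1))
  }
  peak_table$confirmed <- ok
  peak_table
}

#' Pooled retention-time histogram of detected peaks
#'
#' Counts all peaks from all samples in equal-width retention-time bins over
#' the samples' common axis range: where in the run the cohort's significant
#' compounds concentrate.
#'
#' @param peak_tables list of peak tables sharing one rt axis range.
#' @param n_bins number of equal-width bins (>= 1).
#' @param rt_range optional `c(lo, hi)` axis range; defaults to the pooled
#'   peak range.
#' @return data.frame with columns `bin_left`, `bin_right`, `count`.
#' @export
peak_density <- function(peak_tables, n_bins, rt_range = NULL) {
  if (!length(peak_tables)) stop_fmt("no peak tables supplied")
  if (!is_count(n_bins) || n_bins < 1) stop_fmt("n_bins must be a count >= 1")
  rts <- unlist(lapply(peak_tables, function(t) t$rt))
  if (is.null(rt_range)) {
    rt_range <- if (length(rts)) range(rts) else c(0, 1)
    if (diff(rt_range) == 0) rt_range <- rt_range + c(-0.5, 0.5)
  }
  breaks <- seq(rt_range[1], rt_range[2], length.out = n_bins + 1L)
  counts <- if (length(rts))
    tabulate(pmin(pmax(findInterval(rts, breaks, rightmost.closed = TRUE), 1L),
                  n_bins), nbins = n_bins)
  else integer(n_bins)
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
             count = counts)
}
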