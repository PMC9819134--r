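#' Construct a chromatogram
#'
#' A chromatogram is one sample's GC/MS trace: a strictly increasing
#' retention-time axis (minutes) and a finite intensity vector (arbitrary
#' detector units) of the same length. It is the raw input consumed by every
#' stage-one operator ([detect_peaks()], [dwt_approximation()], ...).
#'
#' @param rt numeric vector of retention times in minutes, strictly
#'   increasing, length >= 8.
#' @param intensity numeric vector of detector intensities, same length as
#'   `rt`, all finite.
#' @param sample_id character scalar identifying the sample.
#' @return An object of class `"chromatogram"`: a list with elements
#'   `sample_id`, `rt`, `intensity`.
#' @examples
#' ch <- chromatogram(seq(0, 1, by = 0.1), c(0, 1, 4, 9, 16, 9, 4, 1, 0, 0, 0))
#' ch
#' @export
chromatogram <- function(rt, intensity, sample_id = "sample") {
  rt <- as.double(rt)
  intensity <- as.double(intensity)
  obj <- structure(
    list(sample_id = as.character(sample_id)[1], rt = rt, intensity = intensity),
    class = "chromatogram"
  )
  validate_chromatogram(obj)
}

#' Validate a chromatogram's invariants
#'
#' Checks length agreement, minimum size (8 points), strict monotonicity of
#' the retention axis and finiteness of intensities; errors on violation.
#'
#' @param x a `"chromatogram"` object.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_chromatogram <- function(x) {
  if (!inherits(x, "chromatogram")) stop_fmt("not a chromatogram")
  if (length(x$rt) != length(x$intensity))
    stop_fmt("rt and intensity lengths differ (%d vs %d)",
             length(x$rt), length(x$intensity))
  if (length(x$rt) < 8)
    stop_fmt("chromatogram has %d points; at least 8 required", length(x$rt))
  if (anyNA(x$rt) || any(!is.finite(x$rt)))
    stop_fmt("non-finite retention times")
  if (any(diff(x$rt) <= 0))
    stop_fmt("retention times must be strictly increasing (violation near row %d)",
             which(diff(x$rt) <= 0)[1] + 1)
  if (anyNA(x$intensity) || any(!is.finite(x$intensity)))
    stop_fmt("non-finite intensities")
  x
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s: %d points, rt %.3f-%.3f min, intensity [%.4g, %.4g]\n",
              x$sample_id, length(x$rt), min(x$rt), max(x$rt),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
length.chromatogram <- function(x) length(x$rt)

#' @export
plot.chromatogram <- function(x, ..., peaks = NULL) {
  graphics::plot(x$rt, x$intensity, type = "l",
                 xlab = "retention time [min]", ylab = "intensity [a.u.]",
                 main = x$sample_id, ...)
  if (!is.null(peaks) && nrow(peaks) > 0) {
    graphics::points(peaks$rt, peaks$height, pch = 4, col = "red")
  }
  invisible(x)
}
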