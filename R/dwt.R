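# Discrete wavelet transform with reverse-biorthogonal spline wavelets.
#
# Implemented as a classic two-channel biorthogonal filter bank with
# half-point symmetric boundary extension. Filter coefficients below are the
# analysis/synthesis quadruples of the reverse-biorthogonal family (the
# biorthogonal spline filters with decomposition and reconstruction roles
# swapped); rbio2.2 is the default member used for peak confirmation.

.rbio_filters <- list(
  "rbio2.2" = list(
    dec_lo = c(0, 0, 0.3535533905932738, 0.7071067811865476,
               0.3535533905932738, 0),
    dec_hi = c(0.1767766952966369, 0.3535533905932738, -1.0606601717798212,
               0.3535533905932738, 0.1767766952966369, 0),
    rec_lo = c(-0.1767766952966369, 0.3535533905932738, 1.0606601717798212,
               0.3535533905932738, -0.1767766952966369, 0),
    rec_hi = c(0, 0, 0.3535533905932738, -0.7071067811865476,
               0.3535533905932738, 0)
  )
)

wavelet_filters <- function(wavelet_member) {
  f <- .rbio_filters[[wavelet_member]]
  if (is.null(f))
    stop_fmt("unknown wavelet member '%s' (available: %s)", wavelet_member,
             paste(names(.rbio_filters), collapse = ", "))
  f
}

# half-point symmetric extension by p points on each side
sym_extend <- function(x, p) {
  n <- length(x)
  if (p > n) stop_fmt("signal too short for symmetric extension")
  c(rev(x[seq_len(p)]), x, rev(x[seq.int(n - p + 1L, n)]))
}

# one analysis step: convolve the symmetric extension with `filt`, keep every
# second sample; output length floor((n + F - 1)/2)
dwt_step <- function(x, filt) {
  F_len <- length(filt)
  xp <- sym_extend(x, F_len - 1L)
  full <- stats::convolve(xp, rev(filt), type = "open")
  out_len <- (length(x) + F_len - 1L) %/% 2L
  full[seq.int(F_len + 1L, by = 2L, length.out = out_len)]
}

# one synthesis step from approximation+detail coefficients
idwt_step <- function(cA, cD, rec_lo, rec_hi) {
  if (length(cA) != length(cD)) stop_fmt("coefficient length mismatch")
  F_len <- length(rec_lo)
  up <- function(c) { u <- numeric(2L * length(c)); u[seq(1L, by = 2L, length.out = length(c))] <- c; u }
  full <- stats::convolve(up(cA), rev(rec_lo), type = "open") +
          stats::convolve(up(cD), rev(rec_hi), type = "open")
  L <- 2L * length(cA) - F_len + 2L
  full[seq.int(F_len - 1L, length.out = L)]
}

# multilevel analysis: list(cA_L, cD_L, cD_{L-1}, ..., cD_1)
wavedec <- function(x, level, filters) {
  if (level < 1) stop_fmt("level must be >= 1")
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    if (length(a) < length(filters$dec_lo))
      stop_fmt("signal too short (%d points) for level-%d decomposition",
               length(x), level)
    d <- dwt_step(a, filters$dec_hi)
    a <- dwt_step(a, filters$dec_lo)
    details[[level - l + 1L]] <- d
  }
  c(list(a), details)
}

# multilevel synthesis, trimming each step to the recorded detail length + 1
# at most (mirrors the coefficient bookkeeping of the analysis side)
waverec <- function(coeffs, filters) {
  a <- coeffs[[1L]]
  for (d in coeffs[-1L]) {
    if (length(a) == length(d) + 1L) a <- a[-length(a)]
    a <- idwt_step(a, d, filters$rec_lo, filters$rec_hi)
  }
  a
}

#' Lowpass (approximation) reconstruction of a signal at a DWT level
#'
#' Decomposes the signal with the reverse-biorthogonal filter bank to the
#' requested level, zeroes every detail band, and reconstructs back to the
#' original grid. The result is the smooth approximation the peak-confirmation
#' step compares detected peaks against: genuine chromatographic peaks
#' survive the lowpass, single-sample spikes do not.
#'
#' @param intensity numeric signal vector.
#' @param level decomposition level, 1 or 2.
#' @param wavelet_member filter family member; currently `"rbio2.2"`.
#' @return Numeric vector of the same length as `intensity`.
#' @examples
#' x <- dnorm(seq(-4, 4, length.out = 64))
#' a <- dwt_approximation(x, level = 2)
#' length(a) == length(x)
#' @export
dwt_approximation <- function(intensity, level, wavelet_member = "rbio2.2") {
  if (!is_count(level) || !(level %in% c(1, 2)))
    stop_fmt("level must be 1 or 2")
  filters <- wavelet_filters(wavelet_member)
  if (length(intensity) < length(filters$dec_lo) * 2^level)
    stop_fmt("signal of %d points too short for level %d with a %d-tap filter",
             length(intensity), level, length(filters$dec_lo))
  coeffs <- wavedec(as.double(intensity), level, filters)
  for (i in seq_along(coeffs)[-1L])
    coeffs[[i]] <- numeric(length(coeffs[[i]]))
  out <- waverec(coeffs, filters)
  out[seq_along(intensity)]
}

# full reconstruction (approximation + all details): used by tests to assert
# the perfect-reconstruction property of the filter bank
dwt_reconstruct <- function(intensity, level, wavelet_member = "rbio2.2") {
  filters <- wavelet_filters(wavelet_member)
  coeffs <- wavedec(as.double(intensity), level, filters)
  waverec(coeffs, filters)[seq_along(intensity)]
}
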