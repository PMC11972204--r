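#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with the conventional shape: response
#' peak at 6 s, undershoot peak at 16 s, peak-to-undershoot ratio 6:1. The
#' sampled kernel is normalized so that its discrete integral is 1, making
#' the convolution of a long boxcar plateau at the injected amplitude.
#'
#' @param t Time points in seconds (>= 0).
#' @param peak Response peak time (s).
#' @param undershoot Undershoot peak time (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return HRF values at `t` (unnormalized; see [hrf_kernel()]).
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  stopifnot(peak > 0, undershoot > 0, ratio > 0)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

#' Sampled, integral-normalized HRF kernel
#'
#' @param tr_s Sampling interval (s).
#' @param duration_s Kernel support (s); the canonical response has decayed
#'   by 32 s.
#' @param ... Passed to [hrf_double_gamma()].
#' @return Numeric kernel with `sum(kernel) * tr_s == 1`.
#' @export
hrf_kernel <- function(tr_s, duration_s = 32, ...) {
  stopifnot(tr_s > 0)
  t <- seq(0, duration_s, by = tr_s)
  h <- hrf_double_gamma(t, ...)
  h / (sum(h) * tr_s)
}

#' Sample a boxcar from an events table onto the TR grid
#'
#' Each volume's value is the fraction of its acquisition interval covered
#' by events of the requested condition, so non-TR-aligned (percept) onsets
#' contribute fractionally rather than being rounded.
#'
#' @param events Events table (see [validate_events()]).
#' @param condition Condition label to extract.
#' @param n_volumes,tr_s Run geometry.
#' @return Numeric vector of length `n_volumes` in `[0, 1]`.
#' @export
event_boxcar <- function(events, condition, n_volumes, tr_s) {
  ev <- events[events$trial_type == condition, , drop = FALSE]
  box <- numeric(n_volumes)
  if (nrow(ev) == 0L) return(box)
  vol_start <- (seq_len(n_volumes) - 1) * tr_s
  vol_end <- vol_start + tr_s
  for (i in seq_len(nrow(ev))) {
    a <- ev$onset[i]
    b <- a + ev$duration[i]
    ov <- pmin(vol_end, b) - pmax(vol_start, a)
    box <- box + pmax(ov, 0) / tr_s
  }
  pmin(box, 1)
}

#' Convolve a TR-sampled boxcar with the HRF kernel
#'
#' @param box Boxcar vector (one value per volume).
#' @param kernel HRF kernel from [hrf_kernel()].
#' @param tr_s Sampling interval (s).
#' @return Regressor of the same length as `box`; plateau equals the boxcar
#'   plateau for blocks much longer than the kernel support.
#' @export
convolve_hrf <- function(box, kernel, tr_s) {
  n <- length(box)
  full <- stats::convolve(box, rev(kernel), type = "open") * tr_s
  full[seq_len(n)]
}
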