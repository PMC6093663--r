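#' Shift a series so its minimum is zero
#'
#' @param values Numeric vector.
#' @return `values - min(values)`.
#' @export
shift_to_min <- function(values) {
  if (!length(values)) stop("empty series", call. = FALSE)
  values - min(values)
}

#' Centered moving average with shrunken edge windows
#'
#' Interior points are the mean of a centered window of `window` points (for
#' even `window` the extra point falls on the trailing side); near the edges
#' the window shrinks to the available samples, so the output has the same
#' length as the input and no group delay is introduced.
#'
#' @param values Numeric vector.
#' @param window Window length in samples (default 10, i.e. 1 s at 10 Hz).
#' @return Smoothed vector, same length.
#' @export
moving_average <- function(values, window = 10) {
  n <- length(values)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (window > n) stop("window longer than series", call. = FALSE)
  if (window == 1) return(values)
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Apply a symmetric Hann window
#'
#' `w[n] = 0.5 * (1 - cos(2*pi*n/(N-1)))`, n = 0..N-1, so both endpoints are
#' exactly zero: the tapering removes the discontinuity that would otherwise
#' appear when the FFT treats the segment as periodic.
#'
#' @param values Numeric vector, length >= 2.
#' @return Windowed vector.
#' @export
hann_window <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 samples to window", call. = FALSE)
  values * 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Run the full conditioning chain on a ROI segment
#'
#' Fixed order: minimum subtraction, 10-point moving average, Hann window.
#' The order is recorded in the result for provenance.
#'
#' @param seg A `roi_segment` (or bare numeric vector).
#' @param smooth_window Moving-average length in samples.
#' @return A list of class `conditioned_segment`: `values`, `source`,
#'   `steps_applied`.
#' @export
condition_segment <- function(seg, smooth_window = 10) {
  raw <- if (inherits(seg, "roi_segment")) seg$values else as.numeric(seg)
  out <- hann_window(moving_average(shift_to_min(raw), smooth_window))
  structure(list(
    values = out,
    source = if (inherits(seg, "roi_segment")) seg else NULL,
    steps_applied = c("shift", "smooth", "window")
  ), class = "conditioned_segment")
}
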