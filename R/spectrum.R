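#' Normalized single-sided amplitude spectrum of a conditioned segment
#'
#' Amplitudes are `2 * |X_k| / N` for bins k = 1..N/2 (the DC bin is dropped),
#' with no compensation for the Hann window's coherent gain of 0.5. Under
#' this convention a windowed sine of unit amplitude shows about 0.5 at its
#' bin, so a rhythm's physical peak-to-peak pressure is four times the
#' spectrum amplitude: a factor of 2 from the windowing and a factor of 2
#' from peak-to-peak being twice the sine amplitude (see [sine_model()]).
#' Frequencies are reported in cycles/min; the bin spacing is
#' `rate * 60 / N` (0.29296875 cycles/min at 10 Hz, N = 2048).
#'
#' @param seg A `conditioned_segment` (or numeric vector already
#'   conditioned), length a power of two.
#' @param sample_rate Hz; taken from the segment's source ROI when available.
#' @param channel_name Label carried into the spectrum.
#' @return A list of class `amplitude_spectrum`: `frequencies` (cycles/min,
#'   bins 1..N/2), `amplitudes`, `n_samples`, `sample_rate`, `channel_name`.
#' @export
amplitude_spectrum <- function(seg, sample_rate = NULL, channel_name = NULL) {
  if (inherits(seg, "conditioned_segment")) {
    values <- seg$values
    if (!is.null(seg$source)) {
      sample_rate <- sample_rate %||% seg$source$sample_rate
      channel_name <- channel_name %||% seg$source$channel_name
    }
  } else {
    values <- as.numeric(seg)
  }
  sample_rate <- sample_rate %||% 10
  channel_name <- channel_name %||% "signal"
  n <- length(values)
  if (n < 2 || bitwAnd(n, n - 1L) != 0L)
    stop("segment length must be a power of two (got ", n, ")", call. = FALSE)
  x <- stats::fft(values)
  k <- seq_len(n %/% 2)
  structure(list(
    frequencies = k * sample_rate * 60 / n,
    amplitudes = 2 * Mod(x[k + 1L]) / n,
    n_samples = n, sample_rate = sample_rate, channel_name = channel_name
  ), class = "amplitude_spectrum")
}

#' Bins inside the analysis band
#'
#' The band defaults to 1.75-6.0 cycles/min, the range where rhythmic
#' detrusor activity has been reported; boundaries are inclusive. With N =
#' 2048 at 10 Hz this selects bins 6-20 (1.758 to 5.859 cycles/min).
#'
#' @param spec An `amplitude_spectrum`.
#' @param lo,hi Band edges in cycles/min.
#' @return Integer vector of bin indices (bin k has frequency
#'   `k * rate * 60 / N`).
#' @export
band_bins <- function(spec, lo = 1.75, hi = 6.0) {
  if (lo >= hi) stop("band lower edge must be below upper edge", call. = FALSE)
  k <- which(spec$frequencies >= lo & spec$frequencies <= hi)
  if (!length(k)) stop("no spectrum bins fall inside the band", call. = FALSE)
  k
}

#' Sine-wave model of a detected rhythm
#'
#' Reconstructs the ideal sine implied by one spectral peak: its peak-to-peak
#' pressure is exactly four times the spectrum amplitude at the peak bin (2x
#' window gain, 2x amplitude-to-peak-to-peak). The model can be overlaid on
#' the raw tracing for visual confirmation.
#'
#' @param frequency Peak frequency, cycles/min.
#' @param fft_amplitude Spectrum amplitude at the peak, normalized units.
#' @return A list of class `sine_model`: `frequency`, `fft_amplitude`,
#'   `peak_to_peak` (cm-H2O).
#' @export
sine_model <- function(frequency, fft_amplitude) {
  if (frequency <= 0 || fft_amplitude <= 0)
    stop("frequency and amplitude must be positive", call. = FALSE)
  structure(list(frequency = frequency, fft_amplitude = fft_amplitude,
                 peak_to_peak = 4 * fft_amplitude),
            class = "sine_model")
}

#' Evaluate a sine model as a time series
#'
#' @param model A `sine_model`.
#' @param time Sample times, seconds.
#' @param offset Vertical offset added to the sine, cm-H2O.
#' @return Numeric vector `offset + (p2p/2) * sin(2*pi*f*t/60)`.
#' @export
sine_model_series <- function(model, time, offset = 0) {
  offset + model$peak_to_peak / 2 * sin(2 * pi * model$frequency * time / 60)
}

#' Write a spectrum as two-column TSV (cycles/min, amplitude)
#' @param spec An `amplitude_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  writeLines(c("frequency_cpm\tamplitude",
               sprintf("%.8f\t%.8f", spec$frequencies, spec$amplitudes)),
             path)
  invisible(path)
}
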