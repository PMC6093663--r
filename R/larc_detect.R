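#' Analysis configuration
#'
#' Bundles every tunable of the detection pipeline. The defaults are the
#' published operating point: 2048-sample window at 10 Hz, 1.75-6.0
#' cycles/min band, amplitude floor 0.45 normalized FFT units (1.8 cm-H2O in
#' model peak-to-peak terms, since peak-to-peak = 4 x FFT amplitude), 20%
#' per-bin prominence slope, independence ratios 1.5 (vesical over abdominal),
#' 1.33 (abdominal flatness) and 2.0 (unconditional dominance), three peaks,
#' window ends 0/30/60 s before void.
#'
#' @param band_lo_cpm,band_hi_cpm Analysis band, cycles/min.
#' @param amp_threshold Significance amplitude floor, normalized FFT units.
#' @param slope_fraction Prominence slope per frequency bin (0.20 = 20%).
#' @param ratio1 Vesical/abdominal ratio for independence rule A.
#' @param flatness Abdominal peak-to-neighbor flatness bound, rule B.
#' @param ratio2 Unconditional vesical dominance ratio, rule C.
#' @param n_peaks Number of vesical peaks evaluated.
#' @param roi_samples Window length in samples (power of two).
#' @param sample_rate Analysis rate, Hz.
#' @param offsets Window end offsets before void, seconds.
#' @param void_threshold_ml Void-onset detection threshold, ml.
#' @param smooth_window Moving-average length, samples.
#' @return A list of class `larc_config`.
#' @export
larc_config <- function(band_lo_cpm = 1.75, band_hi_cpm = 6.0,
                        amp_threshold = 0.45, slope_fraction = 0.20,
                        ratio1 = 1.5, flatness = 1.33, ratio2 = 2.0,
                        n_peaks = 3, roi_samples = 2048, sample_rate = 10,
                        offsets = c(0, 30, 60), void_threshold_ml = 1,
                        smooth_window = 10) {
  structure(list(band_lo_cpm = band_lo_cpm, band_hi_cpm = band_hi_cpm,
                 amp_threshold = amp_threshold,
                 slope_fraction = slope_fraction, ratio1 = ratio1,
                 flatness = flatness, ratio2 = ratio2, n_peaks = n_peaks,
                 roi_samples = roi_samples, sample_rate = sample_rate,
                 offsets = offsets, void_threshold_ml = void_threshold_ml,
                 smooth_window = smooth_window),
            class = "larc_config")
}

spec_amp <- function(spec, bin) {
  # amplitude at a 1-based spectrum bin, NA outside the spectrum
  if (bin < 1 || bin > length(spec$amplitudes)) NA_real_
  else spec$amplitudes[bin]
}

#' Find the largest local maxima of the vesical spectrum inside the band
#'
#' A peak is a bin (or a plateau of equal bins, represented by its
#' lowest-frequency member) whose amplitude is strictly greater than the
#' adjacent amplitudes in the full spectrum; at the spectrum boundary the
#' single available neighbor decides. Peaks are ranked by descending
#' amplitude, ties toward lower frequency.
#'
#' @param spec An `amplitude_spectrum` (vesical channel).
#' @param band Bin indices from [band_bins()].
#' @param n Maximum number of peaks returned (default 3).
#' @return A list of unscored `peak_evaluation` objects (possibly fewer than
#'   `n`), each with the peak bin, frequency, amplitude and the two
#'   neighboring amplitudes on each side.
#' @export
find_top_peaks <- function(spec, band, n = 3) {
  a <- spec$amplitudes
  m <- length(a)
  # collapse plateaus: runs of equal amplitude
  r <- rle(a)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  k <- length(r$values)
  left_ok <- c(TRUE, r$values[-1L] > r$values[-k])
  right_ok <- c(r$values[-k] > r$values[-1L], TRUE)
  peak_bins <- run_start[left_ok & right_ok]
  peak_bins <- peak_bins[peak_bins %in% band]
  if (!length(peak_bins)) return(list())
  ord <- order(-a[peak_bins], peak_bins)
  peak_bins <- peak_bins[ord][seq_len(min(n, length(peak_bins)))]

  lapply(seq_along(peak_bins), function(i) {
    b <- peak_bins[i]
    structure(list(
      rank = i, bin = b, frequency = spec$frequencies[b],
      pves_amplitude = a[b],
      neighbors_left = c(spec_amp(spec, b - 2L), spec_amp(spec, b - 1L)),
      neighbors_right = c(spec_amp(spec, b + 1L), spec_amp(spec, b + 2L)),
      pabd_at_bin = NA_real_, pabd_neighbors = c(NA_real_, NA_real_),
      significant = NA, independent = NA,
      criterion_detail = list()
    ), class = "peak_evaluation")
  })
}

#' Significance test for one vesical peak
#'
#' A peak is significant when (1) its amplitude exceeds `amp_threshold`
#' (strictly), and (2) it is prominent on both sides: on each side, at least
#' one of the two neighbors must lie at or below the line descending from the
#' peak at `slope_fraction` of the peak amplitude per bin (so a neighbor at
#' distance d qualifies when its amplitude is at most
#' `peak * (1 - slope_fraction * d)`). A side with both neighbors missing
#' (peak at the spectrum boundary) fails and the reason is recorded.
#'
#' @param peak A `peak_evaluation` from [find_top_peaks()].
#' @param amp_threshold Amplitude floor, FFT units (default 0.45).
#' @param slope_fraction Prominence slope per bin (default 0.20).
#' @return The peak with `significant` and `criterion_detail` filled in.
#' @export
test_significance <- function(peak, amp_threshold = 0.45,
                              slope_fraction = 0.20) {
  a <- peak$pves_amplitude
  amp_ok <- a > amp_threshold

  in_region <- function(nb, d) !is.na(nb) && nb <= a * (1 - slope_fraction * d)
  # neighbors_left = amplitudes at bins -2, -1; neighbors_right at +1, +2
  left_ok <- in_region(peak$neighbors_left[2L], 1) ||
    in_region(peak$neighbors_left[1L], 2)
  right_ok <- in_region(peak$neighbors_right[1L], 1) ||
    in_region(peak$neighbors_right[2L], 2)

  detail <- list(
    amplitude = list(pass = amp_ok, value = a, threshold = amp_threshold),
    left_prominence = list(
      pass = left_ok,
      reason = if (all(is.na(peak$neighbors_left))) "no left neighbors" else NULL),
    right_prominence = list(
      pass = right_ok,
      reason = if (all(is.na(peak$neighbors_right))) "no right neighbors" else NULL)
  )
  peak$significant <- amp_ok && left_ok && right_ok
  peak$criterion_detail <- utils::modifyList(peak$criterion_detail, detail)
  peak
}

#' Independence test of a significant vesical peak against the abdominal
#' spectrum
#'
#' With `a` the vesical amplitude, `b0` the abdominal amplitude at the same
#' bin and `bL`, `bR` its immediate abdominal neighbors:
#' * rule A: `a > ratio1 * max(b0, bL, bR)` (vesical clearly above abdominal);
#' * rule B: `b0 < flatness * max(bL, bR)` (no sharp abdominal peak);
#' * rule C: `a > ratio2 * max(b0, bL, bR)` (vesical dominates outright,
#'   regardless of any abdominal peak).
#' The peak is independent when (A and B) or C.
#'
#' @param peak A significant `peak_evaluation`.
#' @param pabd_spec The abdominal `amplitude_spectrum` from the same window.
#' @param ratio1,flatness,ratio2 Rule thresholds (defaults 1.5, 1.33, 2.0).
#' @return The peak with `independent`, the abdominal amplitudes and rule
#'   detail filled in.
#' @export
test_independence <- function(peak, pabd_spec, ratio1 = 1.5,
                              flatness = 1.33, ratio2 = 2.0) {
  if (!isTRUE(peak$significant))
    stop("independence is only evaluated for significant peaks",
         call. = FALSE)
  b <- peak$bin
  b0 <- spec_amp(pabd_spec, b)
  bL <- spec_amp(pabd_spec, b - 1L)
  bR <- spec_amp(pabd_spec, b + 1L)
  a <- peak$pves_amplitude
  bmax <- max(b0, bL, bR, na.rm = TRUE)
  nbmax <- suppressWarnings(max(bL, bR, na.rm = TRUE)) # -Inf if both missing

  rule_a <- a > ratio1 * bmax
  rule_b <- is.finite(nbmax) && b0 < flatness * nbmax
  rule_c <- a > ratio2 * bmax

  peak$pabd_at_bin <- b0
  peak$pabd_neighbors <- c(bL, bR)
  peak$independent <- (rule_a && rule_b) || rule_c
  peak$criterion_detail <- utils::modifyList(peak$criterion_detail, list(
    rule_a = list(pass = rule_a, ratio = ratio1),
    rule_b = list(pass = rule_b, flatness = flatness),
    rule_c = list(pass = rule_c, ratio = ratio2)
  ))
  peak
}

#' Classify one analysis window from its paired spectra
#'
#' Finds up to `n_peaks` vesical band peaks, applies the significance test to
#' each, the independence test to the significant ones, and assigns the study
#' category: `"no_significant"`, `"significant_not_independent"`, or
#' `"significant_and_independent"` (S&I) when any peak passes both. The
#' slowest S&I frequency and its sine model are reported for S&I studies.
#'
#' @param pves_spec,pabd_spec Vesical and abdominal `amplitude_spectrum`
#'   objects from the same window of the same study.
#' @param config A [larc_config()].
#' @param study_id,roi_offset_s Metadata carried into the result.
#' @return A list of class `larc_result`.
#' @export
classify_study <- function(pves_spec, pabd_spec, config = larc_config(),
                           study_id = "study", roi_offset_s = NA_real_) {
  band <- band_bins(pves_spec, config$band_lo_cpm, config$band_hi_cpm)
  peaks <- find_top_peaks(pves_spec, band, config$n_peaks)
  peaks <- lapply(peaks, test_significance,
                  amp_threshold = config$amp_threshold,
                  slope_fraction = config$slope_fraction)
  peaks <- lapply(peaks, function(p) {
    if (isTRUE(p$significant))
      test_independence(p, pabd_spec, config$ratio1, config$flatness,
                        config$ratio2)
    else { p$independent <- FALSE; p }
  })

  any_sig <- any(vapply(peaks, function(p) isTRUE(p$significant), logical(1)))
  indep <- vapply(peaks, function(p) isTRUE(p$independent), logical(1))
  category <- if (any(indep)) "significant_and_independent"
  else if (any_sig) "significant_not_independent"
  else "no_significant"

  slowest_freq <- NA_real_
  slowest_model <- NULL
  if (any(indep)) {
    si <- peaks[indep]
    freqs <- vapply(si, `[[`, numeric(1), "frequency")
    pick <- si[[which.min(freqs)]]
    slowest_freq <- pick$frequency
    slowest_model <- sine_model(pick$frequency, pick$pves_amplitude)
  }

  structure(list(
    study_id = study_id, roi_offset_s = roi_offset_s, category = category,
    peaks = peaks, slowest_si_frequency = slowest_freq,
    slowest_si_model = slowest_model
  ), class = "larc_result")
}

#' @export
print.larc_result <- function(x, ...) {
  cat(sprintf("<larc_result> %s (window end offset %g s): %s\n",
              x$study_id, x$roi_offset_s, x$category))
  for (p in x$peaks)
    cat(sprintf("  peak %d: %.3f cycles/min amp %.3f  sig=%s indep=%s\n",
                p$rank, p$frequency, p$pves_amplitude, p$significant,
                p$independent))
  if (!is.na(x$slowest_si_frequency))
    cat(sprintf("  slowest S&I: %.3f cycles/min, model p2p %.2f cm-H2O\n",
                x$slowest_si_frequency, x$slowest_si_model$peak_to_peak))
  invisible(x)
}

#' Run the full detection pipeline on a recording
#'
#' For each window offset: extract the vesical and abdominal ROI, condition
#' (shift, smooth, Hann window), transform to amplitude spectra, and
#' classify. The recording must pass [validate_for_analysis()]; the
#' `any_si` flag is the OR of the per-offset S&I outcomes.
#'
#' @param rec A uniform `uds_recording` at the analysis rate.
#' @param config A [larc_config()]; `config$offsets` selects the windows.
#' @return A list of class `larc_study_report`: `study_id`, `results` (one
#'   `larc_result` per offset), `any_si`.
#' @export
analyze_recording <- function(rec, config = larc_config()) {
  elig <- validate_for_analysis(rec, volume_threshold = config$void_threshold_ml)
  if (!elig$eligible)
    stop("recording ineligible: ", paste(elig$reasons, collapse = "; "),
         call. = FALSE)
  results <- lapply(config$offsets, function(off) {
    specs <- lapply(c("p_ves", "p_abd"), function(ch) {
      roi <- extract_roi(rec, ch, end_offset_s = off,
                         roi_samples = config$roi_samples,
                         volume_threshold = config$void_threshold_ml)
      amplitude_spectrum(condition_segment(roi, config$smooth_window))
    })
    classify_study(specs[[1L]], specs[[2L]], config,
                   study_id = rec$study_id, roi_offset_s = off)
  })
  names(results) <- paste0("offset_", config$offsets)
  any_si <- any(vapply(results, function(r)
    r$category == "significant_and_independent", logical(1)))
  structure(list(study_id = rec$study_id, results = results, any_si = any_si),
            class = "larc_study_report")
}

#' @export
print.larc_study_report <- function(x, ...) {
  cat(sprintf("<larc_study_report> %s  any-offset S&I: %s\n", x$study_id,
              x$any_si))
  for (r in x$results)
    cat(sprintf("  offset %g s: %s\n", r$roi_offset_s, r$category))
  invisible(x)
}
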