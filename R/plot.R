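#' Plot a study's pressure tracings and paired spectra
#'
#' Two panels: the vesical and abdominal tracings with the analysis window
#' shaded (and, for an S&I study, the detected sine model overlaid on the
#' vesical trace), and the paired amplitude spectra with the analysis band
#' shaded.
#'
#' @param rec The analyzed `uds_recording`.
#' @param report A `larc_study_report` from [analyze_recording()].
#' @param config The [larc_config()] used.
#' @param offset Which window offset to display (default: first configured).
#' @return Invisibly, `NULL`.
#' @export
plot_larc_study <- function(rec, report, config = larc_config(),
                            offset = config$offsets[1L]) {
  res <- report$results[[paste0("offset_", offset)]]
  roi_v <- extract_roi(rec, "p_ves", offset, config$roi_samples,
                       config$void_threshold_ml)
  roi_a <- extract_roi(rec, "p_abd", offset, config$roi_samples,
                       config$void_threshold_ml)
  spec_v <- amplitude_spectrum(condition_segment(roi_v, config$smooth_window))
  spec_a <- amplitude_spectrum(condition_segment(roi_a, config$smooth_window))

  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))

  rng <- range(rec$channels$p_ves, rec$channels$p_abd)
  plot(rec$time, rec$channels$p_ves, type = "l", col = "steelblue",
       xlab = "time (s)", ylab = "pressure (cm-H2O)", ylim = rng,
       main = sprintf("%s - %s", rec$study_id, res$category))
  graphics::lines(rec$time, rec$channels$p_abd, col = "tomato")
  t0 <- roi_v$start_time
  t1 <- t0 + length(roi_v$values) / roi_v$sample_rate
  graphics::rect(t0, rng[1], t1, rng[2], col = grDevices::adjustcolor(
    "green", 0.15), border = NA)
  if (!is.null(res$slowest_si_model)) {
    tt <- seq(t0, t1, by = 1 / roi_v$sample_rate)
    graphics::lines(tt, sine_model_series(res$slowest_si_model, tt,
                                          offset = mean(roi_v$values)),
                    lty = 2)
  }
  graphics::legend("topleft", legend = c("P_ves", "P_abd"), bty = "n",
                   col = c("steelblue", "tomato"), lty = 1)

  keep <- spec_v$frequencies <= 12
  plot(spec_v$frequencies[keep], spec_v$amplitudes[keep], type = "b",
       pch = 20, col = "steelblue", xlab = "frequency (cycles/min)",
       ylab = "normalized amplitude")
  graphics::lines(spec_a$frequencies[keep], spec_a$amplitudes[keep],
                  type = "b", pch = 20, col = "tomato")
  usr <- graphics::par("usr")
  graphics::rect(config$band_lo_cpm, usr[3], config$band_hi_cpm, usr[4],
                 col = grDevices::adjustcolor("gray", 0.3), border = NA)
  invisible(NULL)
}
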