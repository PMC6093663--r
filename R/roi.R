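#' Locate the onset of the voiding event
#'
#' The void onset is the time of the first sample at which voided volume
#' exceeds `volume_threshold` and stays above it for the rest of the
#' recording; brief sub-threshold jitter from the flowmeter never triggers.
#'
#' @param rec A `uds_recording` with a `voided_volume` channel.
#' @param volume_threshold Threshold in ml (default 1).
#' @return Onset time in seconds, or `NA` for a no-void study.
#' @export
detect_void_onset <- function(rec, volume_threshold = 1) {
  v <- rec$channels$voided_volume
  if (is.null(v)) stop("recording has no voided_volume channel", call. = FALSE)
  above <- v > volume_threshold
  if (!any(above)) return(NA_real_)
  # first index after the last sub-threshold sample
  last_below <- max(which(!above), 0L)
  if (last_below == length(v)) return(NA_real_)
  rec$time[last_below + 1L]
}

#' Extract the fixed-length analysis window (region of interest)
#'
#' The region of interest (ROI) is a contiguous slice of exactly
#' `roi_samples` points (2048 at 10 Hz = 204.8 s) ending `end_offset_s`
#' seconds before the void onset. For no-void studies the window is anchored
#' to the end of the recording instead. The slice is pure: no padding or
#' interpolation.
#'
#' @param rec A uniform `uds_recording` at the analysis rate.
#' @param channel Channel name, e.g. `"p_ves"` or `"p_abd"`.
#' @param end_offset_s Seconds between the window end and the void onset
#'   (canonical values 0, 30, 60).
#' @param roi_samples Window length in samples (default 2048, a power of two).
#' @param volume_threshold Void detection threshold in ml.
#' @return A list of class `roi_segment` with `channel_name`, `values`,
#'   `start_time`, `end_offset_s`, `void_onset_time` and `sample_rate`.
#' @export
extract_roi <- function(rec, channel, end_offset_s = 30, roi_samples = 2048,
                        volume_threshold = 1) {
  if (!is_uniform(rec))
    stop("recording must be uniformly sampled; call resample_uniform() first",
         call. = FALSE)
  vals <- rec$channels[[channel]]
  if (is.null(vals)) stop("no such channel: ", channel, call. = FALSE)
  rate <- rec$sample_rate
  onset <- detect_void_onset(rec, volume_threshold)

  # index one past the window end (0-based arithmetic on the uniform grid)
  if (is.na(onset)) {
    end_idx <- length(vals) - round(end_offset_s * rate)
  } else {
    end_idx <- round((onset - rec$time[1L] - end_offset_s) * rate)
  }
  start_idx <- end_idx - roi_samples # 0-based index of first sample
  if (start_idx < 0L || end_idx > length(vals)) {
    need <- roi_samples / rate + end_offset_s
    have <- if (is.na(onset)) diff(range(rec$time)) else onset - rec$time[1L]
    stop(sprintf(
      "insufficient pre-void data for ROI: need %.1f s, have %.1f s",
      need, have), call. = FALSE)
  }

  structure(list(
    channel_name = channel,
    values = vals[(start_idx + 1L):end_idx],
    start_time = rec$time[start_idx + 1L],
    end_offset_s = end_offset_s,
    void_onset_time = onset,
    sample_rate = rate
  ), class = "roi_segment")
}

#' @export
print.roi_segment <- function(x, ...) {
  cat(sprintf(
    "<roi_segment> %s: %d samples @ %g Hz from %.1f s (ends %g s before %s)\n",
    x$channel_name, length(x$values), x$sample_rate, x$start_time,
    x$end_offset_s,
    if (is.na(x$void_onset_time)) "recording end"
    else sprintf("void at %.1f s", x$void_onset_time)))
  invisible(x)
}
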