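#' Construct a multichannel urodynamic recording
#'
#' A `uds_recording` holds uniformly sampled pressure and volume channels from
#' a single fill-void cycle: vesical pressure (`p_ves`, cm-H2O), abdominal
#' pressure (`p_abd`, cm-H2O), voided volume (ml), and optionally detrusor
#' pressure (`p_det = p_ves - p_abd`), infused volume and flow. Clinician
#' labels (detrusor overactivity, etiology) ride along as metadata.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing.
#' @param p_ves Vesical pressure series, cm-H2O.
#' @param p_abd Abdominal pressure series, cm-H2O.
#' @param voided_volume Voided volume series, ml; non-negative and
#'   non-decreasing up to `volume_slack_ml`.
#' @param p_det Optional detrusor pressure; derived as `p_ves - p_abd` when
#'   `derive_p_det = TRUE` and not supplied.
#' @param infused_volume,flow Optional infused volume (ml) and flow (ml/s).
#' @param study_id Study identifier.
#' @param sample_rate Sampling rate in Hz; when `NULL`, inferred from `time`.
#' @param do_label Clinician detrusor-overactivity flag: "yes", "no" or
#'   "unknown".
#' @param etiology_label "neurogenic", "idiopathic" or "unknown".
#' @param derive_p_det Derive `p_det` from the pressures when absent.
#' @param volume_slack_ml Permitted transient decrease in voided volume
#'   (flowmeter jitter) before the monotonicity invariant fails.
#'
#' @return An object of class `uds_recording`.
#' @export
uds_recording <- function(time, p_ves, p_abd, voided_volume,
                          p_det = NULL, infused_volume = NULL, flow = NULL,
                          study_id = "study", sample_rate = NULL,
                          do_label = "unknown", etiology_label = "unknown",
                          derive_p_det = TRUE, volume_slack_ml = 0.5) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 1L) stop("recording must contain at least one sample", call. = FALSE)
  if (n > 1L && any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)

  channels <- list(p_ves = p_ves, p_abd = p_abd, voided_volume = voided_volume,
                   p_det = p_det, infused_volume = infused_volume, flow = flow)
  channels <- channels[!vapply(channels, is.null, logical(1))]
  channels <- lapply(channels, as.numeric)
  bad <- names(channels)[vapply(channels, length, integer(1)) != n]
  if (length(bad))
    stop("channel length mismatch with time: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (req in c("p_ves", "p_abd", "voided_volume"))
    if (is.null(channels[[req]]))
      stop("required channel missing: ", req, call. = FALSE)

  if (derive_p_det && is.null(channels$p_det))
    channels$p_det <- channels$p_ves - channels$p_abd

  vv <- channels$voided_volume
  if (any(vv < -volume_slack_ml))
    stop("voided_volume has negative values beyond slack", call. = FALSE)
  if (n > 1L && any(diff(vv) < -volume_slack_ml))
    stop("voided_volume decreases by more than the slack tolerance",
         call. = FALSE)

  if (is.null(sample_rate)) {
    sample_rate <- if (n > 1L) 1 / stats::median(diff(time)) else NA_real_
  }

  do_label <- match.arg(do_label, c("yes", "no", "unknown"))
  etiology_label <- match.arg(etiology_label,
                              c("neurogenic", "idiopathic", "unknown"))

  structure(
    list(study_id = study_id, sample_rate = sample_rate, time = time,
         channels = channels, do_label = do_label,
         etiology_label = etiology_label),
    class = "uds_recording"
  )
}

#' @export
print.uds_recording <- function(x, ...) {
  dur <- if (length(x$time) > 1) diff(range(x$time)) else 0
  cat(sprintf("<uds_recording> %s: %d samples @ %.6g Hz (%.1f s)\n",
              x$study_id, length(x$time), x$sample_rate, dur))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat(sprintf("  DO label: %s, etiology: %s\n", x$do_label, x$etiology_label))
  invisible(x)
}

#' Test whether a recording is sampled on a uniform grid
#'
#' @param rec A `uds_recording`.
#' @param tol Maximum deviation of any time step from `1/sample_rate`, seconds.
#' @return Logical scalar.
#' @export
is_uniform <- function(rec, tol = 1e-6) {
  if (length(rec$time) < 2L) return(TRUE)
  all(abs(diff(rec$time) - 1 / rec$sample_rate) < tol)
}

#' Number of samples in a recording
#' @param rec A `uds_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$time)
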