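#' Column mapping and parsing policy for delimited UDS exports
#'
#' Urodynamics machines export studies as delimited ASCII with one column per
#' channel; the dialect (delimiter, column names, units) varies by vendor and
#' site. A format config names the columns that hold each channel. The
#' canonical dialect written by [write_uds_export()] is tab-delimited with a
#' header row and a `time` column in seconds.
#'
#' @param time,p_ves,p_abd,voided_volume Column names of the required
#'   channels. `time = NULL` means no time column: a uniform grid at
#'   `sample_rate` starting at 0 is assumed.
#' @param p_det,infused_volume,flow Column names of optional channels, or
#'   `NULL` when absent from the export.
#' @param delimiter Field delimiter ("\t" default, "," supported).
#' @param sample_rate Hz; used when `time` is `NULL` and recorded as the
#'   nominal rate otherwise.
#' @param missing Policy for missing numeric cells: `"error"` or `"ffill"`
#'   (forward fill; leading missing values are back-filled from the first
#'   observed value).
#' @return A list of class `uds_format` used by [read_uds_export()].
#' @export
uds_format <- function(time = "time", p_ves = "p_ves", p_abd = "p_abd",
                       voided_volume = "voided_volume", p_det = NULL,
                       infused_volume = NULL, flow = NULL,
                       delimiter = "\t", sample_rate = 10,
                       missing = c("error", "ffill")) {
  structure(list(
    columns = list(time = time, p_ves = p_ves, p_abd = p_abd,
                   voided_volume = voided_volume, p_det = p_det,
                   infused_volume = infused_volume, flow = flow),
    delimiter = delimiter, sample_rate = sample_rate,
    missing = match.arg(missing)
  ), class = "uds_format")
}

#' Read a format config from a YAML file
#'
#' Recognised keys: `delimiter`, `sample_rate`, `missing`, and a `columns`
#' block mapping channel names to export column names.
#'
#' @param path YAML file path.
#' @return A `uds_format`.
#' @export
read_uds_format <- function(path) {
  cfg <- yaml::read_yaml(path)
  cols <- cfg$columns %||% list()
  uds_format(
    time = cols$time %||% "time",
    p_ves = cols$p_ves %||% "p_ves",
    p_abd = cols$p_abd %||% "p_abd",
    voided_volume = cols$voided_volume %||% "voided_volume",
    p_det = cols$p_det, infused_volume = cols$infused_volume,
    flow = cols$flow,
    delimiter = cfg$delimiter %||% "\t",
    sample_rate = cfg$sample_rate %||% 10,
    missing = cfg$missing %||% "error"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

forward_fill <- function(x) {
  na <- is.na(x)
  if (!any(na)) return(x)
  idx <- cumsum(!na)
  filled <- c(NA_real_, x[!na])[idx + 1L]
  # leading NAs: back-fill from the first observation
  if (anyNA(filled) && any(!na)) filled[is.na(filled)] <- x[which(!na)[1L]]
  filled
}

#' Read a delimited urodynamics export
#'
#' @param path Path to the delimited text file (one header row).
#' @param format_config A [uds_format()] naming the columns; default matches
#'   the canonical dialect of [write_uds_export()].
#' @param study_id Identifier; defaults to the file name without extension.
#' @param ... Passed on to [uds_recording()] (labels, slack).
#' @return A [uds_recording()].
#' @export
read_uds_export <- function(path, format_config = uds_format(),
                            study_id = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = format_config$delimiter,
                      check.names = FALSE, colClasses = "numeric"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(df) == 0L) stop("empty export file: ", path, call. = FALSE)

  cols <- format_config$columns
  required <- c("p_ves", "p_abd", "voided_volume")
  for (ch in required) {
    if (is.null(cols[[ch]]))
      stop("format config does not map required channel: ", ch, call. = FALSE)
    if (!cols[[ch]] %in% names(df))
      stop("required column missing from file: ", cols[[ch]], call. = FALSE)
  }

  grab <- function(ch) {
    nm <- cols[[ch]]
    if (is.null(nm) || !nm %in% names(df)) return(NULL)
    v <- df[[nm]]
    if (anyNA(v)) {
      if (format_config$missing == "error")
        stop("missing values in column ", nm, call. = FALSE)
      v <- forward_fill(v)
    }
    v
  }

  time <- grab("time")
  if (is.null(time)) {
    time <- (seq_len(nrow(df)) - 1L) / format_config$sample_rate
  } else if (any(diff(time) <= 0)) {
    stop("non-monotonic time column", call. = FALSE)
  }

  uds_recording(
    time = time, p_ves = grab("p_ves"), p_abd = grab("p_abd"),
    voided_volume = grab("voided_volume"), p_det = grab("p_det"),
    infused_volume = grab("infused_volume"), flow = grab("flow"),
    study_id = study_id %||% sub("\\.[^.]*$", "", basename(path)),
    sample_rate = format_config$sample_rate, ...
  )
}

#' Write a recording in the canonical tab-delimited dialect
#'
#' Numbers are formatted with nine decimal places, which makes
#' write-read-write round trips byte-stable.
#'
#' @param rec A `uds_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_uds_export <- function(rec, path) {
  order <- c("p_ves", "p_abd", "p_det", "infused_volume", "voided_volume",
             "flow")
  cols <- c(list(time = rec$time),
            rec$channels[intersect(order, names(rec$channels))])
  header <- paste(names(cols), collapse = "\t")
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.9f", v)),
                           sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' All channels are linearly interpolated onto a grid at `target_rate`
#' spanning the original time range. No anti-alias filtering is applied: the
#' analysis band tops out at 0.1 Hz, far below Nyquist at any plausible
#' export rate. Already-uniform input at the target rate is returned with
#' values unchanged.
#'
#' @param rec A `uds_recording`.
#' @param target_rate Target sampling rate, Hz (10 is the canonical analysis
#'   rate).
#' @return A `uds_recording` at `target_rate`.
#' @export
resample_uniform <- function(rec, target_rate = 10) {
  if (length(rec$time) < 2L)
    stop("resampling needs at least 2 samples", call. = FALSE)
  if (is_uniform(rec) && isTRUE(all.equal(rec$sample_rate, target_rate)))
    return(rec)
  t0 <- rec$time[1L]
  span <- rec$time[length(rec$time)] - t0
  m <- floor(span * target_rate + 1e-9) + 1L
  grid <- t0 + (seq_len(m) - 1L) / target_rate
  chans <- lapply(rec$channels, function(v)
    stats::approx(rec$time, v, xout = grid, rule = 2)$y)
  uds_recording(
    time = grid, p_ves = chans$p_ves, p_abd = chans$p_abd,
    voided_volume = chans$voided_volume, p_det = chans$p_det,
    infused_volume = chans$infused_volume, flow = chans$flow,
    study_id = rec$study_id, sample_rate = target_rate,
    do_label = rec$do_label, etiology_label = rec$etiology_label,
    derive_p_det = FALSE
  )
}

#' Check a recording's eligibility for LARC analysis
#'
#' Eligible studies have at least `min_fill_s` seconds of filling before the
#' (single, terminal) voiding event, or no void at all. Studies with multiple
#' distinct voiding events are excluded, as are fills too short to contain
#' the analysis window. The check is report-only and never throws.
#'
#' @param rec A `uds_recording`.
#' @param min_fill_s Minimum fill duration in seconds (default 420 = 7 min).
#' @param volume_threshold Void detection threshold, ml (see
#'   [detect_void_onset()]).
#' @param second_void_ml A later voided-volume rise larger than this, after
#' @param flat_gap_s at least this long a flat gap, counts as a second void.
#' @return A list with `eligible` (logical), `reasons` (character),
#'   `fill_duration_s` and `void_onset_time`.
#' @export
validate_for_analysis <- function(rec, min_fill_s = 420,
                                  volume_threshold = 1,
                                  second_void_ml = 10, flat_gap_s = 30) {
  reasons <- character(0)
  onset <- detect_void_onset(rec, volume_threshold)
  fill_dur <- if (is.na(onset)) diff(range(rec$time)) else onset - rec$time[1L]
  if (fill_dur < min_fill_s)
    reasons <- c(reasons,
                 sprintf("fill shorter than %g s (%.1f s available)",
                         min_fill_s, fill_dur))
  if (count_void_events(rec, second_void_ml, flat_gap_s) > 1L)
    reasons <- c(reasons, "multiple voiding events")
  list(eligible = length(reasons) == 0L, reasons = reasons,
       fill_duration_s = fill_dur, void_onset_time = onset)
}

# Count distinct voided-volume rise events: consecutive increments above the
# jitter floor are grouped; groups separated by a flat gap > flat_gap_s are
# distinct events; an event counts as a void if it accumulates > event_ml.
count_void_events <- function(rec, event_ml = 10, flat_gap_s = 30,
                              jitter_ml = 0.05) {
  v <- rec$channels$voided_volume
  t <- rec$time
  dv <- diff(v)
  rising <- which(dv > jitter_ml)
  if (!length(rising)) return(0L)
  gaps <- diff(t[rising])
  grp <- cumsum(c(0, gaps > flat_gap_s))
  rises <- tapply(dv[rising], grp, sum)
  sum(rises > event_ml)
}
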