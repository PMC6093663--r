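#' Specification for a synthetic urodynamic recording
#'
#' Describes one simulated fill-void cycle with known ground truth: baseline
#' pressures with compliance-related drift, Gaussian sensor noise, an
#' optional rhythmic contraction (a pure sine in the 1.75-6 cycles/min band,
#' injected into the vesical channel alone or translated into both channels),
#' an optional respiration-band oscillation, transient events (coughs and
#' Valsalvas appear in both pressure channels; rectal contractions only
#' abdominally), and a terminal void visible in the voided-volume channel.
#'
#' @param duration_s Recording length, seconds (default 600).
#' @param fill_rate Infusion rate, ml/min (default 42, a typical cohort
#'   average).
#' @param baseline_pves,baseline_pabd Baseline pressures, cm-H2O.
#' @param compliance_drift Pressure rise per 100 ml infused, cm-H2O.
#' @param noise_sd Gaussian sensor noise SD per channel, cm-H2O.
#' @param larc `NULL`, or a list with `frequency` (cycles/min),
#'   `peak_to_peak` (cm-H2O), optional `start_s`, `stop_s` (defaults: whole
#'   fill) and `channel` (`"vesical"` or `"both"`).
#' @param respiration `NULL`, or a list with `frequency` (cycles/min, above
#'   the analysis band; default 15) and `amplitude` (cm-H2O).
#' @param events List of event lists, each with `type` (`"cough"`,
#'   `"valsalva"`, `"rectal_contraction"`), `time_s`, `amplitude` (cm-H2O)
#'   and `duration_s`.
#' @param void `NULL` for a no-void study, or a list with `onset_s`,
#'   `voided_ml` and optional `ramp_s` (default 30).
#' @param seed Integer seed making the recording reproducible.
#' @param study_id Identifier.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(duration_s = 600, fill_rate = 42, baseline_pves = 15,
                       baseline_pabd = 10, compliance_drift = 2,
                       noise_sd = 1.5, larc = NULL, respiration = NULL,
                       events = list(),
                       void = list(onset_s = 520, voided_ml = 300),
                       seed = 1L, study_id = "synthetic") {
  if (!is.null(larc)) {
    larc$start_s <- larc$start_s %||% 0
    larc$stop_s <- larc$stop_s %||% duration_s
    larc$channel <- match.arg(larc$channel %||% "vesical",
                              c("vesical", "both"))
  }
  if (!is.null(respiration)) {
    respiration$frequency <- respiration$frequency %||% 15
    respiration$amplitude <- respiration$amplitude %||% 1.5
  }
  for (ev in events) {
    if (!ev$type %in% c("cough", "valsalva", "rectal_contraction"))
      stop("unknown event type: ", ev$type, call. = FALSE)
    if (ev$time_s < 0 || ev$time_s + ev$duration_s > duration_s)
      stop("event outside recording duration", call. = FALSE)
  }
  if (!is.null(void)) {
    void$ramp_s <- void$ramp_s %||% 30
    if (void$onset_s >= duration_s)
      stop("void onset beyond recording duration", call. = FALSE)
  }
  structure(list(duration_s = duration_s, fill_rate = fill_rate,
                 baseline_pves = baseline_pves, baseline_pabd = baseline_pabd,
                 compliance_drift = compliance_drift, noise_sd = noise_sd,
                 larc = larc, respiration = respiration, events = events,
                 void = void, seed = as.integer(seed), study_id = study_id),
            class = "synth_spec")
}

raised_cosine <- function(t, t0, duration, amplitude) {
  u <- (t - t0) / duration
  ifelse(u >= 0 & u <= 1, amplitude * 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Generate a synthetic recording from a spec
#'
#' The vesical channel is baseline + compliance drift (proportional to
#' infused volume) + the rhythm sine (half the peak-to-peak as amplitude) +
#' respiration + noise + translated events; the abdominal channel is its
#' baseline + respiration + noise + all abdominal events (translated and
#' rectal). Voided volume rises smoothly from zero at the void onset. The
#' ground-truth sidecar (expected category, injected rhythm parameters) is
#' attached as attribute `"ground_truth"`.
#'
#' @param spec A [synth_spec()].
#' @param sample_rate Hz (default 10).
#' @return A `uds_recording` with a `ground_truth` attribute.
#' @export
generate_recording <- function(spec, sample_rate = 10) {
  set.seed(spec$seed)
  n <- round(spec$duration_s * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate

  onset <- if (is.null(spec$void)) Inf else spec$void$onset_s
  infused <- spec$fill_rate / 60 * pmin(t, onset)

  pves <- spec$baseline_pves + spec$compliance_drift * infused / 100
  pabd <- rep(spec$baseline_pabd, n)

  if (!is.null(spec$larc)) {
    l <- spec$larc
    active <- t >= l$start_s & t <= l$stop_s
    wave <- (l$peak_to_peak / 2) * sin(2 * pi * l$frequency * t / 60) * active
    pves <- pves + wave
    if (l$channel == "both") pabd <- pabd + wave
  }
  if (!is.null(spec$respiration)) {
    r <- spec$respiration
    resp <- r$amplitude * sin(2 * pi * r$frequency * t / 60)
    pves <- pves + resp
    pabd <- pabd + resp
  }
  for (ev in spec$events) {
    bump <- raised_cosine(t, ev$time_s, ev$duration_s, ev$amplitude)
    pabd <- pabd + bump
    if (ev$type != "rectal_contraction") pves <- pves + bump  # translated
  }
  pves <- pves + stats::rnorm(n, sd = spec$noise_sd)
  pabd <- pabd + stats::rnorm(n, sd = spec$noise_sd)

  if (is.null(spec$void)) {
    vv <- rep(0, n)
  } else {
    u <- pmin(pmax((t - onset) / spec$void$ramp_s, 0), 1)
    vv <- spec$void$voided_ml * 0.5 * (1 - cos(pi * u))
  }
  flow <- c(0, diff(vv)) * sample_rate

  truth_category <-
    if (is.null(spec$larc)) "no_significant"
    else if (spec$larc$channel == "both") "significant_not_independent"
    else "significant_and_independent"

  rec <- uds_recording(
    time = t, p_ves = pves, p_abd = pabd, voided_volume = vv,
    infused_volume = infused, flow = flow, study_id = spec$study_id,
    sample_rate = sample_rate
  )
  attr(rec, "ground_truth") <- list(category = truth_category,
                                    larc = spec$larc, spec = spec)
  rec
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n` studies with the requested mix of ground-truth categories and
#' assigns clinician-style detrusor-overactivity (DO) labels by a stated
#' rule: rhythm-bearing (S&I) studies are DO; translated-rhythm studies are
#' not DO (abdominal artifact); of the no-rhythm studies, a fraction
#' `do_fraction_sporadic` is labelled DO (sporadic, non-rhythmic
#' contractions the detector is not meant to find). This rule makes
#' specificity-1, sensitivity-below-1 cohorts constructible.
#'
#' @param n Cohort size.
#' @param mix Named proportions over `no_significant`,
#'   `significant_not_independent`, `significant_and_independent`; must sum
#'   to 1.
#' @param seed Integer master seed; per-study seeds are derived from it.
#' @param do_fraction_sporadic Fraction of no-rhythm studies labelled DO.
#' @param base_spec Template [synth_spec()] whose fields (noise, baselines,
#'   void) the cohort inherits.
#' @param larc_frequency,larc_p2p Injected rhythm parameters for the
#'   rhythm-bearing categories.
#' @return A list: `recordings` (list of `uds_recording`), `labels`
#'   (data.frame with `study_id`, `do_label`, `truth_category`).
#' @export
generate_cohort <- function(n, mix = c(no_significant = 0.5,
                                       significant_not_independent = 0.2,
                                       significant_and_independent = 0.3),
                            seed = 1L, do_fraction_sporadic = 0.5,
                            base_spec = synth_spec(),
                            larc_frequency = 3.0, larc_p2p = 10) {
  if (n < 1) stop("cohort size must be positive", call. = FALSE)
  if (abs(sum(mix) - 1) > 1e-9)
    stop("mix proportions must sum to 1", call. = FALSE)
  cats <- c("no_significant", "significant_not_independent",
            "significant_and_independent")
  if (!all(names(mix) %in% cats))
    stop("unknown category in mix", call. = FALSE)
  counts <- round(n * mix[cats])
  counts[is.na(counts)] <- 0
  # fix rounding so the counts sum to n
  counts[1L] <- counts[1L] + (n - sum(counts))
  assignment <- rep(cats, counts)

  set.seed(seed)
  sporadic_do <- stats::runif(n) < do_fraction_sporadic

  recordings <- vector("list", n)
  labels <- data.frame(study_id = character(n), do_label = character(n),
                       truth_category = character(n),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cat_i <- assignment[i]
    sp <- unclass(base_spec)
    sp$seed <- seed + i
    sp$study_id <- sprintf("synth_%03d", i)
    sp["larc"] <- list(switch(cat_i,
      no_significant = NULL,
      significant_not_independent = list(frequency = larc_frequency,
                                         peak_to_peak = larc_p2p,
                                         channel = "both"),
      significant_and_independent = list(frequency = larc_frequency,
                                         peak_to_peak = larc_p2p,
                                         channel = "vesical")))
    sp <- do.call(synth_spec, sp)
    recordings[[i]] <- generate_recording(sp)
    labels$study_id[i] <- sp$study_id
    labels$truth_category[i] <- cat_i
    labels$do_label[i] <- switch(cat_i,
      significant_and_independent = "yes",
      significant_not_independent = "no",
      no_significant = if (sporadic_do[i]) "yes" else "no")
  }
  list(recordings = recordings, labels = labels)
}
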