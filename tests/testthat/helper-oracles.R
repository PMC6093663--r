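# Independent brute-force oracles, written deliberately apart from the
# package implementation so they can cross-check it.

# Two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, using stats::dhyper for the point probabilities.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; k1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, r1 + k1 - n):min(r1, k1)
  probs <- stats::dhyper(support, k1, n - k1, r1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Brute-force re-evaluation of the detection rules straight from two raw
# amplitude spectra: scan every band bin for a local maximum, keep the n
# largest, and apply the significance and independence rules with explicit
# arithmetic.
oracle_classify <- function(pves, pabd, cfg = larc_config()) {
  av <- pves$amplitudes
  fr <- pves$frequencies
  m <- length(av)
  in_band <- which(fr >= cfg$band_lo_cpm & fr <= cfg$band_hi_cpm)

  is_peak <- logical(m)
  for (k in in_band) {
    # a plateau of equal bins is represented by its lowest-frequency member
    if (k > 1 && av[k - 1] == av[k]) next
    if (k > 1 && av[k - 1] > av[k]) next
    j <- k + 1
    while (j <= m && av[j] == av[k]) j <- j + 1  # skip the plateau
    if (j <= m && av[j] >= av[k]) next
    is_peak[k] <- TRUE
  }
  peaks <- which(is_peak)
  peaks <- peaks[order(-av[peaks], peaks)]
  peaks <- utils::head(peaks, cfg$n_peaks)

  sig <- indep <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    k <- peaks[i]; a <- av[k]
    amp_ok <- a > cfg$amp_threshold
    line <- function(d) a * (1 - cfg$slope_fraction * d)
    left <- (k - 1 >= 1 && av[k - 1] <= line(1)) ||
      (k - 2 >= 1 && av[k - 2] <= line(2))
    right <- (k + 1 <= m && av[k + 1] <= line(1)) ||
      (k + 2 <= m && av[k + 2] <= line(2))
    sig[i] <- amp_ok && left && right
    if (sig[i]) {
      bb <- pabd$amplitudes
      b0 <- bb[k]
      nb <- c(if (k - 1 >= 1) bb[k - 1], if (k + 1 <= m) bb[k + 1])
      big <- max(c(b0, nb))
      ruleA <- a > cfg$ratio1 * big
      ruleB <- length(nb) > 0 && b0 < cfg$flatness * max(nb)
      ruleC <- a > cfg$ratio2 * big
      indep[i] <- (ruleA && ruleB) || ruleC
    }
  }
  list(
    bins = peaks, significant = sig, independent = indep,
    category = if (any(indep)) "significant_and_independent"
               else if (any(sig)) "significant_not_independent"
               else "no_significant"
  )
}

# Spectra pair for a synthetic recording at one window offset.
spectra_at <- function(rec, offset, cfg = larc_config()) {
  lapply(c(p_ves = "p_ves", p_abd = "p_abd"), function(ch)
    amplitude_spectrum(condition_segment(
      extract_roi(rec, ch, offset, cfg$roi_samples, cfg$void_threshold_ml),
      cfg$smooth_window)))
}

# Hand-built spectrum object around a given amplitude vector.
fake_spectrum <- function(amplitudes, sample_rate = 10) {
  n <- 2 * length(amplitudes)
  structure(list(
    frequencies = seq_along(amplitudes) * sample_rate * 60 / n,
    amplitudes = amplitudes, n_samples = n, sample_rate = sample_rate,
    channel_name = "fake"), class = "amplitude_spectrum")
}

# A flat spectrum with chosen amplitudes patched in at chosen bins.
patched_spectrum <- function(bins, values, floor = 0.01, n_half = 1024) {
  a <- rep(floor, n_half)
  a[bins] <- values
  fake_spectrum(a)
}
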