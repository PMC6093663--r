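test_that("peak finding returns ranked in-band local maxima", {
  # single dominant bin
  s <- patched_spectrum(10, 2.0)
  p <- find_top_peaks(s, band_bins(s))
  expect_length(p, 1)
  expect_equal(p[[1]]$bin, 10)
  expect_equal(p[[1]]$pves_amplitude, 2.0)
  expect_equal(p[[1]]$neighbors_left, c(0.01, 0.01))

  # three maxima, ranked by amplitude
  s3 <- patched_spectrum(c(8, 12, 17), c(1.0, 3.0, 2.0))
  p3 <- find_top_peaks(s3, band_bins(s3))
  expect_equal(vapply(p3, `[[`, integer(1), "bin"), c(12L, 17L, 8L))
  expect_equal(vapply(p3, `[[`, integer(1), "rank"), 1:3)

  # ties break toward lower frequency
  st <- patched_spectrum(c(9, 14), c(2.0, 2.0))
  pt <- find_top_peaks(st, band_bins(st))
  expect_equal(pt[[1]]$bin, 9)

  # a plateau is one peak at its lower-frequency bin
  sp <- patched_spectrum(c(11, 12), c(2.0, 2.0))
  pp <- find_top_peaks(sp, band_bins(sp))
  expect_length(pp, 1)
  expect_equal(pp[[1]]$bin, 11)
})

test_that("monotonically decreasing amplitudes yield no in-band peak", {
  # enumeration oracle: with amplitudes strictly decreasing across the whole
  # spectrum, no bin beats its left neighbor, so no local maximum exists
  s <- fake_spectrum(seq(2, 0.1, length.out = 1024))
  expect_length(find_top_peaks(s, band_bins(s)), 0)
  oc <- oracle_classify(s, fake_spectrum(rep(0.01, 1024)))
  expect_length(oc$bins, 0)
})

test_that("significance requires the amplitude floor and both prominences", {
  mk <- function(a, left, right) {
    s <- patched_spectrum(10, a)
    s$amplitudes[8:9] <- left
    s$amplitudes[11:12] <- right
    find_top_peaks(s, band_bins(s))[[1]]
  }
  # no neighbor under the slope line: need <= 0.8 a at d=1 or <= 0.6 a at d=2
  p1 <- test_significance(mk(1.0, c(0.9, 0.85), c(0.86, 0.9)))
  expect_false(p1$significant)
  expect_true(p1$criterion_detail$amplitude$pass)
  expect_false(p1$criterion_detail$left_prominence$pass)

  # K = 0.5 and L = 0.7 are in-region; amplitude 1.0 > 0.45
  p2 <- test_significance(mk(1.0, c(0.95, 0.5), c(0.7, 0.95)))
  expect_true(p2$significant)

  # sharp but tiny peak fails the 0.45 floor
  p3 <- test_significance(mk(0.40, c(0.01, 0.01), c(0.01, 0.01)))
  expect_false(p3$significant)
  expect_false(p3$criterion_detail$amplitude$pass)
  expect_true(p3$criterion_detail$left_prominence$pass)

  # in model peak-to-peak units the floor is 1.8 cm-H2O = 4 x 0.45
  expect_equal(4 * larc_config()$amp_threshold, 1.8)
})

test_that("independence combines (A and B) or C as stated", {
  sig_peak <- function(a) {
    s <- patched_spectrum(10, a)
    test_significance(find_top_peaks(s, band_bins(s))[[1]])
  }
  pabd <- function(b0, bn) patched_spectrum(c(9, 10, 11), c(bn, b0, bn))

  # A true (3.0 > 1.5), B true (1.0 < 1.197): independent
  p <- test_independence(sig_peak(3.0), pabd(1.0, 0.9))
  expect_true(p$independent)

  # sharp abdominal peak: A true, B false, C false: not independent
  p <- test_independence(sig_peak(1.9), pabd(1.2, 0.5))
  expect_false(p$independent)
  expect_true(p$criterion_detail$rule_a$pass)
  expect_false(p$criterion_detail$rule_b$pass)
  expect_false(p$criterion_detail$rule_c$pass)

  # C alone suffices regardless of the abdominal peak
  p <- test_independence(sig_peak(2.6), pabd(1.2, 0.5))
  expect_true(p$independent)
  expect_false(p$criterion_detail$rule_b$pass)
  expect_true(p$criterion_detail$rule_c$pass)

  # contract: independence is only defined for significant peaks
  ns <- sig_peak(0.2)
  expect_false(ns$significant)
  expect_error(test_independence(ns, pabd(0.1, 0.1)), "significant")
})

test_that("study classification matches synthetic ground truth", {
  cfg <- larc_config()
  flat <- generate_recording(synth_spec(seed = 5))
  sp <- spectra_at(flat, 30, cfg)
  expect_equal(classify_study(sp$p_ves, sp$p_abd, cfg)$category,
               "no_significant")

  ves <- generate_recording(synth_spec(
    larc = list(frequency = 3, peak_to_peak = 10), seed = 5))
  sp <- spectra_at(ves, 30, cfg)
  res <- classify_study(sp$p_ves, sp$p_abd, cfg)
  expect_equal(res$category, "significant_and_independent")
  expect_lt(abs(res$slowest_si_frequency - 3.0), 600 / 2048 + 1e-9)
  expect_lt(abs(res$slowest_si_model$peak_to_peak - 10), 2)

  both <- generate_recording(synth_spec(
    larc = list(frequency = 3, peak_to_peak = 10, channel = "both"),
    seed = 5))
  sp <- spectra_at(both, 30, cfg)
  expect_equal(classify_study(sp$p_ves, sp$p_abd, cfg)$category,
               "significant_not_independent")
})

test_that("analyze_recording ORs the per-offset S&I outcomes", {
  # rhythm that stops 90 s before the void is found at the earlier window
  rec <- generate_recording(synth_spec(
    larc = list(frequency = 3, peak_to_peak = 12, start_s = 0, stop_s = 430),
    void = list(onset_s = 520, voided_ml = 300), noise_sd = 0.5, seed = 9))
  rep <- analyze_recording(rec)
  expect_named(rep$results, c("offset_0", "offset_30", "offset_60"))
  expect_equal(rep$any_si,
               any(vapply(rep$results, function(r)
                 r$category == "significant_and_independent", logical(1))))
  expect_equal(rep$results$offset_60$category, "significant_and_independent")

  flat <- generate_recording(synth_spec(seed = 2))
  repf <- analyze_recording(flat)
  expect_false(repf$any_si)
  expect_error(
    analyze_recording(generate_recording(synth_spec(duration_s = 300,
                                                    void = NULL, seed = 2))),
    "ineligible")
})

test_that("a faint rhythm ending early is caught more often at earlier windows", {
  # near-threshold amplitude: a strong rhythm is found at every offset even
  # when truncated, so the offset contrast only shows near the floor
  hits <- matrix(NA, 20, 2, dimnames = list(NULL, c("off0", "off60")))
  for (i in 1:20) {
    rec <- generate_recording(synth_spec(
      larc = list(frequency = 3, peak_to_peak = 3, stop_s = 430),
      void = list(onset_s = 520, voided_ml = 300), seed = 100 + i))
    rep <- analyze_recording(rec)
    hits[i, ] <- c(
      rep$results$offset_0$category == "significant_and_independent",
      rep$results$offset_60$category == "significant_and_independent")
  }
  expect_gt(sum(hits[, "off60"]), sum(hits[, "off0"]))
})

test_that("raising the rhythm amplitude never loses an S&I call", {
  # same noise realization, increasing injected amplitude
  cfg <- larc_config()
  for (seed in c(31, 32, 33)) {
    prev_si <- FALSE
    for (p2p in c(4, 6, 8, 12, 16)) {
      set.seed(seed)
      noise_v <- rnorm(6000, sd = 1.5)
      noise_a <- rnorm(6000, sd = 1.5)
      rec <- generate_recording(synth_spec(
        larc = list(frequency = 3.2, peak_to_peak = p2p), noise_sd = 0,
        seed = seed))
      rec$channels$p_ves <- rec$channels$p_ves + noise_v
      rec$channels$p_abd <- rec$channels$p_abd + noise_a
      sp <- spectra_at(rec, 30, cfg)
      si <- classify_study(sp$p_ves, sp$p_abd, cfg)$category ==
        "significant_and_independent"
      if (prev_si) expect_true(si)
      prev_si <- si
    }
  }
})

test_that("classification agrees with the brute-force rule oracle", {
  cfg <- larc_config()
  set.seed(77)
  specs <- list(
    synth_spec(seed = 201),
    synth_spec(larc = list(frequency = 2.3, peak_to_peak = 9), seed = 202),
    synth_spec(larc = list(frequency = 4.1, peak_to_peak = 10,
                           channel = "both"), seed = 203),
    synth_spec(larc = list(frequency = 5.5, peak_to_peak = 14), seed = 204,
               events = list(list(type = "cough", time_s = 300,
                                  amplitude = 40, duration_s = 1.5))),
    synth_spec(respiration = list(frequency = 15, amplitude = 2), seed = 205)
  )
  for (s in specs) {
    rec <- generate_recording(s)
    for (off in c(0, 30, 60)) {
      sp <- spectra_at(rec, off, cfg)
      res <- classify_study(sp$p_ves, sp$p_abd, cfg)
      orc <- oracle_classify(sp$p_ves, sp$p_abd, cfg)
      expect_equal(res$category, orc$category)
      expect_equal(vapply(res$peaks, `[[`, integer(1), "bin"), orc$bins)
      expect_equal(vapply(res$peaks, function(p) isTRUE(p$significant),
                          logical(1)), orc$significant)
      expect_equal(vapply(res$peaks, function(p) isTRUE(p$independent),
                          logical(1)), orc$independent)
    }
  }
})

test_that("identical inputs give identical results", {
  s <- synth_spec(larc = list(frequency = 3, peak_to_peak = 8), seed = 55)
  r1 <- analyze_recording(generate_recording(s))
  r2 <- analyze_recording(generate_recording(s))
  expect_identical(r1, r2)
})
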