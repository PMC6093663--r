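test_that("a noiseless eventless spec is exactly baseline plus drift", {
  sp <- synth_spec(noise_sd = 0, void = NULL, duration_s = 600,
                   baseline_pves = 15, compliance_drift = 2, fill_rate = 42)
  rec <- generate_recording(sp)
  expect_equal(rec$channels$p_ves,
               15 + 2 * (42 / 60 * rec$time) / 100, tolerance = 1e-12)
  expect_equal(rec$channels$p_abd, rep(10, 6000))
  expect_equal(rec$channels$voided_volume, rep(0, 6000))
  expect_equal(attr(rec, "ground_truth")$category, "no_significant")
})

test_that("the injected sine, events and void land where specified", {
  sp <- synth_spec(
    noise_sd = 0,
    larc = list(frequency = 3, peak_to_peak = 10, start_s = 100,
                stop_s = 400),
    events = list(
      list(type = "cough", time_s = 50, amplitude = 40, duration_s = 2),
      list(type = "rectal_contraction", time_s = 200, amplitude = 8,
           duration_s = 20)),
    void = list(onset_s = 520, voided_ml = 300))
  rec <- generate_recording(sp)
  t <- rec$time
  # sine only inside [100, 400], amplitude p2p/2, vesical only
  i_in <- which(t == 200.5)
  expect_equal(rec$channels$p_ves[t == 50.5] -
                 rec$channels$p_ves[t == 49.9] > 10, TRUE) # cough translated
  expect_equal(max(abs(rec$channels$p_ves[t > 420 & t < 500] -
                         (15 + 2 * rec$channels$infused_volume[t > 420 & t < 500] / 100))),
               0, tolerance = 1e-9)
  # rectal contraction is abdominal-only
  bump_win <- t >= 200 & t <= 220
  expect_gt(max(rec$channels$p_abd[bump_win]) - 10, 7)
  expect_lt(max(abs(rec$channels$p_ves[bump_win] -
                      (15 + 2 * rec$channels$infused_volume[bump_win] / 100 +
                         5 * sin(2 * pi * 3 * t[bump_win] / 60)))), 1e-9)
  # voided volume: zero before onset, monotone rise to the target
  expect_true(all(rec$channels$voided_volume[t < 520] == 0))
  expect_equal(max(rec$channels$voided_volume), 300)
  expect_equal(detect_void_onset(rec, 1), 520, tolerance = 2)

  # events outside the recording are rejected
  expect_error(synth_spec(events = list(list(type = "cough", time_s = 599,
                                             amplitude = 40,
                                             duration_s = 5))),
               "outside")
  expect_error(synth_spec(larc = NULL, void = list(onset_s = 700,
                                                   voided_ml = 100)),
               "beyond")
  expect_error(synth_spec(events = list(list(type = "sneeze", time_s = 1,
                                             amplitude = 1,
                                             duration_s = 1))),
               "unknown event")
})

test_that("generation is deterministic under a fixed seed", {
  sp <- synth_spec(larc = list(frequency = 3, peak_to_peak = 10), seed = 123)
  r1 <- generate_recording(sp)
  r2 <- generate_recording(sp)
  expect_identical(r1, r2)

  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_uds_export(r1, f1)
  write_uds_export(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cohorts honour the category mix and DO labelling rule", {
  ch <- generate_cohort(20, mix = c(no_significant = 1), seed = 3,
                        do_fraction_sporadic = 0)
  expect_length(ch$recordings, 20)
  expect_true(all(ch$labels$do_label == "no"))
  expect_true(all(ch$labels$truth_category == "no_significant"))

  ch2 <- generate_cohort(
    10, mix = c(no_significant = 0.5, significant_not_independent = 0.2,
                significant_and_independent = 0.3), seed = 3)
  expect_equal(sum(ch2$labels$truth_category == "significant_and_independent"),
               3)
  # all rhythm-bearing studies are DO; translated-rhythm studies are not
  expect_true(all(ch2$labels$do_label[
    ch2$labels$truth_category == "significant_and_independent"] == "yes"))
  expect_true(all(ch2$labels$do_label[
    ch2$labels$truth_category == "significant_not_independent"] == "no"))

  expect_error(generate_cohort(0), "positive")
  expect_error(generate_cohort(5, mix = c(no_significant = 0.5)), "sum to 1")
})

test_that("injected rhythm parameters are recovered across seeds", {
  n_ok_f <- 0
  p2p_err <- numeric(0)
  freqs <- seq(2.0, 5.5, length.out = 25)
  for (i in 1:25) {
    rec <- generate_recording(synth_spec(
      larc = list(frequency = freqs[i], peak_to_peak = 10), seed = 400 + i))
    sp <- spectra_at(rec, 30)
    res <- classify_study(sp$p_ves, sp$p_abd)
    if (res$category == "significant_and_independent" &&
        abs(res$slowest_si_frequency - freqs[i]) <= 600 / 2048 + 1e-9) {
      n_ok_f <- n_ok_f + 1
      p2p_err <- c(p2p_err, abs(res$slowest_si_model$peak_to_peak - 10) / 10)
    }
  }
  expect_gte(n_ok_f, 23) # >= 90% of seeds
  expect_lt(median(p2p_err), 0.25)
})
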