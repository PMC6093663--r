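---
title: "Detecting low amplitude rhythmic contractions in urodynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting low amplitude rhythmic contractions in urodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A urodynamic study (UDS) fills the bladder at a controlled rate while
recording vesical pressure (P_ves, via a bladder catheter) and abdominal
pressure (P_abd, via a rectal catheter), both in cm-H2O, together with
infused and voided volumes. Detrusor overactivity (DO) — involuntary
detrusor contractions during filling — is diagnosed visually. A subset of
patients shows not isolated contractions but a *rhythm*: low amplitude
rhythmic contractions (LARC) of a few cycles per minute and often only a few
cm-H2O, which are hard to judge by eye. `larcfft` detects this rhythm
objectively in the frequency domain and, crucially, rejects rhythms of
abdominal origin by comparing the two pressure channels: true detrusor
activity appears in P_ves but not P_abd, whereas coughs, Valsalvas and
movement are *translated* into both channels, and rectal contractions appear
only abdominally.

## The procedure

**Analysis window.** The void onset is the first voided-volume sample above
1 ml that stays above it. The region of interest (ROI) is exactly N = 2048
samples at 10 Hz (204.8 s), ending 0, 30 or 60 s before the void onset.
Three offsets are analyzed because voiding-phase contractions can precede
the recorded void and flowmeter transit delays blur the onset. The fixed
power-of-two N keeps the DFT bin width identical across studies
(Δf = 600/2048 = 0.29296875 cycles/min) so that the amplitude thresholds
below are comparable between patients; this is why the sample count, not a
round number of seconds, is authoritative. For studies with no void, the
window is anchored to the recording end — the only landmark available.

**Conditioning.** Per channel, in fixed order: (1) subtract the minimum of
the window, (2) 10-point moving average, (3) Hann window
\(w[n] = \tfrac12(1-\cos 2\pi n/(N-1))\). The minimum shift and the
exclusion of the DC bin make the spectrum insensitive to constant offsets
(catheter zeroing differences); the Hann taper removes the discontinuity
that would otherwise leak broadband energy when the FFT treats the segment
as periodic.

**Spectrum.** Normalized single-sided amplitudes \(A_k = 2|X_k|/N\) for
bins \(k = 1..N/2\), *without* compensating the Hann coherent gain of ½.
Under this convention a windowed sine of unit amplitude reads ≈ 0.5 at its
bin, so the physical peak-to-peak pressure of a detected rhythm is
\(4 A_k\): one factor of 2 from the windowing, one from converting sine
amplitude to peak-to-peak. This is the only normalization that makes the
two published forms of the significance floor (0.45 spectrum units and
1.8 cm-H2O peak-to-peak) the same threshold, and the package treats them
that way.

**Detection band.** 1.75–6.0 cycles/min (bins 6–20), inclusive at both
edges: the range where bladder rhythmic activity has been reported, and
safely below respiration. Neighbor bins used by the criteria may lie just
outside the band; the full spectrum is retained.

**Significance (is the vesical peak real?).** The three largest in-band
local maxima are evaluated. A peak of amplitude \(a\) is significant when
\(a > 0.45\) (strict), and on *each* side at least one of the two nearest
neighbors lies at or below the slope line \(a(1 - 0.2d)\) at bin distance
\(d \in \{1,2\}\) — a 20 %-per-bin prominence requirement that rejects broad
humps (drift, sporadic contractions) while tolerating the leakage shoulder
of an off-bin sine.

**Independence (is it bladder, not bowel?).** With \(b_0\) the abdominal
amplitude at the peak bin and \(b_L, b_R\) its immediate neighbors:
rule A, \(a > 1.5\max(b_0,b_L,b_R)\); rule B, \(b_0 < 1.33\max(b_L,b_R)\)
(no sharp abdominal peak); rule C, \(a > 2\max(b_0,b_L,b_R)\). The peak is
independent when (A and B) or C — rule C is deliberately unconditional, so a
vesical rhythm that dwarfs a small synchronous abdominal ripple still
counts. A study is S&I when **any** of its three peaks is significant and
independent; the *slowest* S&I frequency and its sine model
(peak-to-peak = 4 × amplitude) are reported, and an any-offset flag ORs the
three windows.

**Cohort statistics.** S&I calls are cross-tabulated against clinician DO
labels; sensitivity = S&I∩DO / DO, specificity = ¬S&I∩¬DO / ¬DO. The
association is tested with a two-sided Fisher exact test implemented from
first principles (log-factorial hypergeometric point probabilities, summing
all tables with the observed margins whose point probability is at most the
observed one, relative tie tolerance 1e-12 — the point-probability
convention of standard tools). Group descriptives use mean ± standard error;
ages are compared with a pooled-variance two-tailed t-test.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `roi_samples` | 2048 | samples | power of two; fixes bin width across studies |
| `sample_rate` | 10 | Hz | canonical analysis rate |
| `offsets` | 0, 30, 60 | s | pre-void ramp-up and flowmeter delay |
| `band_lo_cpm`, `band_hi_cpm` | 1.75, 6.0 | cycles/min | reported LARC range, below respiration |
| `amp_threshold` | 0.45 | spectrum units | = 1.8 cm-H2O peak-to-peak |
| `slope_fraction` | 0.20 | per bin | prominence (sharpness) requirement |
| `ratio1`, `flatness`, `ratio2` | 1.5, 1.33, 2.0 | ratios | independence rules A/B/C |
| `n_peaks` | 3 | — | peaks evaluated per spectrum |
| `void_threshold_ml` | 1 | ml | above flowmeter jitter |
| `smooth_window` | 10 | samples | 1 s moving average |
| `min_fill_s` | 420 | s | eligibility: at least 7 min of filling |

The detection thresholds are an operating point inherited from visual
calibration on real studies, not optimized by this package; learning them
from data is out of scope.

## The synthetic generator

`synth_spec()`/`generate_recording()` emulate the signal classes the
detector must separate: baseline pressures (defaults 15/10 cm-H2O vesical/
abdominal — typical small offsets of non-equalized catheters), a compliance
drift of 2 cm-H2O per 100 ml infused (normal compliance is tens of
ml/cm-H2O), filling at 42 ml/min (a typical cohort mean), white Gaussian
sensor noise (default SD 1.5 cm-H2O), an injected pure-sine rhythm
(detected LARC is itself modeled as an ideal sine, so a sine is the natural
ground-truth primitive), respiration at ≥ 10 cycles/min, raised-cosine
transients (coughs/Valsalvas in both channels, rectal contractions
abdominal-only), and a terminal void as a smooth voided-volume ramp
(default onset 520 s, 300 ml). Recordings are deterministic given the seed.

What the generator does **not** emulate: non-sinusoidal or
frequency-drifting rhythms, autocorrelated (pink) sensor noise, catheter
flushes and repositioning artifacts, post-void residual behavior, and the
visual-diagnosis noise of real DO labels. Passing the ground-truth tests
therefore demonstrates that the decision rules are implemented correctly
and behave sensibly under realistic amplitudes and noise — not that the
published clinical sensitivity/specificity would be reproduced on real
patients.

## Numerical choices and edge cases

* **Moving average alignment**: centered, with shrunken windows at the
  edges — no group delay, so peak frequencies are unaffected (an even-length
  centered window retains a half-sample delay, irrelevant to amplitude
  spectra). A trailing average would shift phase only.
* **Hann convention**: symmetric (`N-1` denominator); endpoints exactly 0.
  The periodic convention would change band amplitudes by < 0.1 % at
  N = 2048.
* **Peak ties and plateaus**: equal-amplitude runs are one peak at the
  lowest-frequency bin; equal-amplitude distinct peaks rank lower frequency
  first. Neighbor comparisons at the spectrum boundary use the available
  neighbor; a side with no neighbors fails prominence and records why.
* **Strictness**: the amplitude floor and independence comparisons are
  strict (`>`, `<`); the prominence line is inclusive (at-or-below). These
  choices differ only on measure-zero events for real signals.
* **Windows near the recording start**: extracting a ROI that would precede
  the data is an eligibility error reporting required vs available seconds.
* **Degenerate statistics**: a single S&I study reports SE 0 with a flag;
  an empty S&I subgroup gives an empty summary; zero pooled variance in the
  t-test gives p = 1 (equal means) or p = 0 (unequal).
* **Resampling**: linear interpolation onto a uniform grid, no anti-alias
  filter (the band of interest ends at 0.1 Hz, far below Nyquist of any
  plausible export rate); idempotent on already-uniform input.
* **Multiple voids**: a voided-volume rise of > 10 ml after > 30 s of flat
  signal marks a second void event and excludes the study (the pipeline
  analyzes a single fill-void cycle). The values separate terminal voids
  from leaks in the synthetic fixtures; real exports may need site-specific
  tuning.

## Test problem sizes

The suite generates all fixtures in code: 600 s recordings at 10 Hz
(6000 samples), ground-truth batches of 50 seeds per scenario for the
classifier (injected rhythms spread over 2.0–5.5 cycles/min at 10 cm-H2O
peak-to-peak, noise SD 1.5), 25-seed parameter-recovery runs, a 20-seed
near-threshold comparison of window offsets (peak-to-peak 3 cm-H2O, chosen
near the 1.8 cm-H2O floor because stronger truncated rhythms are detected
at every offset), and exhaustive Fisher-test verification against direct
hypergeometric enumeration for all 2×2 tables with total ≤ 40. These sizes
keep the full suite around ten seconds on one CPU while exercising every
decision rule.

## Known limitations

* The detector sees any sufficiently sharp, vesical-dominant band peak as
  LARC; it cannot distinguish a true detrusor rhythm from a rhythmic
  artifact confined to the vesical catheter.
* Frequency resolution is 0.293 cycles/min; reported frequencies are
  quantized to the bin grid, and an off-bin rhythm loses up to ~15 % of its
  model amplitude to scalloping (the moving average adds ≲ 1.5 % at the top
  of the band).
* No-void studies use the recording end as the window anchor; if filling
  ended long before the export stopped, the analyzed window may lie outside
  active filling.
* DO labels are inputs; the package never re-derives the clinical
  diagnosis.
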