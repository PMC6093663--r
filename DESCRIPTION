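Package: larcfft
Title: FFT Detection of Low Amplitude Rhythmic Contractions in Urodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects low amplitude rhythmic contractions (LARC) in
    multichannel urodynamic pressure recordings using a windowed FFT of a
    fixed 2048-sample region of interest before the voiding event. Vesical
    spectral peaks in the 1.75-6 cycles/min band are tested for significance
    (amplitude and prominence) and for independence from the abdominal
    pressure spectrum, each study is classified accordingly, and cohort-level
    diagnostic statistics (sensitivity, specificity, exact association tests)
    are computed against clinician detrusor-overactivity labels. Includes a
    synthetic recording generator with known ground truth and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
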