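Package: hearscale
Title: Stratified-Scale Smartphone Hearing Screening Simulation and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for stratified-scale adaptive pure-tone hearing screening.
    Implements the Hearing Scale Test (HST) adaptive screening state machine
    (descend/ascend in 5 dB scales from a fixed start scale to the minimum
    audible hearing scale or a no-response outcome), fixed-level screening
    protocol presets (AAP, ASHA), a 2-down-1-up calibration staircase with
    ascending pre-scan, calibrated pure-tone stimulus synthesis (dB HL to
    dB SPL via RETSPL profiles, amplitude-modulated tones, WAV export),
    psychometric-function listener simulation with cohort generators, and
    screening-test evaluation (2x2 contingency tables, sensitivity,
    specificity, predictive values, per-scale threshold summaries and
    protocol comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
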