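Package: thetanf
Title: Closed-Loop Intracranial Theta Neurofeedback Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis toolkit for closed-loop
    intracranial memory neurofeedback. Generates synthetic mesial temporal
    lobe EEG (1/f background, theta oscillations, epileptic spike
    transients) tied to an old/new word recognition paradigm, runs the
    intermittent bar-feedback loop (Welch theta band power, 4-8 Hz,
    averaged across contacts), cleans spike artifacts by artifact subspace
    reconstruction with an adaptive cutoff rule driven by the epoch
    exceedance fraction, and provides the offline statistics battery:
    binwise spectral tests with Holm-Bonferroni correction, one-way
    session ANOVA with Tukey post-hoc on log theta power, and subset-ruled
    Spearman correlations between theta power and recognition performance.
    Continuous signals are read and written as EDF, events as tab-separated
    tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
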