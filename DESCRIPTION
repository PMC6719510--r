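Package: mmnload
Title: Visual Perceptual Load and the Auditory Mismatch Negativity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis workflow for a crossmodal attention
    study asking whether visual perceptual load modulates the auditory
    frequency mismatch negativity (MMN). Provides constrained stimulus
    sequence generators for oddball and equiprobable-control tone blocks
    paired with a visual search task, a synthetic epoched-EEG cohort
    generator with known ground-truth event-related potential (ERP)
    components, the preregistered ERP measurement pipeline (baseline
    correction, rereferencing, amplitude-range artifact rejection,
    difference waves, mean-amplitude measures for N1, oddball MMN,
    corrected MMN, P3a, and the visual P3), and a Bayesian inference layer
    (uniform-prior Bayes factors with a t likelihood, credible intervals,
    and flat-prior correlation Bayes factors) that reproduces published
    group-level Bayes factors from printed summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
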