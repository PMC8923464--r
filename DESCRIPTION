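Package: anpitch
Title: Auditory-Nerve Ideal-Observer Modeling of Frequency and F0 Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates human auditory-nerve population responses to pure tones
    and harmonic complex tones with a phenomenological front end (gammatone
    filterbank, saturating transduction, phase-locking rolloff), and derives
    psychophysical thresholds via Fisher-information/Cramer-Rao ideal-observer
    analysis for inhomogeneous Poisson spike trains. Provides all-information
    and rate-place observers, frequency and fundamental-frequency difference
    limen (FDL/F0DL) experiment pipelines with LOESS summaries, excitation
    patterns and autocorrelograms, calibrated stimulus synthesis (harmonic
    complexes, threshold-equalizing noise, complex-tone maskers) with seeded
    level and phase roving, and a Monte-Carlo maximum-likelihood oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
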