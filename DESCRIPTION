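Package: fraccyc
Title: Fractal Cycles of Sleep from Aperiodic EEG Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects ultradian sleep cycles from the aperiodic (1/f, fractal)
    component of overnight EEG. Per-epoch power spectra are separated into
    fractal and oscillatory parts by irregular-resampling auto-spectral
    analysis (IRASA), the log-log slope of the fractal part is tracked across
    the night, and prominent peaks of the z-normalized, Savitzky-Golay
    smoothed slope series delimit "fractal cycles". Classical non-REM - REM
    cycles (including skipped-REM first cycles) are segmented from hypnograms
    with adapted Feinberg & Floyd rules, and the correspondence between the
    two cycle definitions is quantified with rank correlations, nonparametric
    tests and Bayesian population prevalence. Includes EDF/hypnogram readers,
    a synthetic night generator with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
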