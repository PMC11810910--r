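Package: pareidoscope
Title: Reverse-Correlation Classification Images from Noise-Pattern Oddity Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates three-alternative oddity experiments in which observers
    search two-dimensional Gaussian noise patterns for faces or letter-like
    targets, and recovers the internal template driving their choices by
    reverse correlation.  Provides generators for noise canvases, procedural
    target banks and composited stimuli; template-matching synthetic observers
    with softmax choice, position bias, lapses and evidence-dependent response
    times; selected/unselected average and difference (classification) images
    with luminance enhancement; per-pixel linear mixed-model maps of the
    selected-versus-unselected contrast with Benjamini-Hochberg false discovery
    rate control; a random-selection null calibration; and supporting analyses
    (log response-time mixed models, position-bias chi-square statistics,
    Spearman correlations, response-time median splits, brightness-difference
    contrasts, radial Fourier amplitude spectra and Euclidean image distances).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
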