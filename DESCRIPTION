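Package: dynloc
Title: Dynamic Sound-Localization Experiments with Head-Rotation-Gated
    Binaural Cues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Machinery for sound-localization experiments in which listeners
    make small head rotations while a wideband stimulus plays. Provides
    interaural-polar coordinate arithmetic, sagittal-plane source grids and
    seeded trial plans, an HRTF processing chain (time-of-arrival estimation
    and removal, minimum-phase reconstruction, spherical-mesh subdivision,
    VBAP spectral interpolation, spherical-head TOA model, spectral
    flattening and frozen-spectrum synthesis), head-tracked block-convolution
    binaural rendering with rotation-based gating, a synthetic-listener
    simulator with known ground truth, response screening and localization
    metrics (lateral/polar precision error, front-back confusion rate), and
    the mixed-effects inferential stage with Tukey-adjusted marginal-mean
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
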