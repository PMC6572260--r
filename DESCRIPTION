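Package: lssrt
Title: Dynamic Retention-Time Prediction and LC-MS Feature Annotation
    with the Linear Solvent Strength Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts reversed-phase liquid chromatography retention times
    under arbitrary single-ramp gradient programs from per-compound linear
    solvent strength (LSS) parameters (ln kw, S), recovers those parameters
    from retention times measured under two gradients, autocalibrates
    predictions against a small set of known compounds through a global
    affine fit, and annotates LC-MS features by adduct-corrected exact mass
    and predicted retention time with provenance-dependent tolerances.
    Includes annotation quality metrics (success and misattribution rates,
    gamma-based annotation multiplicity percentiles), CSV/JSON readers and
    writers for compound libraries, feature lists, calibrants and
    configuration, a synthetic-data generator for end-to-end validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
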