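Package: serialboot
Title: Bootstrap Resampling Tools for Time-Resolved Serial Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Appraises conformational changes recovered from time-resolved
    serial crystallography data by resampling. Provides fixed-size bootstrap
    resampling of diffraction frames with Monte-Carlo merging, isomorphous
    difference Fourier and Polder-style omit map synthesis, structure-factor
    extrapolation to a hypothetical full-occupancy activated dataset, singular
    value decomposition of resampled difference-map ensembles, a lightweight
    reciprocal-space two-state refinement engine with occupancy scans, and
    closed-form plus resampling-based coordinate-error estimates. A built-in
    synthetic serial-diffraction generator emulates per-frame partial
    intensities so every tool can be exercised end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
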