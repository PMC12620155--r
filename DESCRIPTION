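Package: arfimap
Title: Model-Based Displacement Map Reconstruction for MR-ARFI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for magnetic resonance acoustic radiation force imaging
    (MR-ARFI) of focused ultrasound. Reconstructs quantitative tissue
    displacement maps from alternating-contrast complex image timeseries by
    jointly estimating a complex baseline image, per-timepoint smooth
    polynomial phase errors, and a sparse displacement-phase map; also
    provides ROI-phase-corrected and four-image difference reference
    estimators, displacement/phase and mechanical-index conversions, a
    synthetic acquisition simulator with known ground truth, and
    precision/contrast-to-noise evaluation metrics. Includes a command-line
    interface for simulate/fit/evaluate/mi workflows on NIfTI magnitude and
    phase volumes with JSON sidecars.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
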