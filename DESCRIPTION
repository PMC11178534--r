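Package: retnpi
Title: Retinal Nonperfusion Index Quantification for Ultra-Widefield Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal nonperfusion from ultra-widefield fluorescein
    angiograms on a spherical model eye. Maps image pixels back onto the
    retinal sphere, computes per-pixel retinal areas by spherical
    trigonometry, partitions the retina into posterior pole, mid periphery
    and far periphery by geodesic distance from the fovea, segments
    nonperfused retina by guided region growing with manual positive and
    negative corrections and artifact exclusion, and derives the per-zone
    and overall nonperfusion index (NPI). Longitudinal progression is
    estimated with mixed models for repeated measures with random effects
    for patient and eye, yielding piecewise annual rates of change.
    Includes a synthetic cohort and image generator emulating centripetal
    nonperfusion progression for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    lme4,
    yaml,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
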