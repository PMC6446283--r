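Package: natsc
Title: Quantification and Test-Retest Analysis of Cerebral Sodium (23Na) MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts cerebral sodium (23Na) MR image signal to tissue sodium
    concentration (TSC, mmol/kg wet weight) using a relaxation-corrected,
    reference-phantom-calibrated equation with biexponential transverse decay,
    and analyses repeatability (same-day test-retest), reproducibility
    (8-day interval), laterality, inter-individual fluctuation and
    inter-reader agreement of landmark ROI measurements. Ships a synthetic
    cohort generator (digital head phantom, forward signal synthesis, Rician
    noise, session gain drift and repositioning, reader placement jitter) so
    the full pipeline is exercisable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
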