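Package: iacorridor
Title: Infra-Acetabular Screw Corridor Morphometry from 3D Bone Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of the infra-acetabular screw corridor on
    segmented pelvic bone models. Constructs anatomical reference frames
    (anterior pelvic plane, sagittal midline plane) from bony landmarks,
    casts virtual-fluoroscopy ray projections at a configurable inlet tilt,
    searches the projection for the maximal intra-osseous screw cylinder,
    and applies the 3.5 mm insertion cutoff. Includes a synthetic phantom
    generator with analytic ground truth, a cohort emulator, and the cohort
    statistics stage (t tests, chi-square insertion-rate comparison, one-way
    ANOVA with post-hoc contrasts, Pearson correlations, report tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
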