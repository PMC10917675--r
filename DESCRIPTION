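Package: dbsmap
Title: Sweet Spot Mapping and Fiber Filtering for Deep Brain Stimulation
    Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Group-level mapping of deep brain stimulation (DBS) effects from
    patient electric-field (E-field) volumes and clinical outcomes. Implements
    voxel-wise sweet-spot mapping (mass-univariate Spearman correlation between
    stimulation magnitude and percent clinical improvement over a coverage
    mask), streamline-level fiber filtering against a normative connectome
    (per-streamline rank correlation of peak E-field magnitudes with outcomes,
    top-percentile sweet-streamline selection, and weighted peak-percentile
    scoring), outcome estimation from fitted models, k-fold cross-validation
    with permutation inference, cross-disorder specificity analysis,
    electrode-placement control analyses, and a compromise-type power analysis
    for correlation effects. A synthetic phantom cohort generator (analytic
    inverse-square E-fields, bilateral four-contact leads, planted target
    spots and streamline bundles) makes every stage testable end to end
    without patient data. Reads and writes NIfTI-1 volumes and TRK/TCK
    streamline files.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
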