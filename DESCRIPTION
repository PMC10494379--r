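Package: mbDWI
Title: Multi-b-Value Diffusion-Weighted MRI Model Fitting and Diagnostic
    Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxel-wise fitting of monoexponential (ADC), biexponential
    intravoxel-incoherent-motion (D, D*, f) and stretched-exponential
    (DDC, alpha) decay models to 4D multi-b-value diffusion-weighted MRI
    volumes, with a region-of-interest measurement protocol and the full
    diagnostic-statistics chain (independent-samples t test, intraclass
    correlation, Bland-Altman limits of agreement, ROC analysis with
    Youden-optimal cutoffs and DeLong AUC comparison) used to separate
    tumour progression from pseudoprogression in glioblastoma. Includes a
    Rician-noise digital phantom generator that emulates a labelled
    two-group lesion cohort so the whole pipeline is testable end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    minpack.lm,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
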