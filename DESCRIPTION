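Package: cshpet
Title: Mid-Treatment FDG-PET Heterogeneity Analysis via Cumulative
    SUV-Volume Histograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of paired baseline and mid-treatment
    FDG-PET scans of a primary tumour: first-order SUV features (SUVmax,
    SUVmean, metabolic tumour volume, total lesion glycolysis), fixed-bin
    SUV discretisation, intra-tumoural metabolic heterogeneity scored as
    the area under the cumulative SUV-volume histogram (AUC-CSH),
    longitudinal percentage-change features, pre-specified risk
    stratification, and a survival layer (Kaplan-Meier, log-rank, Cox
    regression, 2-year locoregional recurrence-free survival). Includes a
    gradient-based semi-automated lesion delineation tool, synthetic
    tumour-phantom and cohort simulators for validation, and a pipeline
    orchestrator with a full run manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    survival,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
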