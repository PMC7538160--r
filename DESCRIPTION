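Package: ictrace
Title: Whole-Brain Viral Tracing Quantification and Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying whole-brain viral tracing
    experiments from coronal section images: detection of retrogradely
    labeled somata, double-positive starter cells and anterogradely labeled
    axons; assignment of detections to a bregma-indexed polygonal ROI atlas
    with a subregion-to-major-region hierarchy; normalization to percent of
    brain-wide total and cell density with background thresholding;
    anterior-posterior density profiles with linear interpolation and
    Savitzky-Golay smoothing; reciprocity, pairwise-correlation and
    complete-linkage clustering analyses of tracing cohorts; and
    count-validation statistics (relative percent difference, one-way ANOVA
    with Tukey HSD). A synthetic-data module generates section images and
    mouse-cohort count tables with known ground truth so every stage is
    testable without microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    readxl,
    mclust,
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
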