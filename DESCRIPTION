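Package: tiltQA
Title: Neck-Tilt Stratified Quality Assurance of Auto-Segmented
    Radiotherapy Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies sagittal neck tilt from cervical spinal-cord
    segmentations by principal component analysis over the C1-C4 extent,
    stratifies a cohort into normal and abnormal tilt groups by percentile
    cutoffs, scores auto-segmented organ-at-risk contours against
    gold-standard contours with volumetric Dice, surface Dice at a
    configurable tolerance, and mean distance to agreement, computes
    gold-versus-test mean-dose differences with a low-dose exclusion rule,
    and tests for cohort differences with two-tailed Wilcoxon rank-sum
    tests. Includes a deterministic synthetic phantom-cohort generator so
    the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
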