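Package: annoret
Title: Annotator Variability and Retraining Effects in Lesion-Detection CAD
Version: 0.1.0
Authors@R: person("annoret", "maintainers", email = "annoret@example.org",
    role = c("aut", "cre"))
Description: A desk-scale simulation framework for studying how annotator
    variability and annotation-integration strategies change the performance of
    retrained lesion-detection CAD software. Provides synthetic 3D phantom and
    annotator-behaviour generators for chest-CT nodule and brain-MRA aneurysm
    tasks, a compact candidate-detection pipeline with CNN or logistic
    false-positive reduction, spherical-ROI annotation integration
    (AND/OR/VOTING with a 3 mm centroid-matching rule), a two-round retraining
    protocol, and lesion-level evaluation via FROC curves, the competition
    performance metric (CPM), and the Steel-Dwass all-pairs rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
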