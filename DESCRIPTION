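Package: lesionquant
Title: Regional MS Lesion Quantification on Multi-Contrast Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying regional multiple-sclerosis lesion burden
    on co-registered PD-, T2- and T1-weighted brain volumes: synthetic
    multi-contrast phantom generation with region atlases and lesion ground
    truth, preprocessing (grid resampling, bias-field correction, rigid
    inter-contrast registration, two-piece linear intensity normalization),
    Bayesian multispectral T2-lesion segmentation, relative-threshold
    T1-hypointensity segmentation with cross-protocol threshold calibration,
    connected-component lesion counting with minimum-size rules, regional
    volumetrics, lesion frequency maps, and group comparisons (Fisher's exact
    test, Student's t on log-transformed volumes, Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
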