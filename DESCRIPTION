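Package: dermopt
Title: Optimized Dermoscopy Lesion Diagnosis with Modified Thermal Exchange Optimization
Version: 0.1.0
Authors@R: person("dermopt", "maintainers", email = "maintainers@dermopt.dev", role = c("aut", "cre"))
Description: An end-to-end pipeline for automated skin-lesion diagnosis from
    dermoscopy images: non-local-means denoising, Otsu thresholding with
    binary morphology for lesion segmentation, extraction of sixteen
    intensity, texture (GLCM) and shape descriptors, wrapper feature
    selection driven by a Modified Thermal Exchange Optimization (MTEO)
    metaheuristic scored with the Matthews correlation coefficient, and a
    support-vector-machine classifier. Ships the TEO/MTEO continuous
    optimizer as a general minimizer, a benchmark-function validation
    harness, and a synthetic dermoscopy image generator so every stage is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
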