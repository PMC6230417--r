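Package: ctburden
Title: Volumetric and Density Response Assessment of Diffuse Liver
    Metastases on Contrast-Enhanced CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computer-aided assessment of drug-treatment response in
    diffuse liver metastases from paired contrast-enhanced CT
    examinations. Segments the liver with a two-component Gaussian
    mixture intensity model fitted by expectation-maximization,
    classifies tumor voxels with a four-layer backpropagation neural
    network over statistical and gray-level co-occurrence texture
    features, and summarises the whole tumor burden as total volume,
    mean volumetric density and RECIST 1.1 diameter sums. Percent
    changes between time points (including the combined
    volume-plus-density statistic) are correlated with
    progression-free survival at the cohort level. A synthetic CT
    phantom generator with analytic ground truth supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
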