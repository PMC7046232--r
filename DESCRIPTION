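Package: plantarmap
Title: Personalized Pixel-Wise Analysis of Plantar Pressure Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pixel-wise statistical models of healthy peak plantar
    pressure images as linear functions of demographic covariates, and flags
    where an individual's measured pressures depart from their personalized
    predicted baseline. Anatomical correspondence across feet is established
    by mutual-information rigid registration, diffeomorphic demons alignment
    of footprint silhouettes, and iterative groupwise template construction.
    Single-case inference uses Crawford-Howell style t-statistics thresholded
    with random field theory, and surviving clusters are summarized into
    anatomical region patterns (heel, midfoot, metatarsal 1, metatarsals 2-5,
    toes). A synthetic cohort generator with known demographic effects and
    injectable regional abnormalities supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    generics,
    tibble,
    ggplot2,
    stats,
    utils,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
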