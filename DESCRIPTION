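Package: chainsreg
Title: Population-Based Affine Registration of Brain Image Cohorts via
    Chain Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Affine registration of cohorts of 3-D brain volumes with
    highly variable appearance and positioning. All images are first
    registered pairwise with a local normalised-mutual-information (NMI)
    engine; the inverse-NMI distances define a complete directed graph
    from which a rooted-tree chain graph is built with automatic rank
    selection. Each image is then mapped to a reference either by
    composing the transforms along its graph path (indirect) or by a
    local refinement initialised at the composed transform (direct).
    Includes a procedural brain phantom simulator (lesioned, repositioned
    and noisy cohorts with known ground truth), residual-displacement
    evaluation and lesion-overlap metrics, and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
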