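Package: scmbench
Title: Stochastic Context Models for Evaluating Generative Image Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-exact generators and post-hoc analyzers for stochastic
    context models (SCMs): an alphabet model with prescribed letter and
    letter-pair prevalences, a Voronoi model with zero-intensity edges and
    perfect area-intensity rank correlation, and an eight-class flag model
    with joint position, prevalence, intensity and texture constraints.
    Includes a simplified breast-phantom fixture with thresholdable tissue
    bands and a ligament skeleton, an ensemble-level evaluation framework
    (texture, morphology, skeleton and tissue-ratio feature families, PCA
    embedding, paired cosine-similarity Kolmogorov-Smirnov summaries,
    k-nearest-neighbor coverage and density, class prevalence), and error-mode
    injectors that corrupt clean ensembles at controlled rates so every
    analyzer can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
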