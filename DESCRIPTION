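Package: lpgx
Title: Linear-Programming Separating-Hyperplane Classification of Gene
    Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiclass classification of microarray gene-expression
    profiles by pairwise linear-programming separating hyperplanes.
    Provides affine min-max normalization, class-centered margin-based
    feature filtering, an L1-slack linear program whose optimal value is
    zero exactly when two classes are linearly separable, threshold
    calibration of the fitted planes, one-vs-one voting and decision-list
    classifiers, a full evaluation battery (confusion matrix, pairwise
    precision, macro metrics), and a seeded generator of leukemia-shaped
    synthetic expression data with planted separable features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: Classification, GeneExpression, Microarray, FeatureExtraction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
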