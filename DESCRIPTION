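Package: tsfnn
Title: Three-Stage Fusion Neural Networks for Mixed-Type Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates two-branch fusion neural networks for
    clinical tables that mix categorical and numerical predictors, motivated by
    vertical root fracture risk prediction after root canal therapy. Numerical
    items are min-max normalized and categorical items are globally
    ordinal-encoded, then passed through an embedding layer obtained by
    pre-training a one-hidden-layer network and stripping its output nodes.
    The fusion classifier (TSFNN) and its ablation baselines (plain ANN,
    numerical-only and categorical-only branches, two-way concatenation
    without a fusion sub-network) are trained with mini-batch gradient descent
    and optional batch normalization, and compared under leave-one-out
    cross-validation with pooled confusion-matrix metrics. A synthetic-data
    generator emulates the 17-item dental schema with configurable planted
    effects, standing in for private clinical records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
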