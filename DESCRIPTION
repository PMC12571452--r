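Package: cgsda
Title: snoRNA-Disease Association Prediction with Dual Graph Neural Network Branches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores candidate snoRNA-disease associations by link prediction on
    the bipartite association network. Two graph neural network branches are
    fused: a Chebyshev-interpolation spectral convolution (ChebNetII) branch and
    a gated graph sequence (GRU message passing) branch, each with residual
    injection of the encoded initial features to counter over-smoothing, followed
    by a sigmoid inner-product decoder. Includes balanced-negative-sampling
    training, ten-fold cross-validation with seven metrics, ablation variants,
    case-study ranking protocols, a seeded planted-structure synthetic data
    generator, and a k-mer sequence featurizer. Model fitting is implemented in
    base R with analytic gradients and adaptive moment optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
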