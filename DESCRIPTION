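Package: regnet
Title: Regulatory Component Analysis of Gene Expression and Regulator Binding Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers quantitative regulator-gene interactions by decomposing a
    gene-expression matrix onto regulator activity profiles under joint
    constraints of sparseness and regulator-target connectivity. Regulator
    activities are summarised as the median expression of bound targets; the
    coefficient matrix is learned by projected gradient descent with a Hoyer
    L1/L2 sparseness projection per column. Significant targets are called
    against a randomized-binding permutation null with empirical p-values, and
    multi-regulator modules, co-target tables and Cytoscape-ready edge lists
    are assembled. Includes a ground-truth synthetic data generator, recovery
    scoring, broom-style tidiers, ggplot2 autoplot methods, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
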