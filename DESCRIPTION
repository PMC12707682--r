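Package: permanet
Title: PERMA-Guided Multi-Topology Graph Attention Networks for Student
    Well-Being Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts student well-being from tabular behavioural, social,
    physical and mental-state features by combining Seligman's PERMA
    positive-psychology framework with multi-topology graph neural networks
    and a PERMA-aligned transformer encoder. Provides a synthetic cohort
    generator driven by latent PERMA factors, four student-relationship graph
    constructions (cosine, Euclidean-kernel, learning-style and PERMA-weighted)
    with graph-level attention fusion, a five-head attention encoder with dual
    prediction heads and a consistency-regularised multi-task loss, a PERMA
    evaluation framework (dimension accuracy, consistency index, composite
    score), paired-comparison testing, and reduced-scale ablation and
    hyperparameter-sweep harnesses. Training uses a self-contained
    reverse-mode automatic-differentiation tape written in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    methods,
    optparse,
    yaml
Config/testthat/edition: 3
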