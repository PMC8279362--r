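Package: homssp
Title: Homology-Aware Benchmarking of Protein Secondary Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how sequence homology between
    and within the datasets of a protein secondary structure prediction (SSP)
    experiment shapes its apparent and practical accuracy. Provides a synthetic
    protein-family generator with controlled pairwise identities, pairwise
    identity computation and greedy within/between dataset homology reduction,
    position-specific scoring matrix (PSSM) profiles with Shannon entropy,
    a windowed-feature bootstrapped voting ensemble predictor, Q and SOV
    accuracy measures, and orchestration of multi-repeat dataset-layout
    experiments that quantify overfitting as the gap between training and
    independent-test accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    nnet,
    rpart,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
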