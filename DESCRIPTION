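Package: grnDoE
Title: Design of Perturbation Experiments for Ensembles of Executable Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Given an ensemble of executable gene regulatory network (GRN)
    models sharing the same genes and stimuli, identifies the single most
    informative gene-perturbation experiment, predicts its outcome by
    stochastic simulation of a piecewise-deterministic Markov process
    (two-state promoter bursting coupled to mRNA/protein kinetics), and --
    given post-perturbation single-cell data -- eliminates
    topology-inconsistent candidate networks and merges the survivors into a
    refined network.  Includes topology variance indices for pre-selecting
    perturbation targets, entropy-based ranking of candidate experiments,
    summed per-gene Kantorovich (Wasserstein) distances between expression
    datasets, noisy simulated-annealing calibration of basal-expression
    parameters, and a synthetic-ensemble generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
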