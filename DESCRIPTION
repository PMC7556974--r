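Package: atomicNMF
Title: Sparse Bayesian Non-Negative Matrix Factorization with an Atomic
    Prior and Asynchronous Gibbs Updates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Bayesian non-negative matrix factorization of bulk and
    single-cell expression matrices by Gibbs sampling over an atomic prior
    (Poisson atom counts with Exponential masses, giving each factor element
    a Gamma marginal with Poisson-distributed shape). Proposals are generated
    sequentially but accumulated into a queue of mutually independent
    birth/death/move/exchange updates that can be evaluated in any order with
    results bit-identical to the sequential Markov chain. A sparse
    reformulation of the conditional-update sums makes the per-proposal cost
    proportional to the number of non-zero data entries. Includes a
    deterministic simulator for sparse single-cell-like counts with known
    ground-truth factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, Matrix, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
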