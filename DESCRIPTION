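Package: plsnet
Title: Gene Regulatory Network Inference with Partial Least Squares Ensembles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from steady-state
    expression data by decomposing the network inference problem into one
    feature-selection subproblem per target gene. Each subproblem is solved
    with SIMPLS partial least squares, candidate regulators are scored by
    their variable importance in projection (VIP), and scores are aggregated
    over randomized resamples of conditions and candidate-regulator subsets.
    Regulator rows of the resulting adjacency matrix are rescaled by their
    variance so that hub regulators are promoted. Includes DREAM-style
    evaluation of ranked edge predictions (AUPR, AUROC, overall score),
    readers and writers for DREAM-layout files, and a synthetic linear
    network simulator for end-to-end benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
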