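Package: csg2a
Title: Condition-Specific Gene-Gene Attention Networks for Chemical
    Perturbation and Drug Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models chemical-induced transcriptomic perturbation with a
    condition-specific gene-gene attention network: per-sample dot-product
    attention over gene-level condition representations is summed with a
    protein-protein interaction prior and used directly as the weights of a
    linear layer mapping basal to perturbed expression.  The pretrained
    network transfers, with frozen parameters and a learnable per-gene
    scaling layer, to cell-level drug response (log IC50) regression.
    Includes expression/PPI/response-table input-output and normalization,
    the four cross-validation partitioning schemes (mixed, cell-blind,
    drug-blind, disjoint), interpretability procedures (drug-averaged
    attention maps, mechanism-of-action correlation contrasts, differential
    expression on predicted profiles, responder separation), and a
    seed-reproducible synthetic perturbation world for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
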