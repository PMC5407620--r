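Package: temponet
Title: Temporal Process Networks for Tracking Disease Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks disease progression through a temporal network of
    biological processes built from time-series expression data. Scores the
    perturbation of every gene set (biological process) at every time point
    with a weighted running-sum enrichment statistic and a gene-label
    permutation null, links processes that share genes into an undirected
    co-membership network, enumerates high-perturbation temporal paths with
    a greedy branching search, and assesses the resulting path sets with
    overlap-factor statistics, degree-preserving edge-swap network nulls,
    and cross-dataset precision analysis. Includes a synthetic-data
    generator that plants a known perturbed path so the whole pipeline can
    be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    ggplot2
Config/testthat/edition: 3
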