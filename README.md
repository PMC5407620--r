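# temponet

Tracking disease progression through a temporal network of biological
processes.

Gradual diseases — diet-induced obesity, diabetes — perturb biological
processes in sequence: processes disturbed at an early time point push,
through the genes they share, processes disturbed later. Given a time-series
expression experiment (a gene × time-point log2 fold-change matrix, or the
probe-level replicate table it comes from) and a gene-set library of
biological processes, `temponet`:

1. scores every process at every time point with a weighted running-sum
   enrichment statistic — for a ranked list of N genes and a set S,
   `es(S) = max_i(P_hit − P_miss) + min_i(P_hit − P_miss)`, where `P_hit`
   accumulates `|r_j|/N_R` over set members and `P_miss` accumulates
   `1/(N − N_H)` over non-members — normalized against a gene-label
   permutation null (`nes`, with same-sign-tail p-values);
2. builds the **process network** whose nodes are processes and whose edges
   connect any two processes sharing at least one gene;
3. enumerates **temporal paths** (one process per time point, consecutive
   processes adjacent in the network) with a greedy branching search: the
   top-2 nes candidates at each of T selection instances give `2^T = 1024`
   paths for T = 10, with a bottom-2 "unperturbed" control and random-walk
   baselines;
4. assesses the path sets with **overlap-factor** statistics (which paths
   reuse the same edge at the same transition), degree-preserving
   double-edge-swap network nulls for per-edge chance probabilities, and
   cross-dataset **precision** of the selected paths.

A synthetic-data module generates gene-set libraries with controlled
overlap, probe-level replicate tables, and fold-change matrices with a
planted chain of perturbed processes, so the entire pipeline is testable
and reproducible without external downloads.

Intended users: computational biologists analyzing temporal microarray,
RNA-seq, or proteomics contrasts who want process-level progression
hypotheses and the genes connecting consecutive perturbed processes.

## Worked example

Everything below runs on synthetic data in a couple of minutes:

```r
library(temponet)

spec <- synthetic_spec()                  # 2000 genes, 120 processes, T = 10
sl  <- make_library(spec, seed = 1)       # planted 10-process chain inside
fc  <- make_fc_matrix(spec, sl, seed = 1)
pt  <- make_probe_table(spec, fc, seed = 1)

mat <- preprocess_probe_table(pt)         # replicate filters, dummy 0.001, drop
lib <- restrict_to_universe(prepare_library(sl$library), rownames(mat))
nm  <- nes_matrix(mat, lib, n_perm = 200, seed = 1)
net <- build_network(lib)

paths  <- systematic_paths(nm, net, branch = 2)
greedy <- systematic_paths(nm, net, branch = 1)
identical(unname(greedy$processes[1, ]), sl$planted)
#> [1] TRUE
paths
#> path_set (systematic-max): 1024 paths of length 10 (1024 distinct)
#>   mean nes: mean 1.281, range [1.122, 1.521]
overlap_summary(paths)
#> overlap report: 1024 paths, mean overlap factor 554.9844, mean nes 1.2815
bc <- best_covering(paths, k = 2)
sprintf("best pair covers %d of %d paths (%.1f%%)", bc$covered, length(paths),
        100 * bc$fraction)
#> [1] "best pair covers 953 of 1024 paths (93.1%)"
```

Reading the numbers: the branch-2 search enumerates exactly `2^10 = 1024`
paths; the pure-greedy path recovers the planted chain; the perturbed paths'
mean nes (1.28) sits far above random walks on the same grid (≈ 1.00, see
the acceptance report), and their mean overlap factor (≈ 555) shows the set
converging onto a few backbones — two paths suffice to cover 93% of the set.
Compare `systematic_paths(..., direction = "min")` for the unperturbed
control, `edge_probabilities()` + `compare_link_probability_sets()` for the
degree-preserving edge null, and `path_precision()` /
`process_precision_baseline()` for cross-dataset specificity.

Real data enters through `read_gmt()` (Enrichr-style GMT libraries),
`read_probe_table()` (TSV plus a JSON/YAML column mapping), or
`read_fc_matrix()` for an already-computed matrix. The staged runner
`run_pipeline(dir, spec, pipeline_config(), seed)` (or the thin CLI wrapper
`inst/cli/temponet.R`) writes every artifact — GMT, matrices, enrichment
tables, edge lists, path sets, overlap reports — plus JSON run manifests
with checksums.

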