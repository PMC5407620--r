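---
title: "Tracking progression through temporal process networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking progression through temporal process networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temponet)
```

## The model

Gradual diseases such as diet-induced obesity perturb biological processes in
an interdependent sequence: processes disturbed early push, through the genes
they share, processes disturbed later. `temponet` operationalizes this idea
on time-series expression data in four steps.

**1. Per-time-point process perturbation.** For each time point the genes are
ranked by descending absolute log2 fold change, and each process (gene set
$S$ with $N_H$ members inside the ranked list of $N$ genes) is scored with a
weighted running sum. Walking down the list, member genes add
$|r_j| / N_R$ (with $r_j$ the gene's signed fold change and
$N_R = \sum_{g_j \in S} |r_j|$) while non-members subtract $1/(N - N_H)$. The
enrichment score is

$$\mathrm{es}(S) \;=\; \max_i \bigl(P_{hit} - P_{miss}\bigr)(i) \;+\;
  \min_i \bigl(P_{hit} - P_{miss}\bigr)(i),$$

the *maximum plus the minimum* of the running sum — deliberately not the
classic single max-deviation GSEA statistic (that variant is available via
`method = "max_deviation"` for comparison, but the max-plus-min form is the
default and the one all downstream results use). The null distribution
permutes gene labels, which is equivalent to drawing uniformly random hit
positions; `nes = es / mean(same-sign null portion)` and the p-value is the
same-sign tail fraction over all permutations, ties counting. Because the
null depends only on the ranked weights and $N_H$, nulls are shared across
equal-sized sets within a time point (sub-seeded from the master seed), which
cuts runtime by roughly the number of distinct set sizes.

**2. The process network.** Processes become nodes; two processes are linked
whenever they share at least one gene, and the edge stores the shared genes.
The working process list is derived from a GMT library by keeping only
subset-minimal sets ("subset" read as *proper* subset, so exact duplicates
both survive) and then sets with more than 15 genes — in that order.

**3. Temporal paths.** A path visits one process per time point, consecutive
processes adjacent in the network. The systematic search picks, at time
point 1, the top-`branch` processes by nes among all nodes and, at every
later time point, the top-`branch` among the current node's neighbors,
branching depth-first: `branch = 2` over 10 time points enumerates
$2^{10} = 1024$ paths. Ties are broken by ascending process name so builds
are reproducible; converging duplicate paths are retained so the $2^T$
accounting holds. Setting `direction = "min"` builds the lowest-nes control
set; random-walk baselines (`random_paths()`) start at a uniform non-isolated
node and step uniformly over neighbors, revisits allowed in both procedures
(immediate repetition is impossible because the network has no self-edges).

**4. Assessment.** Three independent lenses:

* *Overlap factor.* For path $i$ and transition $j$, $O(e_i^{j,j+1})$ is the
  set of other paths using the same unordered process pair at the same
  transition; $O(P_i)$ is the union over transitions, reported numerically as
  its cardinality. Converging path sets score high; edge-disjoint sets score
  0. `resampled_null()` calibrates the statistic on random-path pools, and
  `best_covering()` finds the one or two paths whose overlap sets (plus the
  chosen paths themselves) cover the most paths.
* *Degree-preserving network null.* Each observed edge's chance probability
  is the fraction of double-edge-swap randomizations (degrees conserved
  exactly, self/duplicate edges rejected) in which the pair stays connected.
  Edges inside high-perturbation paths having systematically lower
  probability than edges at large indicates the links are not explained by
  hub degrees.
* *Cross-dataset precision.* A path's mean nes is recomputed in other
  datasets (aligning its last $k$ processes when a dataset has only $k < T$
  time points); comparison values at or above the source value are false
  positives under a detection threshold just below the source value, so
  precision is $100 \cdot tp/(tp+fp)$ and the exceedance probability is the
  exceedance fraction. Ties count against the method.

## Preprocessing probe tables

Replicate-level tables (three log2 fold-change values plus a t-test p-value
per probe per time point) are reduced to one gene-by-time matrix:

1. *Primary fill*: a cell is filled with a probe's replicate mean when all
   three replicates exceed 2-fold (|log2 FC| > 1); among qualifying probes of
   a gene the minimum-p probe wins, ties resolved by probe id.
2. *Secondary fill* for remaining cells of retained genes: candidate probes
   have at least two of three replicates outside [-1, 1], falling back to
   probes entirely inside; probes whose replicates share a strict sign are
   preferred (three-replicate mean), then probes with a same-sign pair (mean
   of the pair). Averages strictly inside (-0.8, 0.8) become the dummy value
   0.001 — the placeholder for measured-but-unperturbed cells — as does any
   cell with no qualifying probe (logged). Zero breaks sign agreement.
3. *Merging* of two labels measuring the same day (weeks convert to days as
   $7w + 14$, so Week 0 coincides with Day 14): same-direction perturbed
   pairs average, opposite directions get the dummy, one-sided perturbation
   passes through, and unperturbed pairs deterministically keep the first
   label's value — a fixed choice where any value would do, made for
   reproducibility.
4. Genes never perturbed at any time point are dropped.

Every final cell is therefore either a rule-derived replicate average or
exactly 0.001, an invariant the tests assert.

## The synthetic study conditions

`synthetic_spec()` defines the conditions every pipeline stage is exercised
under: 2000 genes, 120 processes with a truncated power-law size distribution
(minimum 16, exponent 2.5), 10 time points, and a planted chain of 10
processes — one per time point — whose consecutive members are forced to
share a connector gene. Genes of planted process $j$ receive
|log2 FC| ≥ 3 (the effect size) at time point $j$ with random signs;
replicate noise is 0.1.

Background cells mix centered Gaussian noise (sd 0.2) with spurious fold
changes: each cell independently receives, with probability 0.35, a value of
magnitude U(0.85, 2.5). This emulates two features of real matrices that
matter to the statistic: most genes exceed the 2-fold threshold somewhere
(so they survive the never-perturbed drop), and ranked lists carry a
*continuous* weight spectrum. The latter is load-bearing: if background
weights were all-or-nothing, any set sharing one or two top-ranked genes
with a truly perturbed set — with the rest of its members at the dummy
value — would reach es ≈ 1, because those couple of heavy hits carry
essentially all of $N_R$. With the chosen rate, a typical set has
probability ≈ $0.65^{15} \approx 10^{-3}$ of being entirely dummy-valued at
a time point, so the degenerate case is rare, as it is in real data. The
magnitude range deliberately dips below the 2-fold threshold so the
secondary fill's 0.8 band is exercised and moderate weights populate the
list.

What passing tests on these conditions do **not** show: robustness to probe
sets with systematically biased replicates, to temporally correlated
background drift, to unbalanced time-point spacing, or to gene sets whose
true perturbation is partial. The generator draws cells independently and
perturbs whole sets; real data does neither.

## Numerical and design choices

* Thresholds are strict as printed: perturbation means |v| > 1; an average
  keeps the cell iff |a| ≥ 0.8; the size filter keeps sets with > 15 genes.
* The dummy is inserted as +0.001 regardless of the sign of the candidate
  average.
* p-values of 0 are reported as computed; the permutation count is carried
  so the resolution floor 1/n_perm is always recoverable, and a degenerate
  null (no same-sign mass) yields `nes = NA` with the floored p-value and a
  flag rather than a silent zero.
* Enrichment is invariant to positive rescaling of all fold changes (both
  $P_{hit}$ terms rescale and cancel); a test asserts this.
* The number of swap attempts per randomized network defaults to 10 per
  edge; graphs with no legal swap (a triangle) come back unchanged.
* Coverage counting for the best pair includes the two chosen paths; the
  union of the overlap sets alone is also reported.
* Pools smaller than the branch factor branch over what exists (tiny test
  graphs hit this; a 51549-edge working network never does); a branch
  reaching an isolated pool is aborted and counted.
* Resampling uses 1000 repetitions of 1024-path draws by default; both
  counts are configuration, since reports of the repetition count vary.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
enrichment grids of 120 × 10 at 200 permutations per null, networks of
~110 nodes and ~800 edges, 1024-path systematic sets, 20000-walk random
pools, 300 network randomizations, and 10–20 generator seeds per property.
These sizes were chosen so that permutation nulls are stable (Monte-Carlo
error on a null mean well under the nes contrasts being tested) while a full
run stays in the minutes range; every quantity printed by
`scripts/acceptance.R` is recomputed from scratch at run time.

## Known limitations

* The max-plus-min statistic weakly separates "all members at the top" from
  "few heavy members plus dummy-weight members" whenever the weight spectrum
  collapses to two values; see the synthetic-conditions section.
* The exhaustive pair search in `best_covering()` is quadratic in the number
  of paths and guarded by `max_paths`; no greedy set-cover generalization
  beyond k = 2 is provided.
* No FDR control, leading-edge extraction, or phenotype permutation: the
  method uses gene-label permutation and raw p-values only.
* Cross-dataset evaluation recomputes nes within each dataset's own gene
  universe; processes absent from a dataset are skipped with a warning
  rather than imputed.

## A worked run

```{r run, eval = FALSE}
spec <- synthetic_spec()
sl  <- make_library(spec, seed = 1)
fc  <- make_fc_matrix(spec, sl, seed = 1)
pt  <- make_probe_table(spec, fc, seed = 1)
mat <- preprocess_probe_table(pt)
lib <- restrict_to_universe(prepare_library(sl$library), rownames(mat))
nm  <- nes_matrix(mat, lib, n_perm = 200, seed = 1)
net <- build_network(lib)

paths <- systematic_paths(nm, net, branch = 2)          # 1024 paths
greedy <- systematic_paths(nm, net, branch = 1)
identical(unname(greedy$processes[1, ]), sl$planted)    # planted chain found

overlap_summary(paths)
best_covering(paths, k = 2)
```

The staged equivalent, writing every artifact plus run manifests to a
directory, is `run_pipeline(dir, spec, pipeline_config(), seed = 1)`, or the
command-line wrapper `inst/cli/temponet.R`.
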