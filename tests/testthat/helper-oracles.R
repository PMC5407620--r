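# Independent oracles and small fixture builders, kept deliberately naive so
# they stay independent of the implementation they check.

# naive double-loop running sum: P_hit - P_miss computed by direct summation
naive_running_sum <- function(genes, weights, set) {
  n <- length(genes)
  hit <- genes %in% set
  nr <- sum(abs(weights[hit]))
  nh <- sum(hit)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ph <- 0
    pm <- 0
    for (j in seq_len(i)) {
      if (hit[j]) ph <- ph + abs(weights[j]) / nr
      else pm <- pm + 1 / (n - nh)
    }
    out[i] <- ph - pm
  }
  out
}

naive_es <- function(genes, weights, set) {
  rs <- naive_running_sum(genes, weights, set)
  max(rs) + min(rs)
}

# brute-force subset-minimal filter: all-pairs proper-subset check
naive_subset_minimal <- function(sets) {
  keep <- rep(TRUE, length(sets))
  for (p in seq_along(sets)) {
    for (q in seq_along(sets)) {
      if (p == q) next
      if (length(sets[[q]]) < length(sets[[p]]) &&
          all(sets[[q]] %in% sets[[p]])) {
        keep[p] <- FALSE
      }
    }
  }
  sets[keep]
}

# random gene-set library over a small universe
random_library <- function(n_sets, n_genes = 50, min_size = 2, max_size = 12,
                           seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(genes, sample(min_size:max_size, 1))
  })
  names(sets) <- sprintf("S%03d", seq_len(n_sets))
  geneset_library(sets)
}

# fabricate a nes_matrix object directly from a numeric grid
fake_nes <- function(grid, n_perm = 1000L) {
  structure(
    list(es = grid, nes = grid, pvalue = grid * 0,
         size = stats::setNames(rep(10L, nrow(grid)), rownames(grid)),
         processes = rownames(grid), timepoints = colnames(grid),
         n_perm = n_perm, method = "max_plus_min",
         failures = data.frame(process = character(0),
                               timepoint = character(0),
                               reason = character(0))),
    class = "nes_matrix"
  )
}

# a path_set built from a character matrix
make_paths <- function(m, provenance = "random", mean_nes = NULL) {
  path_set(m, provenance = provenance, mean_nes = mean_nes)
}

# random path set over a small node alphabet (no adjacency constraint needed
# for overlap algebra checks)
random_path_set <- function(n_paths, t = 5, n_nodes = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(LETTERS[seq_len(n_nodes)], n_paths * t, replace = TRUE),
              nrow = n_paths)
  make_paths(m)
}

# probe table with a single time point from a matrix of replicate triplets
single_tp_probes <- function(reps, pvals = NULL, genes = NULL, ids = NULL,
                             tp = "Day 1") {
  n <- nrow(reps)
  probe_table(
    probe_id = ids %||% sprintf("pr%02d", seq_len(n)),
    gene_symbol = genes %||% sprintf("g%02d", seq_len(n)),
    timepoints = tp,
    values = array(reps, dim = c(n, 1L, 3L)),
    pvalues = matrix(pvals %||% rep(0.5, n), ncol = 1L)
  )
}

# small planted synthetic scenario used by several module tests (direct
# fold-change route, no probe table)
small_scenario <- function(seed = 1, n_genes = 600, n_processes = 40,
                           n_timepoints = 5, n_perm = 100) {
  spec <- synthetic_spec(n_genes = n_genes, n_processes = n_processes,
                         n_timepoints = n_timepoints)
  sl <- make_library(spec, seed = seed)
  fc <- make_fc_matrix(spec, sl, seed = seed)
  mat <- drop_never_perturbed(fc$matrix)
  lib <- suppressWarnings(
    restrict_to_universe(prepare_library(sl$library), rownames(mat)))
  nm <- nes_matrix(mat, lib, n_perm = n_perm, seed = seed)
  net <- build_network(lib)
  list(spec = spec, sl = sl, fc = fc, mat = mat, lib = lib, nm = nm, net = net)
}
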