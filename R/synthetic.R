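#' Specification for the synthetic study conditions
#'
#' Defines the synthetic gene-set library and temporal fold-change data the
#' generators emulate: a heavy-tailed set-size distribution, shared-gene
#' connectivity, and a planted chain of perturbed processes, one per time
#' point, connected in the process network. Defaults are sized for stable
#' permutation nulls at sub-minute runtimes: 2000 genes, 120 processes, 10
#' time points, a planted chain of length 10, an effect size of 3 (log2
#' fold change of planted-process genes at their time point) over a
#' background noise scale of 0.2.
#'
#' @param n_genes Gene universe size (default 2000).
#' @param n_processes Number of gene sets (default 120).
#' @param n_timepoints Number of time points T (default 10).
#' @param path_length Length of the planted chain (default `n_timepoints`;
#'   must not exceed it, nor `n_processes`).
#' @param effect Log2 fold-change magnitude planted in the genes of the
#'   planted process at its time point (default 3).
#' @param noise Background log2 fold-change noise sd (default 0.2; must be
#'   below `effect`).
#' @param replicate_noise Probe replicate noise sd (default 0.1).
#' @param background_rate Per-cell probability of a spurious background
#'   fold change (default 0.35), emulating the pervasive incidental
#'   perturbation of real expression data so that most genes survive the
#'   never-perturbed drop.
#' @param background_range Log2 magnitude range of spurious fold changes
#'   (default `c(0.85, 2.5)`): the range spans both moderate sub-threshold
#'   values (which real matrices retain through the secondary-fill band) and
#'   clear 2-fold changes, giving the ranked lists a continuous weight
#'   spectrum rather than an all-or-nothing one; the upper end stays below
#'   the planted effect.
#' @param size_alpha Power-law-like exponent of the set-size distribution
#'   (default 2.5).
#' @param min_size Minimum set size (default 16, matching the working-list
#'   size filter).
#' @param max_size Maximum set size (default `n_genes %/% 10`).
#' @param overlap_rate Fraction of each set's genes drawn from the shared
#'   gene pool (1 = natural co-membership overlap; 0 = pairwise disjoint
#'   sets outside the planted chain).
#' @param positive_effects Force planted fold changes positive (default
#'   FALSE: random signs).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_processes = 120L,
                           n_timepoints = 10L, path_length = n_timepoints,
                           effect = 3, noise = 0.2, replicate_noise = 0.1,
                           background_rate = 0.35,
                           background_range = c(0.85, 2.5),
                           size_alpha = 2.5, min_size = 16L, max_size = NULL,
                           overlap_rate = 1, positive_effects = FALSE) {
  max_size <- max_size %||% (n_genes %/% 10L)
  if (!is_count(n_genes, 10L) || !is_count(n_processes, 2L) ||
      !is_count(n_timepoints, 2L)) {
    stopf("n_genes, n_processes, n_timepoints must be positive integers")
  }
  if (!is_count(path_length, 2L) || path_length > n_timepoints ||
      path_length > n_processes) {
    stopf("path_length must satisfy 2 <= path_length <= min(n_timepoints, n_processes)")
  }
  if (!is_number(effect) || !is_number(noise) || effect <= noise) {
    stopf("effect size must exceed the noise scale")
  }
  if (overlap_rate < 0 || overlap_rate > 1) stopf("overlap_rate must be in [0,1]")
  if (min_size < 1L || max_size < min_size) stopf("invalid size bounds")
  if (background_rate < 0 || background_rate > 1) {
    stopf("background_rate must be in [0,1]")
  }
  if (length(background_range) != 2L || background_range[1] > background_range[2]) {
    stopf("background_range must be an increasing length-2 vector")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_processes = as.integer(n_processes),
         n_timepoints = as.integer(n_timepoints),
         path_length = as.integer(path_length),
         effect = effect, noise = noise, replicate_noise = replicate_noise,
         background_rate = background_rate,
         background_range = background_range,
         size_alpha = size_alpha, min_size = as.integer(min_size),
         max_size = as.integer(max_size), overlap_rate = overlap_rate,
         positive_effects = positive_effects),
    class = "synthetic_spec"
  )
}

# discrete power-law-like sizes via inverse-transform sampling, truncated
.sample_sizes <- function(n, alpha, smin, smax) {
  u <- stats::runif(n)
  s <- floor(smin * (1 - u)^(-1 / (alpha - 1)))
  pmin(pmax(s, smin), smax)
}

#' Generate a synthetic gene-set library with a planted chain
#'
#' Draws `n_processes` sets with a power-law-like size distribution over a
#' shared gene universe. The first `path_length` processes form the planted
#' chain: every consecutive pair is forced to share at least one deliberately
#' planted connector gene, so the process network contains the chain as a
#' path. With `overlap_rate < 1` part of each set is drawn from a private
#' gene block, down to pairwise-disjoint non-chain sets at 0.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List of class `synthetic_library`: `library` (a
#'   `geneset_library`), `planted` (chain process names in order),
#'   `connectors` (data frame `transition`, `from`, `to`, `gene`).
#' @export
make_library <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  nms <- sprintf("P%03d", seq_len(spec$n_processes))
  sizes <- .sample_sizes(spec$n_processes, spec$size_alpha,
                         spec$min_size, spec$max_size)
  block_len <- spec$n_genes %/% spec$n_processes
  sets <- vector("list", spec$n_processes)
  for (i in seq_len(spec$n_processes)) {
    sz <- sizes[i]
    n_common <- stats::rbinom(1L, sz, spec$overlap_rate)
    n_private <- sz - n_common
    if (n_private > block_len) {
      stopf("overlap constraints infeasible: set of size %d needs %d private genes but blocks hold %d",
            sz, n_private, block_len)
    }
    block <- genes[((i - 1L) * block_len + 1L):(i * block_len)]
    g <- character(0)
    if (n_private > 0L) g <- sample(block, n_private)
    if (n_common > 0L) g <- union(g, sample(genes, n_common))
    while (length(g) < sz) g <- union(g, sample(genes, sz - length(g)))
    sets[[i]] <- g
  }
  names(sets) <- nms
  # plant connector genes between consecutive chain processes
  connectors <- data.frame(transition = integer(0), from = character(0),
                           to = character(0), gene = character(0),
                           stringsAsFactors = FALSE)
  for (j in seq_len(spec$path_length - 1L)) {
    shared <- intersect(sets[[j]], sets[[j + 1L]])
    gene <- if (length(shared)) shared[1L] else {
      cg <- sample(sets[[j]], 1L)
      sets[[j + 1L]] <- union(sets[[j + 1L]], cg)
      cg
    }
    connectors <- rbind(connectors, data.frame(
      transition = j, from = nms[j], to = nms[j + 1L], gene = gene,
      stringsAsFactors = FALSE))
  }
  structure(
    list(library = geneset_library(sets),
         planted = nms[seq_len(spec$path_length)],
         connectors = connectors),
    class = "synthetic_library"
  )
}

#' @export
print.synthetic_library <- function(x, ...) {
  print(x$library)
  cat(sprintf("  planted chain: %s\n", paste(x$planted, collapse = " -> ")))
  invisible(x)
}

#' Generate a temporal fold-change matrix with a planted perturbed path
#'
#' Background values are centered Gaussian noise; the genes of planted
#' process j receive `|log2 FC| >= effect` at time point j (random signs
#' unless `positive_effects`). A gene belonging to several planted processes
#' is perturbed at each of their time points.
#'
#' @param spec A [synthetic_spec()].
#' @param lib A [make_library()] result (or a plain `geneset_library` when
#'   no planting is wanted — then pass `planted = character(0)`).
#' @param seed Integer seed.
#' @param planted Optional override of the planted chain.
#' @return List of class `synthetic_fc`: `matrix` (gene x time point,
#'   labels `"Day 1"` ... `"Day T"`), `truth` (data frame `process`,
#'   `timepoint`, `n_genes`), `planted_cells` (data frame `gene`,
#'   `timepoint`, `value`).
#' @export
make_fc_matrix <- function(spec, lib, seed = 1L, planted = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (inherits(lib, "synthetic_library")) {
    planted <- planted %||% lib$planted
    library <- lib$library
  } else {
    stopifnot(inherits(lib, "geneset_library"))
    planted <- planted %||% character(0)
    library <- lib
  }
  set.seed(seed + 1L)
  genes <- library$universe
  tps <- paste("Day", seq_len(spec$n_timepoints))
  mat <- matrix(stats::rnorm(length(genes) * spec$n_timepoints, 0, spec$noise),
                nrow = length(genes), dimnames = list(genes, tps))
  # spurious background perturbations, as in real expression data where most
  # genes exceed the fold-change threshold at some time point
  if (spec$background_rate > 0) {
    hit <- which(stats::runif(length(mat)) < spec$background_rate)
    mag <- stats::runif(length(hit), spec$background_range[1],
                        spec$background_range[2])
    sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
    mat[hit] <- sgn * mag
  }
  cells <- list()
  for (j in seq_along(planted)) {
    g <- library$sets[[planted[j]]]
    mag <- spec$effect + abs(stats::rnorm(length(g), 0, spec$noise))
    sgn <- if (spec$positive_effects) 1 else sample(c(-1, 1), length(g), replace = TRUE)
    mat[g, j] <- sgn * mag
    cells[[j]] <- data.frame(gene = g, timepoint = tps[j], value = mat[g, j],
                             stringsAsFactors = FALSE)
  }
  truth <- if (length(planted)) {
    data.frame(process = planted, timepoint = tps[seq_along(planted)],
               n_genes = vapply(library$sets[planted], length, 1L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(process = character(0), timepoint = character(0),
               n_genes = integer(0))
  }
  structure(
    list(matrix = mat, truth = truth,
         planted_cells = if (length(cells)) do.call(rbind, cells)
                         else data.frame(gene = character(0),
                                         timepoint = character(0),
                                         value = numeric(0))),
    class = "synthetic_fc"
  )
}

#' Generate a probe-level replicate table from a fold-change matrix
#'
#' Emits 1-3 probes per gene. The first probe of each gene carries replicate
#' triplets equal to the matrix value plus replicate noise; additional
#' probes are degraded copies (value scaled by 0.3) so that probe selection
#' by p-value is exercised. P-values are small where the underlying value is
#' perturbed and large elsewhere. Sub-threshold cells naturally exercise the
#' secondary-fill branches (all-inside-band and mixed-sign replicates).
#'
#' @param spec A [synthetic_spec()].
#' @param fc A [make_fc_matrix()] result or a plain gene x time-point matrix.
#' @param seed Integer seed.
#' @return A [probe_table()].
#' @export
make_probe_table <- function(spec, fc, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mat <- if (inherits(fc, "synthetic_fc")) fc$matrix else fc
  set.seed(seed + 2L)
  genes <- rownames(mat)
  n_probes <- sample(1:3, length(genes), replace = TRUE,
                     prob = c(0.6, 0.3, 0.1))
  gene_of_probe <- rep(genes, n_probes)
  copy_idx <- unlist(lapply(n_probes, seq_len))
  n <- length(gene_of_probe)
  tn <- ncol(mat)
  probe_id <- sprintf("%s_pr%d", gene_of_probe, copy_idx)
  base_vals <- mat[gene_of_probe, , drop = FALSE]
  # degraded secondary probes: attenuated signal, noisier p-values
  atten <- ifelse(copy_idx == 1L, 1, 0.3)
  values <- array(NA_real_, dim = c(n, tn, 3L))
  for (k in 1:3) {
    values[, , k] <- base_vals * atten +
      matrix(stats::rnorm(n * tn, 0, spec$replicate_noise), n, tn)
  }
  perturbed <- abs(base_vals * atten) > 1
  pvalues <- matrix(stats::runif(n * tn, 0.05, 1), n, tn)
  # primary probes of perturbed cells get the smallest p-values; degraded
  # copies stay noisier so min-p probe selection prefers the faithful probe
  copy_mat <- matrix(copy_idx, n, tn)
  p1 <- perturbed & copy_mat == 1L
  p2 <- perturbed & copy_mat > 1L
  pvalues[p1] <- stats::runif(sum(p1), 0, 0.01)
  pvalues[p2] <- stats::runif(sum(p2), 0.02, 0.2)
  probe_table(probe_id, gene_of_probe, colnames(mat), values, pvalues)
}
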