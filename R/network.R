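#' Build the shared-gene process network
#'
#' Undirected graph whose nodes are processes (gene sets) and whose edges
#' connect any two processes sharing at least one gene. Each edge is
#' annotated with the shared genes; each node carries its set size.
#'
#' @param library A `geneset_library` with at least two sets.
#' @return An `igraph` graph with vertex attributes `name`, `size` and edge
#'   attributes `shared_count`, `shared` (list of character vectors).
#' @export
build_network <- function(library) {
  stopifnot(inherits(library, "geneset_library"))
  n <- length(library$sets)
  if (n < 2L) stopf("need at least two gene sets to build a network")
  gene_idx <- lapply(library$sets, match, table = library$universe)
  inc <- Matrix::sparseMatrix(
    i = unlist(gene_idx, use.names = FALSE),
    j = rep.int(seq_len(n), lengths(gene_idx)),
    x = 1,
    dims = c(length(library$universe), n)
  )
  inter <- Matrix::crossprod(inc)
  inter <- methods::as(Matrix::triu(inter, k = 1), "TsparseMatrix")
  keep <- inter@x >= 1
  from <- inter@i[keep] + 1L
  to <- inter@j[keep] + 1L
  nms <- names(library$sets)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nms[from], to = nms[to], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nms, size = unname(set_sizes(library)),
                          stringsAsFactors = FALSE)
  )
  shared <- mapply(function(a, b) intersect(library$sets[[a]], library$sets[[b]]),
                   from, to, SIMPLIFY = FALSE)
  igraph::E(g)$shared_count <- lengths(shared)
  igraph::E(g)$shared <- shared
  g
}

#' Size and degree distributions of a process network
#'
#' Binned, total-normalized histograms of gene-set sizes and node degrees
#' (suitable for log-log plotting of heavy-tailed distributions).
#'
#' @param network Graph from [build_network()].
#' @param bin_width Width of the histogram bins (default 1).
#' @return List of two data frames (`size`, `degree`) with columns
#'   `bin_start`, `count`, `frequency`; frequencies sum to 1.
#' @export
network_distributions <- function(network, bin_width = 1) {
  if (igraph::vcount(network) == 0L) stopf("empty network")
  binned <- function(x) {
    start <- floor(min(x) / bin_width) * bin_width
    bins <- floor((x - start) / bin_width)
    tab <- table(bins)
    data.frame(
      bin_start = start + as.numeric(names(tab)) * bin_width,
      count = as.integer(tab),
      frequency = as.numeric(tab) / length(x)
    )
  }
  list(size = binned(igraph::V(network)$size),
       degree = binned(igraph::degree(network)))
}

#' Degree-preserving randomization of a network
#'
#' Randomizes the topology by repeated double-edge swaps; swaps that would
#' create self-edges or duplicate edges are rejected, so the degree sequence
#' is conserved exactly. Shared-gene annotations are dropped: the null is
#' purely topological. Networks with no legal swap (e.g. a triangle) come
#' back with the original edge set.
#'
#' @param network Graph from [build_network()].
#' @param seed Optional integer seed.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @return Rewired `igraph` graph with the same degree sequence.
#' @export
degree_preserving_shuffle <- function(network, seed = NULL, swap_factor = 10) {
  if (igraph::ecount(network) < 2L) stopf("need at least two edges to shuffle")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::rewire(network, igraph::keeping_degseq(
    loops = FALSE, niter = ceiling(swap_factor * igraph::ecount(network))))
  for (a in igraph::edge_attr_names(g)) g <- igraph::delete_edge_attr(g, a)
  g
}

#' Chance probability of every observed edge under the degree-preserving null
#'
#' Generates `n_random` independent degree-preserving shuffles and, for every
#' edge of the observed network, reports the fraction of shuffles in which
#' that process pair is connected. A low probability marks an edge that is
#' not explained by the degrees of its endpoints.
#'
#' @inheritParams degree_preserving_shuffle
#' @param n_random Number of random networks (default 10000).
#' @return Data frame `from`, `to`, `probability` with attribute
#'   `n_random`.
#' @export
edge_probabilities <- function(network, n_random = 10000L, seed = NULL,
                               swap_factor = 10) {
  if (!is_count(n_random)) stopf("n_random must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  ends <- igraph::as_edgelist(network, names = FALSE)
  vp <- as.vector(t(ends))
  counts <- numeric(nrow(ends))
  for (i in seq_len(n_random)) {
    g <- igraph::rewire(network, igraph::keeping_degseq(
      loops = FALSE, niter = ceiling(swap_factor * igraph::ecount(network))))
    counts <- counts + (igraph::get_edge_ids(g, vp) > 0)
  }
  nm <- igraph::V(network)$name
  out <- data.frame(
    from = nm[ends[, 1L]], to = nm[ends[, 2L]],
    probability = counts / n_random,
    stringsAsFactors = FALSE
  )
  attr(out, "n_random") <- n_random
  out
}

#' Compare link probabilities of a path-derived edge subset against all edges
#'
#' Reports both sample means and standard deviations together with a Welch
#' two-sample t-test and a Mann-Whitney U test, as used to show that edges
#' inside perturbed paths have lower chance probability than edges at large.
#'
#' @param probs_subset,probs_all Numeric vectors of edge probabilities
#'   (each of length >= 2).
#' @return List of class `link_prob_comparison` with means, sds, and both
#'   test statistics and p-values.
#' @export
compare_link_probability_sets <- function(probs_subset, probs_all) {
  if (length(probs_subset) < 2L || length(probs_all) < 2L) {
    stopf("both probability samples must contain at least two values")
  }
  tt <- stats::t.test(probs_subset, probs_all)
  wt <- suppressWarnings(stats::wilcox.test(probs_subset, probs_all))
  structure(
    list(mean_subset = mean(probs_subset), sd_subset = stats::sd(probs_subset),
         mean_all = mean(probs_all), sd_all = stats::sd(probs_all),
         t_statistic = unname(tt$statistic), t_pvalue = tt$p.value,
         u_statistic = unname(wt$statistic), u_pvalue = wt$p.value,
         n_subset = length(probs_subset), n_all = length(probs_all)),
    class = "link_prob_comparison"
  )
}

#' @export
print.link_prob_comparison <- function(x, ...) {
  cat(sprintf("link probabilities: subset %.3f+-%.3f (n=%d) vs all %.3f+-%.3f (n=%d)\n",
              x$mean_subset, x$sd_subset, x$n_subset,
              x$mean_all, x$sd_all, x$n_all))
  cat(sprintf("  Welch t = %.3f (p = %.3g); Mann-Whitney U = %.1f (p = %.3g)\n",
              x$t_statistic, x$t_pvalue, x$u_statistic, x$u_pvalue))
  invisible(x)
}

#' Export a process network
#'
#' Writes an edge-list TSV (`process_a`, `process_b`, `shared_gene_count`,
#' `shared_genes` semicolon-joined) and, optionally, GraphML for network
#' viewers.
#'
#' @param network Graph from [build_network()].
#' @param path TSV path.
#' @param graphml Optional GraphML path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, graphml = NULL) {
  ends <- igraph::as_edgelist(network)
  shared <- igraph::E(network)$shared
  df <- data.frame(
    process_a = ends[, 1L], process_b = ends[, 2L],
    shared_gene_count = igraph::E(network)$shared_count %||%
      rep(NA_integer_, nrow(ends)),
    shared_genes = if (is.null(shared)) "" else
      vapply(shared, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- network
    if (!is.null(shared)) {
      igraph::E(g)$shared <- vapply(shared, paste, "", collapse = ";")
    }
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
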