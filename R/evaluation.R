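#' Mean nes of a path evaluated in another dataset
#'
#' When the other dataset has fewer time points than the path (k < T), the
#' path's last k processes are aligned to the dataset's k time points.
#' Processes absent from the other dataset's grid are excluded from the mean
#' with a warning.
#'
#' @param path Character vector of process names (length T).
#' @param other_nes A `nes_matrix` with k <= T time points.
#' @return Mean nes over the aligned positions.
#' @export
path_nes_in_dataset <- function(path, other_nes) {
  stopifnot(inherits(other_nes, "nes_matrix"))
  k <- length(other_nes$timepoints)
  if (k > length(path)) {
    stopf("dataset has more time points (%d) than the path (%d)", k, length(path))
  }
  aligned <- utils::tail(path, k)
  rows <- match(aligned, other_nes$processes)
  if (anyNA(rows)) {
    warnf("process(es) absent from the dataset grid, excluded from the mean: %s",
          paste(aligned[is.na(rows)], collapse = ", "))
  }
  vals <- other_nes$nes[cbind(rows, seq_len(k))]
  if (all(is.na(vals))) stopf("no path process could be evaluated in this dataset")
  mean(vals, na.rm = TRUE)
}

#' Precision from true/false positive counts
#'
#' @param true_positives,false_positives Non-negative counts with
#'   `tp + fp >= 1`.
#' @return List with `precision` (exact percentage) and `percent` (nearest
#'   integer percent).
#' @export
precision_from_counts <- function(true_positives, false_positives) {
  if (!is_count(true_positives, 0L) || !is_count(false_positives, 0L)) {
    stopf("counts must be non-negative integers")
  }
  total <- true_positives + false_positives
  if (total == 0L) stopf("tp + fp must be at least 1")
  p <- 100 * true_positives / total
  list(precision = p, percent = round(p))
}

#' Exceedance probability
#'
#' The probability of obtaining, from a comparison value, a score at least as
#' high as the source value: exceedances over total comparisons.
#'
#' @param n_exceed Number of comparison values >= the source value.
#' @param n_total Total number of comparisons (>= 1).
#' @return Numeric probability.
#' @export
exceedance_probability <- function(n_exceed, n_total) {
  if (!is_count(n_total)) stopf("n_total must be a positive integer")
  if (!is_count(n_exceed, 0L) || n_exceed > n_total) {
    stopf("need 0 <= n_exceed <= n_total")
  }
  n_exceed / n_total
}

#' Single-process precision baseline
#'
#' Collects a process's nes at every other time point of the source dataset
#' and at every time point of every other dataset, then counts how many of
#' those comparison values reach the source value. With a detection
#' threshold just below the source value, every such comparison is a false
#' positive and the source itself the one true positive.
#' A tie (comparison value exactly equal to the source) counts against the
#' method.
#'
#' @param process Process name.
#' @param source_nes Source dataset `nes_matrix`.
#' @param source_timepoint Time point (label or index) defining the source
#'   value.
#' @param all_nes_matrices List of `nes_matrix` objects for the other
#'   datasets.
#' @return List of class `precision_report`: `source_value`, `n_exceed`,
#'   `n_total`, `precision`, `percent`, `exceedance_probability`, `values`.
#' @export
process_precision_baseline <- function(process, source_nes, source_timepoint,
                                       all_nes_matrices) {
  stopifnot(inherits(source_nes, "nes_matrix"))
  row <- match(process, source_nes$processes)
  if (is.na(row)) stopf("process %s absent from the source dataset", process)
  t <- if (is.character(source_timepoint)) {
    match(source_timepoint, source_nes$timepoints)
  } else source_timepoint
  if (is.na(t) || t < 1 || t > length(source_nes$timepoints)) {
    stopf("unknown source time point")
  }
  src <- source_nes$nes[row, t]
  if (is.na(src)) stopf("source nes value is missing")
  vals <- source_nes$nes[row, -t]
  for (m in all_nes_matrices) {
    r <- match(process, m$processes)
    if (is.na(r)) {
      warnf("process %s absent from a comparison dataset; skipped", process)
      next
    }
    vals <- c(vals, m$nes[r, ])
  }
  vals <- vals[!is.na(vals)]
  n_exceed <- sum(vals >= src)
  prec <- precision_from_counts(1L, n_exceed)
  structure(
    list(process = process, source_value = src,
         n_exceed = n_exceed, n_total = length(vals),
         precision = prec$precision, percent = prec$percent,
         exceedance_probability = exceedance_probability(n_exceed, length(vals)),
         values = vals),
    class = "precision_report"
  )
}

#' Path-level precision across datasets
#'
#' Evaluates a path's mean nes in the source dataset and in every comparison
#' dataset (with last-k alignment for shorter datasets); comparison values
#' reaching the source mean are false positives under a threshold just below
#' the source value.
#'
#' @param path Character vector of process names.
#' @param source_nes Source dataset `nes_matrix`.
#' @param other_nes_list List of comparison `nes_matrix` objects.
#' @return List of class `precision_report` (with per-dataset `values`).
#' @export
path_precision <- function(path, source_nes, other_nes_list) {
  src <- path_nes_in_dataset(path, source_nes)
  vals <- vapply(other_nes_list, function(m) path_nes_in_dataset(path, m), 0.0)
  n_exceed <- sum(vals >= src)
  prec <- precision_from_counts(1L, n_exceed)
  structure(
    list(process = NULL, source_value = src,
         n_exceed = n_exceed, n_total = length(vals),
         precision = prec$precision, percent = prec$percent,
         exceedance_probability = exceedance_probability(n_exceed,
                                                         max(length(vals), 1L)),
         values = vals),
    class = "precision_report"
  )
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("precision: %d%% (1 true positive, %d false positives of %d comparisons)\n",
              x$percent, x$n_exceed, x$n_total))
  cat(sprintf("  source value %.4f; exceedance probability %.4f\n",
              x$source_value, x$exceedance_probability))
  invisible(x)
}

#' Bipartite gene-process graph of a path
#'
#' Connects each path process (tagged by its time-point position, since a
#' process may recur) to its member genes whose absolute log2 fold change
#' exceeds the cutoff at that process's time point. Genes linking two
#' consecutive processes are flagged as connectors; genes linking three or
#' more consecutive processes are flagged as multi-connectors.
#'
#' @param path Character vector of process names, one per time point.
#' @param library A `geneset_library` containing the path processes.
#' @param matrix Gene x time-point log2 fold-change matrix aligned with the
#'   path positions.
#' @param fc_cutoff_log2 Cutoff on `|log2 FC|` (default 1, i.e. 2-fold).
#' @return List of class `gene_process_graph`: `graph` (bipartite igraph),
#'   `table` (timepoint, position, process, gene, fold_change),
#'   `connectors`, `multi_connectors`.
#' @export
gene_process_graph <- function(path, library, matrix, fc_cutoff_log2 = 1.0) {
  stopifnot(inherits(library, "geneset_library"))
  if (length(path) != ncol(matrix)) {
    stopf("path length (%d) must match the matrix time points (%d)",
          length(path), ncol(matrix))
  }
  missing <- setdiff(path, names(library$sets))
  if (length(missing)) stopf("path process(es) not in library: %s",
                             paste(missing, collapse = ", "))
  tps <- colnames(matrix) %||% paste0("t", seq_along(path))
  per_pos <- lapply(seq_along(path), function(j) {
    genes <- intersect(library$sets[[path[j]]], rownames(matrix))
    genes <- genes[abs(matrix[genes, j]) > fc_cutoff_log2]
    if (length(genes) == 0L) {
      warnf("process %s has no gene above the cutoff at %s", path[j], tps[j])
    }
    genes
  })
  tab <- do.call(rbind, lapply(seq_along(path), function(j) {
    if (length(per_pos[[j]]) == 0L) return(NULL)
    data.frame(timepoint = tps[j], position = j, process = path[j],
               gene = per_pos[[j]],
               fold_change = unname(matrix[per_pos[[j]], j]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(timepoint = character(0), position = integer(0),
                      process = character(0), gene = character(0),
                      fold_change = numeric(0))
  }
  # connector genes: run lengths of consecutive positions containing the gene
  runs <- function(g) {
    hit <- vapply(per_pos, function(p) g %in% p, TRUE)
    r <- rle(hit)
    max(c(0L, r$lengths[r$values]))
  }
  genes <- unique(tab$gene)
  span <- vapply(genes, runs, 0L)
  connectors <- genes[span >= 2L]
  multi <- genes[span >= 3L]
  proc_ids <- sprintf("%s@%d", path, seq_along(path))
  vdf <- rbind(
    data.frame(name = proc_ids, kind = "process", position = seq_along(path),
               label = path, connector = FALSE, stringsAsFactors = FALSE),
    if (length(genes)) data.frame(name = genes, kind = "gene", position = NA,
                                  label = genes, connector = genes %in% connectors,
                                  stringsAsFactors = FALSE)
  )
  edf <- if (nrow(tab)) {
    data.frame(from = sprintf("%s@%d", tab$process, tab$position),
               to = tab$gene, fold_change = tab$fold_change,
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), fold_change = numeric(0))
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  igraph::V(g)$type <- igraph::V(g)$kind == "gene"
  structure(
    list(graph = g, table = tab, connectors = connectors,
         multi_connectors = multi, fc_cutoff_log2 = fc_cutoff_log2),
    class = "gene_process_graph"
  )
}

#' @export
print.gene_process_graph <- function(x, ...) {
  cat(sprintf("gene-process graph: %d process positions, %d genes above cutoff %.3g\n",
              sum(igraph::V(x$graph)$kind == "process"),
              sum(igraph::V(x$graph)$kind == "gene"), x$fc_cutoff_log2))
  cat(sprintf("  %d connector gene(s), %d spanning >= 3 consecutive processes\n",
              length(x$connectors), length(x$multi_connectors)))
  invisible(x)
}

#' Export a gene-process graph
#'
#' Writes GraphML plus a per-gene TSV (`timepoint`, `position`, `process`,
#' `gene`, `fold_change`).
#'
#' @param x A `gene_process_graph`.
#' @param prefix Path prefix; writes `<prefix>.graphml` and `<prefix>.tsv`.
#' @return The two paths, invisibly.
#' @export
write_gene_process_graph <- function(x, prefix) {
  stopifnot(inherits(x, "gene_process_graph"))
  gml <- paste0(prefix, ".graphml")
  tsv <- paste0(prefix, ".tsv")
  g <- x$graph
  igraph::V(g)$position <- ifelse(is.na(igraph::V(g)$position), -1,
                                  igraph::V(g)$position)
  igraph::write_graph(g, gml, format = "graphml")
  utils::write.table(x$table, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gml, tsv))
}
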