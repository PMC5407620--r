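# edge keys: one string per (path, transition); same key <=> same unordered
# process pair at the same transition index
.edge_keys <- function(paths) {
  m <- paths$processes
  tt <- ncol(m) - 1L
  keys <- matrix("", nrow = nrow(m), ncol = tt)
  for (j in seq_len(tt)) {
    a <- m[, j]; b <- m[, j + 1L]
    keys[, j] <- paste(j, pmin(a, b), pmax(a, b), sep = "\r")
  }
  keys
}

# list of overlap-factor sets, one integer vector per path (self excluded)
.overlap_sets <- function(paths) {
  keys <- .edge_keys(paths)
  n <- nrow(keys)
  groups <- lapply(seq_len(ncol(keys)), function(j) {
    split(seq_len(n), keys[, j])
  })
  lapply(seq_len(n), function(i) {
    hits <- unlist(lapply(seq_len(ncol(keys)), function(j) {
      groups[[j]][[keys[i, j]]]
    }), use.names = FALSE)
    hits <- unique(hits)
    hits[hits != i]
  })
}

#' Overlap-factor set of a single edge
#'
#' The set of other paths whose edge at transition `j` connects the same
#' unordered process pair as path `i`'s edge at that same transition (an
#' identical pair used at a different transition does not match).
#'
#' @param paths A `path_set`.
#' @param i Path index.
#' @param j Transition index (1 to T-1).
#' @return Integer vector of path indices (excluding `i`).
#' @export
edge_overlap_factor <- function(paths, i, j) {
  stopifnot(inherits(paths, "path_set"))
  n <- nrow(paths$processes)
  tt <- ncol(paths$processes) - 1L
  if (!is_count(i) || i > n) stopf("path index out of range")
  if (!is_count(j) || j > tt) stopf("transition index out of range")
  keys <- .edge_keys(paths)
  hits <- which(keys[, j] == keys[i, j])
  hits[hits != i]
}

#' Overlap factor of a path
#'
#' Union, over the path's transitions, of the edge overlap-factor sets; the
#' numeric overlap factor is the cardinality of that union.
#'
#' @inheritParams edge_overlap_factor
#' @return List with `set` (integer indices) and `cardinality`.
#' @export
path_overlap_factor <- function(paths, i) {
  stopifnot(inherits(paths, "path_set"))
  n <- nrow(paths$processes)
  if (!is_count(i) || i > n) stopf("path index out of range")
  s <- .overlap_sets(paths)[[i]]
  list(set = sort(s), cardinality = length(s))
}

#' Overlap-factor summary of a path set
#'
#' Per-path overlap-factor cardinalities and their mean, plus the mean of
#' per-path mean nes values when available.
#'
#' @param paths A `path_set` (annotate with [annotate_mean_nes()] to get nes
#'   summaries).
#' @return List of class `overlap_report`: `overlap_factors` (per path),
#'   `mean_overlap_factor`, `mean_nes_values`, `mean_nes`, `sets` (list of
#'   index vectors).
#' @export
overlap_summary <- function(paths) {
  stopifnot(inherits(paths, "path_set"))
  sets <- .overlap_sets(paths)
  card <- lengths(sets)
  structure(
    list(overlap_factors = card,
         mean_overlap_factor = mean(card),
         mean_nes_values = paths$mean_nes,
         mean_nes = if (is.null(paths$mean_nes)) NA_real_ else mean(paths$mean_nes),
         sets = sets),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap report: %d paths, mean overlap factor %.4f",
              length(x$overlap_factors), x$mean_overlap_factor))
  if (!is.na(x$mean_nes)) cat(sprintf(", mean nes %.4f", x$mean_nes))
  cat("\n")
  invisible(x)
}

#' Resampled null distribution of mean overlap factor and mean nes
#'
#' Repeatedly draws `set_size` paths from a pool (without replacement within
#' a draw), computing the mean overlap factor and, when the pool carries
#' mean nes annotations, the mean nes of each draw.
#'
#' @param random_path_pool A `path_set` with at least `set_size` paths.
#' @param set_size Paths per draw (default 1024).
#' @param n_reps Number of draws (default 1000).
#' @param seed Optional integer seed.
#' @return Data frame with columns `rep`, `mean_overlap_factor`, `mean_nes`.
#' @export
resampled_null <- function(random_path_pool, set_size = 1024L, n_reps = 1000L,
                           seed = NULL) {
  stopifnot(inherits(random_path_pool, "path_set"))
  n <- nrow(random_path_pool$processes)
  if (n < set_size) stopf("pool of %d paths is smaller than set_size %d", n, set_size)
  if (!is_count(n_reps)) stopf("n_reps must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  res <- vapply(seq_len(n_reps), function(r) {
    sub <- subset_paths(random_path_pool, sample.int(n, set_size))
    card <- lengths(.overlap_sets(sub))
    c(mean(card),
      if (is.null(sub$mean_nes)) NA_real_ else mean(sub$mean_nes))
  }, c(0.0, 0.0))
  data.frame(rep = seq_len(n_reps),
             mean_overlap_factor = res[1L, ],
             mean_nes = res[2L, ])
}

#' Compare two path sets' overlap-factor and mean-nes distributions
#'
#' Mann-Whitney U tests on the per-path overlap-factor cardinalities and on
#' the per-path mean nes vectors of two path sets.
#'
#' @param set_a,set_b `path_set` objects with at least two paths each.
#' @return List of class `overlap_comparison` with both tests; `ties` notes
#'   degenerate all-tied inputs.
#' @export
compare_overlap_distributions <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "path_set"), inherits(set_b, "path_set"))
  if (nrow(set_a$processes) < 2L || nrow(set_b$processes) < 2L) {
    stopf("both path sets need at least two paths")
  }
  oa <- lengths(.overlap_sets(set_a))
  ob <- lengths(.overlap_sets(set_b))
  all_tied <- length(unique(c(oa, ob))) == 1L
  wo <- if (all_tied) NULL else suppressWarnings(stats::wilcox.test(oa, ob))
  wn <- NULL
  if (!is.null(set_a$mean_nes) && !is.null(set_b$mean_nes)) {
    wn <- suppressWarnings(stats::wilcox.test(set_a$mean_nes, set_b$mean_nes))
  }
  structure(
    list(overlap_u = if (is.null(wo)) NA_real_ else unname(wo$statistic),
         overlap_pvalue = if (is.null(wo)) 1 else wo$p.value,
         nes_u = if (is.null(wn)) NA_real_ else unname(wn$statistic),
         nes_pvalue = if (is.null(wn)) NA_real_ else wn$p.value,
         ties = all_tied),
    class = "overlap_comparison"
  )
}

#' @export
print.overlap_comparison <- function(x, ...) {
  cat(sprintf("overlap factors: U = %.1f, p = %.3g%s\n",
              x$overlap_u, x$overlap_pvalue,
              if (x$ties) " (all values tied)" else ""))
  if (!is.na(x$nes_pvalue)) {
    cat(sprintf("mean nes:        U = %.1f, p = %.3g\n", x$nes_u, x$nes_pvalue))
  }
  invisible(x)
}

#' Coverage-maximizing representative paths
#'
#' For `k = 1`, the path(s) with the largest overlap-factor cardinality. For
#' `k = 2`, the exhaustive pair search maximizing the number of paths in
#' `O(P_a) ∪ O(P_b) ∪ {a, b}` (the chosen paths count as covered; the union
#' of the overlap sets alone is also reported). All tied optima are
#' returned.
#'
#' @param paths A `path_set`.
#' @param k 1 or 2.
#' @param max_paths Guard on the exhaustive pair search (default 5000).
#' @return List with `indices` (matrix, one optimum per row), `covered`,
#'   `fraction`, and for `k = 2` also `covered_overlap_only`.
#' @export
best_covering <- function(paths, k = 1L, max_paths = 5000L) {
  stopifnot(inherits(paths, "path_set"))
  if (!k %in% c(1L, 2L)) stopf("k must be 1 or 2")
  n <- nrow(paths$processes)
  if (k > n) stopf("k exceeds the number of paths")
  sets <- .overlap_sets(paths)
  card <- lengths(sets)
  if (k == 1L) {
    best <- which(card == max(card))
    covered <- max(card) + 1L               # the chosen path covers itself
    return(list(indices = matrix(best, ncol = 1L),
                covered = covered, fraction = covered / n,
                covered_overlap_only = max(card)))
  }
  if (n > max_paths) {
    stopf("exhaustive pair search over %d paths exceeds max_paths = %d", n, max_paths)
  }
  # membership matrix of C_i = O(P_i) ∪ {i}; |C_a ∪ C_b| via cross products
  memb <- matrix(0, n, n)
  for (i in seq_len(n)) memb[i, c(sets[[i]], i)] <- 1
  sizes <- rowSums(memb)
  inter <- tcrossprod(memb)
  union_sz <- outer(sizes, sizes, `+`) - inter
  union_sz[lower.tri(union_sz, diag = TRUE)] <- -Inf
  best_val <- max(union_sz)
  idx <- which(union_sz == best_val, arr.ind = TRUE)
  overlap_only <- vapply(seq_len(nrow(idx)), function(r) {
    length(union(sets[[idx[r, 1L]]], sets[[idx[r, 2L]]]))
  }, 0L)
  list(indices = unname(idx), covered = best_val, fraction = best_val / n,
       covered_overlap_only = overlap_only)
}

#' Path-bundle plot data
#'
#' Time-versus-process plot data for a path set: per (time point, process)
#' node the number of paths through it, and per transition edge a thickness
#' equal to its overlap-factor cardinality (paths sharing the edge minus
#' one).
#'
#' @param paths A `path_set`.
#' @return List of two data frames: `nodes` (`timepoint`, `process`,
#'   `n_paths`) and `edges` (`transition`, `from`, `to`, `n_paths`,
#'   `thickness`).
#' @export
path_bundle_data <- function(paths) {
  stopifnot(inherits(paths, "path_set"))
  m <- paths$processes
  tt <- ncol(m)
  nodes <- do.call(rbind, lapply(seq_len(tt), function(j) {
    tab <- table(m[, j])
    data.frame(timepoint = j, process = names(tab),
               n_paths = as.integer(tab), stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(seq_len(tt - 1L), function(j) {
    a <- pmin(m[, j], m[, j + 1L]); b <- pmax(m[, j], m[, j + 1L])
    key <- paste(a, b, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    data.frame(transition = j,
               from = vapply(parts, `[`, "", 1L),
               to = vapply(parts, `[`, "", 2L),
               n_paths = as.integer(tab),
               thickness = as.integer(tab) - 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Plot a path bundle
#'
#' Draws the time-versus-process bundle with edge thickness proportional to
#' the edge overlap factor. Requires ggplot2.
#'
#' @param paths A `path_set`.
#' @return A ggplot object.
#' @export
plot_path_bundle <- function(paths) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is needed for plotting")
  }
  bd <- path_bundle_data(paths)
  procs <- sort(unique(c(bd$nodes$process)))
  ypos <- stats::setNames(seq_along(procs), procs)
  ed <- bd$edges
  ed$y0 <- ypos[ed$from]; ed$y1 <- ypos[ed$to]
  nd <- bd$nodes
  nd$y <- ypos[nd$process]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$transition, xend = .data$transition + 1,
                   y = .data$y0, yend = .data$y1,
                   linewidth = .data$thickness + 0.2),
      alpha = 0.5) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$timepoint, y = .data$y, size = .data$n_paths)) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 3)) +
    ggplot2::labs(x = "time point", y = "process",
                  linewidth = "edge overlap", size = "paths") +
    ggplot2::theme_minimal()
}
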