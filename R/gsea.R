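#' Rank genes by absolute fold change at one time point
#'
#' Genes are ordered by descending absolute log2 fold change; ties are broken
#' by ascending gene symbol. Weights carry the signed fold change.
#'
#' @param mat Gene x time-point log2 fold-change matrix (gene rownames).
#' @param timepoint Column label or index.
#' @return An object of class `ranked_genes`: list with `genes`, `weights`
#'   (signed), and `n`.
#' @export
rank_genes <- function(mat, timepoint) {
  if (is.character(timepoint)) {
    t <- match(timepoint, colnames(mat))
    if (is.na(t)) stopf("unknown time point: %s", timepoint)
  } else {
    t <- timepoint
    if (t < 1 || t > ncol(mat)) stopf("time-point index out of range: %s", t)
  }
  v <- mat[, t]
  ord <- order(-abs(v), rownames(mat))
  structure(
    list(genes = rownames(mat)[ord], weights = unname(v[ord]),
         n = nrow(mat), timepoint = colnames(mat)[t]),
    class = "ranked_genes"
  )
}

# hit positions of a gene set within a ranked list (sorted, unique);
# case-folded on both sides so library and matrix symbols join reliably
.hit_positions <- function(ranked, genes) {
  sort(which(toupper(ranked$genes) %in% toupper(genes)))
}

# running-sum extrema from sorted hit positions.
# The running sum is piecewise: it jumps up by |r|/NR at hits and falls by
# 1/(N-NH) at misses, so its local maxima sit exactly at hit positions and
# its local minima just before hits and at position N (where it is 0).
.es_from_positions <- function(pos, absw, n, method = "max_plus_min") {
  nh <- length(pos)
  cw <- cumsum(absw[pos])
  nr <- cw[nh]
  if (nr <= 0) stopf("all hit weights are zero; enrichment undefined")
  miss_before <- (pos - seq_len(nh)) / (n - nh)
  d_after <- cw / nr - miss_before
  d_before <- c(0, cw[-nh]) / nr - miss_before
  hi <- max(d_after)
  lo <- min(d_before, 0)
  if (method == "max_plus_min") {
    hi + lo
  } else {                      # classic single max-deviation statistic
    if (hi >= -lo) hi else lo
  }
}

#' Running enrichment sum for a gene set
#'
#' For a ranked list of N genes and a set S with `N_H` members in the list,
#' computes `P_hit(S, i) - P_miss(S, i)` for every position i, where
#' `P_hit` accumulates `|r_j| / N_R` over set members up to i (with
#' `N_R = sum of |r_j|` over members) and `P_miss` accumulates
#' `1 / (N - N_H)` over non-members. Both cumulative fractions reach 1, so
#' the final element is 0 up to rounding.
#'
#' @param ranked A [rank_genes()] result.
#' @param gene_set Character vector of gene symbols (or a single set from a
#'   `geneset_library`).
#' @return Numeric vector of length N.
#' @export
running_sum <- function(ranked, gene_set) {
  stopifnot(inherits(ranked, "ranked_genes"))
  hit <- toupper(ranked$genes) %in% toupper(gene_set)
  nh <- sum(hit)
  n <- ranked$n
  if (nh == 0L) stopf("gene set has no member in the ranked list")
  if (nh == n) stopf("gene set covers the whole ranked list; P_miss undefined")
  absw <- abs(ranked$weights)
  nr <- sum(absw[hit])
  if (nr <= 0) stopf("all hit weights are zero; enrichment undefined")
  cumsum(ifelse(hit, absw / nr, -1 / (n - nh)))
}

#' Enrichment score of a gene set
#'
#' The enrichment score is the maximum plus the minimum of the running sum
#' `P_hit - P_miss` over all list positions (not the classic single
#' max-deviation GSEA statistic; the classic statistic is available via
#' `method = "max_deviation"` for comparison).
#'
#' @inheritParams running_sum
#' @param method `"max_plus_min"` (default) or `"max_deviation"`.
#' @return Numeric enrichment score.
#' @export
enrichment_score <- function(ranked, gene_set,
                             method = c("max_plus_min", "max_deviation")) {
  method <- match.arg(method)
  stopifnot(inherits(ranked, "ranked_genes"))
  pos <- .hit_positions(ranked, gene_set)
  n <- ranked$n
  if (length(pos) == 0L) stopf("gene set has no member in the ranked list")
  if (length(pos) == n) stopf("gene set covers the whole ranked list; P_miss undefined")
  .es_from_positions(pos, abs(ranked$weights), n, method = method)
}

#' Permutation null distribution of the enrichment score
#'
#' Gene-label permutation: each draw scores a uniformly random size-`set_size`
#' subset of rank positions, which is equivalent to permuting the gene labels
#' of the ranked list.
#'
#' @inheritParams enrichment_score
#' @param set_size Number of hits per draw (0 < set_size < N).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000L, seed = NULL,
                             method = c("max_plus_min", "max_deviation")) {
  method <- match.arg(method)
  stopifnot(inherits(ranked, "ranked_genes"))
  n <- ranked$n
  if (!is_count(n_perm)) stopf("n_perm must be a positive integer")
  if (!is_count(set_size) || set_size >= n) stopf("need 0 < set_size < N")
  if (!is.null(seed)) set.seed(seed)
  absw <- abs(ranked$weights)
  vapply(seq_len(n_perm), function(i) {
    .es_from_positions(sort(sample.int(n, set_size)), absw, n, method = method)
  }, 0.0)
}

#' Normalized enrichment score and permutation p-value
#'
#' The normalized score divides the observed enrichment score by the mean of
#' the same-sign portion of the null distribution (keeping the observed
#' sign); the p-value is the fraction, over all permutations, of null scores
#' at least as extreme as the observed score in the same direction (ties
#' count). An es of 0 gets nes 0 by convention. If the same-sign portion of
#' the null is empty the nes is undefined (`NA`) and the p-value is reported
#' at the resolution floor `1/n_perm` with `degenerate = TRUE`.
#'
#' @param es Observed enrichment score.
#' @param null Numeric vector of null enrichment scores.
#' @return List with `nes`, `pvalue`, `degenerate`.
#' @export
normalize_and_pvalue <- function(es, null) {
  if (length(null) == 0L) stopf("empty null distribution")
  if (es == 0) {
    return(list(nes = 0, pvalue = 1, degenerate = FALSE))
  }
  portion <- if (es > 0) null[null > 0] else null[null < 0]
  pvalue <- if (es > 0) mean(null >= es) else mean(null <= es)
  if (length(portion) == 0L) {
    return(list(nes = NA_real_, pvalue = 1 / length(null), degenerate = TRUE))
  }
  list(nes = es / abs(mean(portion)), pvalue = pvalue, degenerate = FALSE)
}

#' Enrichment grid over all processes and time points
#'
#' Computes es, nes and p-value for every gene set at every time point of a
#' fold-change matrix. The library is first restricted to the matrix's gene
#' universe; sets that end up empty or spanning the whole list are recorded
#' as missing cells with a reason (never silent zeros). Null distributions
#' depend only on the ranked weights and the set size, so they are shared
#' across sets of equal size within a time point, with sub-seeds derived from
#' the master seed for reproducibility.
#'
#' @param mat Gene x time-point log2 fold-change matrix.
#' @param library A `geneset_library`.
#' @param n_perm Permutations per null distribution (default 1000).
#' @param seed Master seed (default 1).
#' @param method Enrichment statistic, see [enrichment_score()].
#' @return An object of class `nes_matrix`: list with numeric matrices `es`,
#'   `nes`, `pvalue` (process x time point), `size` (per-process hit count),
#'   `processes`, `timepoints`, `n_perm`, and a `failures` data frame.
#' @export
nes_matrix <- function(mat, library, n_perm = 1000L, seed = 1L,
                       method = c("max_plus_min", "max_deviation")) {
  method <- match.arg(method)
  stopifnot(inherits(library, "geneset_library"))
  lib <- suppressWarnings(restrict_to_universe(library, rownames(mat)))
  procs <- names(lib$sets)
  tps <- colnames(mat)
  dims <- list(procs, tps)
  es <- nes <- pv <- matrix(NA_real_, length(procs), length(tps), dimnames = dims)
  failures <- list()
  n <- nrow(mat)
  sizes <- vapply(lib$sets, function(g) sum(g %in% rownames(mat)), 1L)
  for (t in seq_along(tps)) {
    ranked <- rank_genes(mat, t)
    absw <- abs(ranked$weights)
    rank_of <- match(rownames(mat), ranked$genes)
    names(rank_of) <- rownames(mat)
    nulls <- new.env(parent = emptyenv())
    for (p in seq_along(procs)) {
      pos <- sort(rank_of[lib$sets[[p]]])
      nh <- length(pos)
      if (nh == 0L || nh == n) {
        failures[[length(failures) + 1L]] <- data.frame(
          process = procs[p], timepoint = tps[t],
          reason = if (nh == 0L) "no member in ranked list" else "set spans whole list")
        next
      }
      key <- as.character(nh)
      if (is.null(nulls[[key]])) {
        set.seed(derive_seed(seed, t, nh))
        nulls[[key]] <- vapply(seq_len(n_perm), function(i) {
          .es_from_positions(sort(sample.int(n, nh)), absw, n, method = method)
        }, 0.0)
      }
      e <- .es_from_positions(pos, absw, n, method = method)
      np <- normalize_and_pvalue(e, nulls[[key]])
      es[p, t] <- e
      nes[p, t] <- np$nes
      pv[p, t] <- np$pvalue
    }
    tn_log("nes_matrix: time point %s done (%d processes)", tps[t], length(procs))
  }
  structure(
    list(es = es, nes = nes, pvalue = pv, size = sizes,
         processes = procs, timepoints = tps, n_perm = n_perm,
         method = method,
         failures = if (length(failures)) do.call(rbind, failures)
                    else data.frame(process = character(0),
                                    timepoint = character(0),
                                    reason = character(0))),
    class = "nes_matrix"
  )
}

#' @export
print.nes_matrix <- function(x, ...) {
  cat(sprintf("nes_matrix: %d processes x %d time points (%d permutations, %s statistic)\n",
              length(x$processes), length(x$timepoints), x$n_perm, x$method))
  if (nrow(x$failures)) cat(sprintf("  %d missing cell(s), see $failures\n", nrow(x$failures)))
  invisible(x)
}

#' Long-format table of an enrichment grid
#' @param x A `nes_matrix`.
#' @return Data frame with columns process, timepoint, size, es, nes, pvalue.
#' @export
nes_long <- function(x) {
  stopifnot(inherits(x, "nes_matrix"))
  data.frame(
    process = rep(x$processes, times = length(x$timepoints)),
    timepoint = rep(x$timepoints, each = length(x$processes)),
    size = rep(unname(x$size), times = length(x$timepoints)),
    es = as.vector(x$es), nes = as.vector(x$nes), pvalue = as.vector(x$pvalue),
    stringsAsFactors = FALSE
  )
}

#' Write an enrichment grid to TSV
#'
#' Writes the long table (`*_long.tsv`) and the wide nes matrix
#' (`*_nes.tsv`).
#'
#' @param x A `nes_matrix`.
#' @param prefix Path prefix for the two files.
#' @return Character vector of the two paths, invisibly.
#' @export
write_nes_matrix <- function(x, prefix) {
  stopifnot(inherits(x, "nes_matrix"))
  long_path <- paste0(prefix, "_long.tsv")
  wide_path <- paste0(prefix, "_nes.tsv")
  utils::write.table(nes_long(x), long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  df <- data.frame(process = x$processes, x$nes, check.names = FALSE)
  utils::write.table(df, wide_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(long_path, wide_path))
}
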