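#' Construct a probe-level fold-change table
#'
#' Holds, for every probe and time point, three replicate log2 fold-change
#' values (treated vs control) and one p-value (t-test between the control
#' and treated triplicates, supplied upstream).
#'
#' @param probe_id Character vector of probe identifiers (unique).
#' @param gene_symbol Character vector of gene symbols, one per probe
#'   (uppercased; many probes may map to one gene).
#' @param timepoints Character vector of time-point labels (e.g. `"Day 1"`,
#'   `"Week 3"`).
#' @param values Numeric array `probes x timepoints x 3` of replicate log2
#'   fold changes.
#' @param pvalues Numeric matrix `probes x timepoints` of p-values in `[0,1]`
#'   (NA allowed).
#' @return An object of class `probe_table`.
#' @export
probe_table <- function(probe_id, gene_symbol, timepoints, values, pvalues) {
  probe_id <- as.character(probe_id)
  gene_symbol <- toupper(as.character(gene_symbol))
  timepoints <- as.character(timepoints)
  n <- length(probe_id)
  tn <- length(timepoints)
  if (anyDuplicated(probe_id)) stopf("duplicate probe_id values")
  if (length(gene_symbol) != n) stopf("gene_symbol must match probe_id length")
  if (!is.array(values) || !identical(dim(values), c(n, tn, 3L))) {
    stopf("values must be a %d x %d x 3 array", n, tn)
  }
  if (!is.matrix(pvalues) || !identical(dim(pvalues), c(n, tn))) {
    stopf("pvalues must be a %d x %d matrix", n, tn)
  }
  bad_p <- pvalues[!is.na(pvalues)]
  if (length(bad_p) && (min(bad_p) < 0 || max(bad_p) > 1)) {
    stopf("p-values must lie in [0,1]")
  }
  structure(
    list(probe_id = probe_id, gene_symbol = gene_symbol,
         timepoints = timepoints, values = values, pvalues = pvalues),
    class = "probe_table"
  )
}

#' @export
print.probe_table <- function(x, ...) {
  cat(sprintf("probe_table: %d probes, %d genes, %d time points\n",
              length(x$probe_id), length(unique(x$gene_symbol)),
              length(x$timepoints)))
  invisible(x)
}

#' Day-equivalents of time-point labels
#'
#' `"Day N"` maps to day N; `"Week W"` maps to `7 * W + 14` days, because the
#' week counter in the source experiment starts after the Day 14 sampling
#' (so Week 0 and Day 14 name the same calendar day).
#'
#' @param labels Character vector of labels.
#' @return Numeric vector of day numbers.
#' @export
timepoint_days <- function(labels) {
  m <- regmatches(labels, regexec("^(Day|Week)\\s*([0-9]+)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stopf("unparseable time-point label(s): %s",
                      paste(labels[bad], collapse = ", "))
  unit <- vapply(m, `[`, "", 2L)
  num <- as.numeric(vapply(m, `[`, "", 3L))
  ifelse(unit == "Day", num, 7 * num + 14)
}

# order of probes preferred on p-value ties: lexicographic probe_id
.probe_order <- function(pvals, ids) {
  order(ifelse(is.na(pvals), Inf, pvals), ids)
}

#' Primary fill: genes changed at least 2-fold in all three replicates
#'
#' For each gene and time point, if any probe has all three replicate log2
#' fold changes with `|value| > threshold_log2`, the cell receives that
#' probe's replicate mean; when several probes of a gene qualify the probe
#' with the minimum p-value is used (ties broken by probe id). All other
#' cells are left `NA`. Rows are the union of genes with at least one filled
#' cell.
#'
#' @param probes A [probe_table()].
#' @param threshold_log2 Perturbation threshold on the log2 scale (default 1,
#'   i.e. 2-fold).
#' @return Numeric matrix (filtered genes x time points) with `NA` in
#'   unfilled cells.
#' @export
step1_primary_fill <- function(probes, threshold_log2 = 1.0) {
  stopifnot(inherits(probes, "probe_table"))
  v <- probes$values
  qual <- abs(v[, , 1, drop = FALSE]) > threshold_log2 &
    abs(v[, , 2, drop = FALSE]) > threshold_log2 &
    abs(v[, , 3, drop = FALSE]) > threshold_log2
  qual <- array(qual, dim = dim(v)[1:2])
  means <- (v[, , 1] + v[, , 2] + v[, , 3]) / 3
  means <- matrix(means, nrow = dim(v)[1])
  genes <- sort(unique(probes$gene_symbol[rowSums(qual, na.rm = TRUE) > 0]))
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(probes$timepoints),
                dimnames = list(genes, probes$timepoints))
  if (length(genes) == 0L) {
    warnf("no gene qualifies in the primary fill (all |FC| <= %g somewhere)",
          threshold_log2)
    return(out)
  }
  for (t in seq_along(probes$timepoints)) {
    idx <- which(qual[, t] %in% TRUE)
    if (length(idx) == 0L) next
    ord <- idx[.probe_order(probes$pvalues[idx, t], probes$probe_id[idx])]
    first <- ord[!duplicated(probes$gene_symbol[ord])]
    out[cbind(match(probes$gene_symbol[first], genes), t)] <- means[first, t]
  }
  out
}

# step 2-3 candidate selection and averaging for one gene/time point;
# returns list(value, rule)
.secondary_value <- function(reps_mat, pvals, ids, band = 0.8, dummy = 0.001,
                             threshold_log2 = 1.0) {
  outside <- abs(reps_mat) > threshold_log2
  n_out <- rowSums(outside)
  cand <- which(n_out >= 2L)
  if (length(cand) == 0L) {
    cand <- which(rowSums(abs(reps_mat) <= threshold_log2) == 3L)
  }
  if (length(cand) == 0L) {
    return(list(value = dummy, rule = "no-candidate-dummy"))
  }
  pos <- rowSums(reps_mat[cand, , drop = FALSE] > 0)
  neg <- rowSums(reps_mat[cand, , drop = FALSE] < 0)
  same3 <- cand[pos == 3L | neg == 3L]
  if (length(same3)) {
    pick <- same3[.probe_order(pvals[same3], ids[same3])][1L]
    a <- mean(reps_mat[pick, ])
  } else {
    same2 <- cand[pos == 2L | neg == 2L]
    if (length(same2) == 0L) {
      return(list(value = dummy, rule = "no-sign-agreement-dummy"))
    }
    pick <- same2[.probe_order(pvals[same2], ids[same2])][1L]
    r <- reps_mat[pick, ]
    pair <- if (sum(r > 0) == 2L) r[r > 0] else r[r < 0]
    a <- mean(pair)
  }
  if (a > -band && a < band) {
    list(value = dummy, rule = "band-dummy")
  } else {
    list(value = a, rule = "secondary-average")
  }
}

#' Secondary fill for a single empty cell
#'
#' Applies the fallback rules for a (gene, time point) cell left empty by the
#' primary fill. Candidate probes are those with at least two of three
#' replicates outside `[-threshold, threshold]`; if none exist, probes with
#' all three replicates inside the interval. Among candidates, probes whose
#' three replicates share a strict sign are preferred (three-replicate mean);
#' otherwise probes with exactly two same-sign replicates are used (mean of
#' the same-sign pair). Ties are broken by minimum p-value, then probe id.
#' If the chosen average lies strictly inside `(-band, band)` the dummy value
#' is inserted instead; if no probe matches any rule the dummy is inserted
#' and the case logged.
#'
#' @inheritParams step1_primary_fill
#' @param gene Gene symbol.
#' @param timepoint Time-point label.
#' @param band Averages strictly inside `(-band, band)` become the dummy
#'   (default 0.8).
#' @param dummy Placeholder value for present-but-unperturbed entries
#'   (default 0.001).
#' @return The value to insert (numeric scalar).
#' @export
step23_secondary_fill <- function(probes, gene, timepoint, band = 0.8,
                                  dummy = 0.001, threshold_log2 = 1.0) {
  stopifnot(inherits(probes, "probe_table"))
  gene <- toupper(gene)
  t <- match(timepoint, probes$timepoints)
  if (is.na(t)) stopf("unknown time point: %s", timepoint)
  rows <- which(probes$gene_symbol == gene)
  if (length(rows) == 0L) stopf("gene %s has no probes", gene)
  res <- .secondary_value(
    matrix(probes$values[rows, t, ], nrow = length(rows)),
    probes$pvalues[rows, t], probes$probe_id[rows],
    band = band, dummy = dummy, threshold_log2 = threshold_log2
  )
  if (grepl("dummy", res$rule) && res$rule != "band-dummy") {
    tn_log("secondary fill: %s @ %s -> dummy (%s)", gene, timepoint, res$rule)
  }
  res$value
}

#' Fill all remaining empty cells of a primary-fill matrix
#'
#' Runs [step23_secondary_fill()] on every `NA` cell; primary-fill cells are
#' never overwritten.
#'
#' @param probes A [probe_table()].
#' @param mat Matrix from [step1_primary_fill()].
#' @inheritParams step23_secondary_fill
#' @return Fully filled numeric matrix.
#' @export
fill_missing_cells <- function(probes, mat, band = 0.8, dummy = 0.001,
                               threshold_log2 = 1.0) {
  stopifnot(inherits(probes, "probe_table"))
  gene_rows <- split(seq_along(probes$gene_symbol), probes$gene_symbol)
  for (g in rownames(mat)) {
    rows <- gene_rows[[g]]
    empties <- which(is.na(mat[g, ]))
    for (t in empties) {
      res <- .secondary_value(
        matrix(probes$values[rows, t, ], nrow = length(rows)),
        probes$pvalues[rows, t], probes$probe_id[rows],
        band = band, dummy = dummy, threshold_log2 = threshold_log2
      )
      mat[g, t] <- res$value
    }
  }
  mat
}

#' Merge two time-point columns measuring the same day
#'
#' Per gene: both columns perturbed (`|v| > perturb_threshold`) in the same
#' direction -> mean; perturbed in opposite directions -> dummy; exactly one
#' perturbed -> that value; neither perturbed -> the `label_a` value (a fixed,
#' reproducible choice). The merged column keeps `label_a`'s name.
#'
#' @param mat Fully filled gene x time-point matrix.
#' @param label_a,label_b Column labels to merge (defaults `"Day 14"`,
#'   `"Week 0"`).
#' @param perturb_threshold Perturbation threshold (default 1 on log2 scale).
#' @param dummy Dummy value for sign conflicts (default 0.001).
#' @return Matrix with one fewer column.
#' @export
merge_timepoints <- function(mat, label_a = "Day 14", label_b = "Week 0",
                             perturb_threshold = 1.0, dummy = 0.001) {
  ia <- match(label_a, colnames(mat))
  ib <- match(label_b, colnames(mat))
  if (is.na(ia) || is.na(ib)) stopf("both %s and %s must be columns", label_a, label_b)
  a <- mat[, ia]
  b <- mat[, ib]
  pa <- abs(a) > perturb_threshold
  pb <- abs(b) > perturb_threshold
  merged <- a                                        # neither perturbed: keep a
  merged[pa & pb & sign(a) == sign(b)] <- ((a + b) / 2)[pa & pb & sign(a) == sign(b)]
  merged[pa & pb & sign(a) != sign(b)] <- dummy
  merged[pa & !pb] <- a[pa & !pb]
  merged[!pa & pb] <- b[!pa & pb]
  mat[, ia] <- merged
  mat[, -ib, drop = FALSE]
}

#' Drop genes never perturbed at any time point
#'
#' Removes genes whose absolute value never exceeds `threshold` in any
#' column of the final matrix.
#'
#' @param mat Fully filled gene x time-point matrix.
#' @param threshold Perturbation threshold (default 1 on log2 scale).
#' @return The filtered matrix.
#' @export
drop_never_perturbed <- function(mat, threshold = 1.0) {
  if (anyNA(mat)) stopf("matrix must be fully filled before the drop step")
  keep <- apply(abs(mat), 1L, max) > threshold
  if (!any(keep)) stopf("every gene was dropped; no perturbation above %g anywhere", threshold)
  mat[keep, , drop = FALSE]
}

#' Full probe-level preprocessing pipeline
#'
#' Primary fill, secondary fill of the remaining cells, optional merging of
#' two columns measuring the same day, and removal of never-perturbed genes.
#' Columns are ordered by their day-equivalents when the labels parse as
#' `Day N` / `Week W`.
#'
#' @inheritParams fill_missing_cells
#' @param merge `NULL`, or a length-2 character vector of column labels to
#'   merge (default merges `"Day 14"` and `"Week 0"` when both are present).
#' @return Final gene x time-point log2 fold-change matrix.
#' @export
preprocess_probe_table <- function(probes, threshold_log2 = 1.0, band = 0.8,
                                   dummy = 0.001, merge = NULL) {
  mat <- step1_primary_fill(probes, threshold_log2 = threshold_log2)
  if (nrow(mat) == 0L) stopf("no gene passed the primary fill")
  mat <- fill_missing_cells(probes, mat, band = band, dummy = dummy,
                            threshold_log2 = threshold_log2)
  if (is.null(merge) &&
      all(c("Day 14", "Week 0") %in% colnames(mat))) {
    merge <- c("Day 14", "Week 0")
  }
  if (!is.null(merge)) {
    mat <- merge_timepoints(mat, merge[1L], merge[2L],
                            perturb_threshold = threshold_log2, dummy = dummy)
  }
  days <- tryCatch(timepoint_days(colnames(mat)), error = function(e) NULL)
  if (!is.null(days)) mat <- mat[, order(days), drop = FALSE]
  drop_never_perturbed(mat, threshold = threshold_log2)
}

#' Read a probe table from TSV plus a column-mapping config
#'
#' The TSV needs columns `probe_id` and `gene_symbol`; the mapping names, for
#' every time point, its three replicate columns and its p-value column:
#' `list("Day 1" = list(replicates = c(...), pvalue = "..."), ...)`. The
#' mapping may also be a path to a JSON or YAML file with that structure.
#'
#' @param path TSV file path.
#' @param mapping Named list or path to a JSON/YAML file.
#' @return A [probe_table()].
#' @export
read_probe_table <- function(path, mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- if (grepl("\\.ya?ml$", mapping)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stopf("the yaml package is needed to read YAML mappings")
      }
      yaml::read_yaml(mapping)
    } else {
      jsonlite::read_json(mapping, simplifyVector = TRUE)
    }
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol")
  if (!all(need %in% names(df))) stopf("TSV must contain columns probe_id and gene_symbol")
  tps <- names(mapping)
  n <- nrow(df)
  values <- array(NA_real_, dim = c(n, length(tps), 3L))
  pvalues <- matrix(NA_real_, nrow = n, ncol = length(tps))
  for (t in seq_along(tps)) {
    m <- mapping[[t]]
    reps <- unlist(m$replicates)
    if (length(reps) != 3L) stopf("time point %s must map exactly 3 replicate columns", tps[t])
    miss <- setdiff(c(reps, m$pvalue), names(df))
    if (length(miss)) stopf("missing column(s) in TSV: %s", paste(miss, collapse = ", "))
    for (k in 1:3) values[, t, k] <- as.numeric(df[[reps[k]]])
    pvalues[, t] <- as.numeric(df[[m$pvalue]])
  }
  probe_table(df$probe_id, df$gene_symbol, tps, values, pvalues)
}

#' Write / read a gene x time-point fold-change matrix as TSV
#'
#' Genes as rows (first column `gene`), time-point labels as headers.
#'
#' @param mat Numeric matrix with gene rownames.
#' @param path File path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_fc_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- toupper(df[[1L]])
  m
}
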