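#' Construct a temporal path set
#'
#' A temporal path visits one process per time point, with consecutive
#' processes adjacent in the process network. A path set is a collection of
#' equal-length paths with a provenance tag.
#'
#' @param processes Character matrix, one path per row, one time point per
#'   column.
#' @param provenance One of `"systematic-max"`, `"systematic-min"`,
#'   `"random"`.
#' @param mean_nes Optional numeric vector of per-path mean nes values.
#' @return An object of class `path_set`.
#' @export
path_set <- function(processes, provenance = "random", mean_nes = NULL) {
  if (!is.matrix(processes) || !is.character(processes)) {
    stopf("processes must be a character matrix (paths x time points)")
  }
  if (!is.null(mean_nes) && length(mean_nes) != nrow(processes)) {
    stopf("mean_nes must have one value per path")
  }
  structure(
    list(processes = processes, provenance = provenance, mean_nes = mean_nes),
    class = "path_set"
  )
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("path_set (%s): %d paths of length %d (%d distinct)\n",
              x$provenance, nrow(x$processes), ncol(x$processes),
              nrow(unique(x$processes))))
  if (!is.null(x$mean_nes)) {
    cat(sprintf("  mean nes: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$mean_nes), min(x$mean_nes), max(x$mean_nes)))
  }
  invisible(x)
}

#' @export
length.path_set <- function(x) nrow(x$processes)

#' Subset a path set by path indices
#' @param paths A `path_set`.
#' @param idx Integer vector of path indices.
#' @return A `path_set` containing the selected paths.
#' @export
subset_paths <- function(paths, idx) {
  stopifnot(inherits(paths, "path_set"))
  path_set(paths$processes[idx, , drop = FALSE], paths$provenance,
           if (is.null(paths$mean_nes)) NULL else paths$mean_nes[idx])
}

#' Mean nes of a single temporal path
#'
#' Arithmetic mean of `nes(p_j, time point j)` over the path positions.
#'
#' @param path Character vector of process names, one per time point.
#' @param nes A `nes_matrix`.
#' @return Numeric mean nes.
#' @export
path_mean_nes <- function(path, nes) {
  stopifnot(inherits(nes, "nes_matrix"))
  if (length(path) > length(nes$timepoints)) {
    stopf("path longer than the nes grid (%d > %d)",
          length(path), length(nes$timepoints))
  }
  rows <- match(path, nes$processes)
  if (anyNA(rows)) {
    stopf("process absent from the nes grid: %s",
          paste(path[is.na(rows)], collapse = ", "))
  }
  vals <- nes$nes[cbind(rows, seq_along(path))]
  if (anyNA(vals)) {
    j <- which(is.na(vals))[1L]
    stopf("missing nes for process %s at time point %s", path[j], nes$timepoints[j])
  }
  mean(vals)
}

#' Per-path mean nes for a whole path set
#'
#' @param paths A `path_set`.
#' @param nes A `nes_matrix`.
#' @return Numeric vector, one mean nes per path.
#' @export
pathset_mean_nes <- function(paths, nes) {
  stopifnot(inherits(paths, "path_set"), inherits(nes, "nes_matrix"))
  apply(paths$processes, 1L, path_mean_nes, nes = nes)
}

#' Annotate a path set with mean nes values
#' @inheritParams pathset_mean_nes
#' @return The `path_set` with `mean_nes` filled in.
#' @export
annotate_mean_nes <- function(paths, nes) {
  paths$mean_nes <- pathset_mean_nes(paths, nes)
  paths
}

#' Systematic greedy branching path enumeration
#'
#' Depth-first enumeration of temporal paths: at time point 1 the candidate
#' pool is all network nodes; at time point j > 1 it is the network
#' neighbors of the process chosen at j - 1. At every selection instance the
#' top `branch` candidates by nes at that time point (bottom `branch` for
#' `direction = "min"`) each spawn a branch, yielding `branch^T` paths when
#' every pool has at least `branch` candidates. Equal-nes ties are broken by
#' ascending process name; pools smaller than `branch` branch over whatever
#' exists (logged); a branch reaching an isolated node is aborted and
#' counted. A process may recur at a later time point, but never immediately
#' (the network has no self-edges). Converging duplicate paths are retained.
#'
#' @param nes A `nes_matrix`.
#' @param network Process network whose nodes all appear in `nes`.
#' @param branch Candidates per selection instance (default 2).
#' @param direction `"max"` for perturbed paths, `"min"` for the
#'   lowest-nes control set.
#' @return A `path_set` with provenance `"systematic-max"` or
#'   `"systematic-min"`, annotated with mean nes; attribute `"aborted"`
#'   counts aborted branches.
#' @export
systematic_paths <- function(nes, network, branch = 2L,
                             direction = c("max", "min")) {
  direction <- match.arg(direction)
  stopifnot(inherits(nes, "nes_matrix"))
  if (!is_count(branch)) stopf("branch must be a positive integer")
  nodes <- igraph::V(network)$name
  missing <- setdiff(nodes, nes$processes)
  if (length(missing)) {
    stopf("network node(s) absent from the nes grid: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  tmax <- length(nes$timepoints)
  if (tmax < 2L) stopf("need at least two time points")
  adj <- lapply(igraph::adjacent_vertices(network, igraph::V(network)), names)
  names(adj) <- nodes
  grid <- nes$nes[nodes, , drop = FALSE]
  pick <- function(pool, t) {
    vals <- grid[pool, t]
    ok <- !is.na(vals)
    pool <- pool[ok]; vals <- vals[ok]
    if (length(pool) == 0L) return(character(0))
    ord <- if (direction == "max") order(-vals, pool) else order(vals, pool)
    pool[ord][seq_len(min(branch, length(pool)))]
  }
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 0L)
  acc$aborted <- 0L
  deficits <- 0L
  rec <- function(prefix, t) {
    if (t > tmax) {
      acc$paths[[length(acc$paths) + 1L]] <- prefix
      return(invisible(NULL))
    }
    pool <- if (t == 1L) nodes else adj[[prefix[t - 1L]]]
    top <- pick(pool, t)
    if (length(top) == 0L) {
      acc$aborted <- acc$aborted + 1L
      tn_log("systematic_paths: branch aborted at time point %d (isolated pool)", t)
      return(invisible(NULL))
    }
    if (length(top) < branch) deficits <<- deficits + 1L
    for (cand in top) rec(c(prefix, cand), t + 1L)
    invisible(NULL)
  }
  rec(character(0), 1L)
  if (deficits > 0L) {
    tn_log("systematic_paths: %d selection instance(s) had fewer than %d candidates",
           deficits, branch)
  }
  if (length(acc$paths) == 0L) stopf("every branch aborted; no path found")
  mat <- do.call(rbind, acc$paths)
  out <- path_set(mat, provenance = paste0("systematic-", direction))
  out <- annotate_mean_nes(out, nes)
  attr(out, "aborted") <- acc$aborted
  out
}

#' Random-walk baseline paths
#'
#' Each path starts at a uniformly random non-isolated node and takes
#' uniform random steps to network neighbors. Node revisits are allowed,
#' matching the systematic procedure.
#'
#' @param network Process network.
#' @param length Path length in time points (default 10).
#' @param count Number of paths.
#' @param seed Optional integer seed.
#' @return A `path_set` with provenance `"random"` (no mean nes; annotate
#'   with [annotate_mean_nes()]).
#' @export
random_paths <- function(network, length = 10L, count, seed = NULL) {
  if (!is_count(length, 2L)) stopf("length must be an integer >= 2")
  if (!is_count(count)) stopf("count must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(network)$name
  adj <- lapply(igraph::adjacent_vertices(network, igraph::V(network)), names)
  names(adj) <- nodes
  non_iso <- nodes[lengths(adj) > 0L]
  if (base::length(non_iso) == 0L) stopf("network has no non-isolated node")
  mat <- matrix(NA_character_, nrow = count, ncol = length)
  mat[, 1L] <- non_iso[sample.int(base::length(non_iso), count, replace = TRUE)]
  for (j in 2L:length) {
    prev <- mat[, j - 1L]
    mat[, j] <- vapply(prev, function(v) {
      nb <- adj[[v]]
      nb[sample.int(base::length(nb), 1L)]
    }, "", USE.NAMES = FALSE)
  }
  path_set(mat, provenance = "random")
}

#' Serialize a path set as JSON lines and TSV
#'
#' One JSON record per path (`processes`, `mean_nes`, `provenance`), plus a
#' flat TSV with one row per path.
#'
#' @param paths A `path_set`.
#' @param prefix Path prefix; writes `<prefix>.jsonl` and `<prefix>.tsv`.
#' @return The two paths, invisibly.
#' @export
write_pathset <- function(paths, prefix) {
  stopifnot(inherits(paths, "path_set"))
  jl <- paste0(prefix, ".jsonl")
  tsv <- paste0(prefix, ".tsv")
  recs <- lapply(seq_len(nrow(paths$processes)), function(i) {
    jsonlite::toJSON(list(
      index = i,
      processes = paths$processes[i, ],
      mean_nes = paths$mean_nes[i],
      provenance = paths$provenance
    ), auto_unbox = TRUE, digits = NA)
  })
  writeLines(unlist(recs), jl)
  df <- data.frame(index = seq_len(nrow(paths$processes)),
                   paths$processes,
                   mean_nes = paths$mean_nes %||% NA_real_,
                   provenance = paths$provenance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[2:(1 + ncol(paths$processes))] <-
    paste0("t", seq_len(ncol(paths$processes)))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jl, tsv))
}
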