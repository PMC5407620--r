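#' Construct a gene-set library
#'
#' A gene-set library is an ordered, named collection of gene sets (biological
#' processes), each a set of uppercase gene symbols, together with the universe
#' of all genes appearing in any member set.
#'
#' @param sets Named list of character vectors of gene symbols. Symbols are
#'   case-folded to uppercase and deduplicated within each set; empty strings
#'   are dropped.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled metadata, ignored by all computation).
#' @return An object of class `geneset_library` with elements `sets`
#'   (named list), `descriptions` and `universe`.
#' @export
geneset_library <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || length(sets) == 0L) {
    stopf("a gene-set library needs a non-empty list of sets")
  }
  nm <- names(sets)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stopf("every gene set must be named")
  }
  if (anyDuplicated(nm)) {
    stopf("duplicate gene-set name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) {
    g <- toupper(as.character(g))
    g <- unique(g[!is.na(g) & g != ""])
    g
  })
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) {
    stopf("gene set(s) with no genes: %s", paste(nm[empty], collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- as.character(descriptions)
  if (length(descriptions) != length(sets)) {
    stopf("descriptions must match the number of sets")
  }
  names(descriptions) <- nm
  structure(
    list(sets = sets, descriptions = descriptions,
         universe = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "geneset_library"
  )
}

#' @export
print.geneset_library <- function(x, ...) {
  sz <- set_sizes(x)
  cat(sprintf("geneset_library: %d sets, %d genes (set sizes %d-%d, median %g)\n",
              length(x$sets), length(x$universe),
              min(sz), max(sz), stats::median(sz)))
  invisible(x)
}

#' @export
length.geneset_library <- function(x) length(x$sets)

#' Sizes of the member gene sets
#' @param library A `geneset_library`.
#' @return Named integer vector of set sizes.
#' @export
set_sizes <- function(library) {
  vapply(library$sets, length, 1L)
}

#' Read a gene-set library from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one gene symbol per field. Gene symbols are
#' uppercased, empty tokens dropped and duplicates within a line removed.
#'
#' @param path Path to a GMT file.
#' @return A [geneset_library()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) {
    stopf("malformed GMT line(s) with fewer than 3 fields: line %s",
          paste(which(nf < 3L), collapse = ", "))
  }
  nms <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nms)) {
    stopf("duplicate gene-set name(s) in GMT: %s",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  geneset_library(sets, descriptions = vapply(fields, `[`, "", 2L))
}

#' Write a gene-set library as GMT
#'
#' @param library A `geneset_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "geneset_library"))
  lines <- vapply(seq_along(library$sets), function(i) {
    paste(c(names(library$sets)[i], library$descriptions[i],
            library$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Keep only subset-minimal gene sets
#'
#' Retains a set P if and only if no other set Q is a *proper* subset of P.
#' Sets with identical gene content are therefore all retained (neither is a
#' proper subset of the other); when exact duplicates are present a note is
#' logged. The operation is idempotent.
#'
#' @param library A `geneset_library`.
#' @return Filtered `geneset_library`, with attribute `"report"`: a data frame
#'   with columns `name`, `size`, `retained`, `reason`.
#' @export
filter_subset_minimal <- function(library) {
  stopifnot(inherits(library, "geneset_library"))
  n <- length(library$sets)
  sz <- set_sizes(library)
  # sparse incidence (genes x sets); Q is a proper subset of P iff
  # |Q ∩ P| == |Q| and |Q| < |P|
  gene_idx <- lapply(library$sets, match, table = library$universe)
  inc <- Matrix::sparseMatrix(
    i = unlist(gene_idx, use.names = FALSE),
    j = rep.int(seq_len(n), lengths(gene_idx)),
    x = 1,
    dims = c(length(library$universe), n)
  )
  inter <- as.matrix(Matrix::crossprod(inc))   # n x n intersection sizes
  contains_proper <- vapply(seq_len(n), function(p) {
    q <- inter[, p] == sz & sz < sz[p]
    any(q)
  }, TRUE)
  dup_content <- vapply(seq_len(n), function(p) {
    any(inter[, p] == sz & sz == sz[p] & seq_len(n) != p)
  }, TRUE)
  if (any(dup_content)) {
    tn_log("subset-minimal filter: %d set(s) have exact-duplicate gene content; all retained",
           sum(dup_content))
  }
  keep <- !contains_proper
  report <- data.frame(
    name = names(library$sets),
    size = unname(sz),
    retained = keep,
    reason = ifelse(keep, "", "contains another set as proper subset"),
    stringsAsFactors = FALSE
  )
  out <- geneset_library(library$sets[keep], library$descriptions[keep])
  attr(out, "report") <- report
  out
}

#' Drop small gene sets
#'
#' Retains sets strictly larger than `min_exclusive` genes (default 15, i.e.
#' at least 16 genes survive). The universe is recomputed.
#'
#' @param library A `geneset_library`.
#' @param min_exclusive Exclusive lower size bound (>= 0).
#' @return Filtered `geneset_library` with a `"report"` attribute.
#' @export
filter_min_size <- function(library, min_exclusive = 15L) {
  stopifnot(inherits(library, "geneset_library"))
  if (!is_count(min_exclusive, min = 0L)) stopf("min_exclusive must be a non-negative integer")
  sz <- set_sizes(library)
  keep <- sz > min_exclusive
  report <- data.frame(
    name = names(library$sets),
    size = unname(sz),
    retained = keep,
    reason = ifelse(keep, "", sprintf("size <= %d", min_exclusive)),
    stringsAsFactors = FALSE
  )
  if (!any(keep)) {
    warnf("size filter removed every gene set (threshold > %d)", min_exclusive)
    out <- structure(list(sets = list(), descriptions = character(0),
                          universe = character(0)),
                     class = "geneset_library")
    attr(out, "report") <- report
    return(out)
  }
  out <- geneset_library(library$sets[keep], library$descriptions[keep])
  attr(out, "report") <- report
  out
}

#' Restrict a library to a gene universe
#'
#' Intersects every set with `genes` (e.g. the genes actually measured in an
#' expression matrix); sets left empty are dropped with a warning.
#'
#' @param library A `geneset_library`.
#' @param genes Character vector of gene symbols (case-folded to uppercase).
#' @return Restricted `geneset_library`.
#' @export
restrict_to_universe <- function(library, genes) {
  stopifnot(inherits(library, "geneset_library"))
  genes <- toupper(as.character(genes))
  sets <- lapply(library$sets, intersect, y = genes)
  keep <- lengths(sets) > 0L
  if (!all(keep)) {
    warnf("restrict_to_universe dropped %d empty set(s)", sum(!keep))
  }
  if (!any(keep)) stopf("no gene set overlaps the given universe")
  geneset_library(sets[keep], library$descriptions[keep])
}

#' Apply the working-list filters in order
#'
#' Composition used to derive the working process list from a raw library:
#' subset-minimal filter first, then the size filter.
#'
#' @inheritParams filter_min_size
#' @return Filtered `geneset_library`; attribute `"report"` combines both
#'   filter reports.
#' @export
prepare_library <- function(library, min_exclusive = 15L) {
  a <- filter_subset_minimal(library)
  ra <- attr(a, "report")
  b <- filter_min_size(a, min_exclusive = min_exclusive)
  rb <- attr(b, "report")
  dropped_a <- ra[!ra$retained, , drop = FALSE]
  report <- rbind(rb, dropped_a)
  attr(b, "report") <- report[order(report$name), , drop = FALSE]
  b
}

#' Write a filter report as TSV
#' @param library A filtered library carrying a `"report"` attribute.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_report <- function(library, path) {
  report <- attr(library, "report")
  if (is.null(report)) stopf("library carries no filter report")
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
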