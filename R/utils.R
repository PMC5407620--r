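`%||%` <- function(x, y) if (is.null(x)) y else x

# internal logger; silent unless options(temponet.verbose = TRUE)
tn_log <- function(...) {
  if (isTRUE(getOption("temponet.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

# derived sub-seed kept inside 32-bit integer range
derive_seed <- function(master, a, b = 0L) {
  as.integer((as.double(master) * 7919 + as.double(a) * 104729 + as.double(b)) %% 2147483647)
}
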