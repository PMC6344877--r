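#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a base seed and a stream label.
#'
#' Gives every (gene, model, restart) combination its own reproducible RNG
#' stream while staying inside 32-bit integer range.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  # polynomial string hash mod a 31-bit prime
  codes <- utf8ToInt(labels)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483629
  as.integer(h + 1L)
}

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (x < lo || x > hi)
    stopf("'%s' must be in [%s, %s]", name, format(lo), format(hi))
  invisible(x)
}

#' Write a data frame as TSV (no quoting, no row names).
#' @keywords internal
#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             ...)
}
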