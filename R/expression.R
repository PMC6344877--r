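#' Expression matrix container
#'
#' A genes x timepoints matrix of linear-scale expression intensities on a
#' strictly increasing time grid (hours). This mirrors unreplicated
#' microarray time courses: one value per gene per time point.
#'
#' @param values numeric matrix, one row per gene.
#' @param gene_ids character vector of unique gene identifiers.
#' @param times numeric vector of sampling times in hours, strictly
#'   increasing, one per column.
#' @return An `expression_matrix` object (list with `values`, `gene_ids`,
#'   `times`).
#' @export
expression_matrix <- function(values, gene_ids, times) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stopf("expression values must be finite numerics")
  if (length(gene_ids) != nrow(values))
    stopf("gene_ids length (%d) != row count (%d)", length(gene_ids),
          nrow(values))
  if (anyDuplicated(gene_ids))
    stopf("duplicated gene ids: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(times) != ncol(values))
    stopf("times length (%d) != column count (%d)", length(times),
          ncol(values))
  if (any(diff(times) <= 0))
    stopf("time points must be strictly increasing")
  dimnames(values) <- list(gene_ids, as.character(times))
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 times = as.numeric(times)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d timepoints (%g-%g h)\n",
              nrow(x$values), ncol(x$values), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression time-series table
#'
#' Expects a TSV whose first column holds gene ids and whose remaining
#' column names are sampling times in hours. Microarray series published on
#' a log scale are brought back to intensity scale by supplying `log_base`
#' (every value v becomes log_base^v).
#'
#' @param path TSV file path.
#' @param log_base base used to de-log the values, or `NULL` to leave them
#'   unchanged. Use 2 for log2-published data.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, log_base = NULL) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stopf("expected gene-id column plus >=1 time column")
  gene_ids <- as.character(df[[1L]])
  times <- suppressWarnings(as.numeric(colnames(df)[-1L]))
  if (anyNA(times)) stopf("non-numeric time column headers")
  if (any(diff(times) <= 0)) stopf("time columns not strictly increasing")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) stopf("non-numeric expression cells")
  if (!is.null(log_base)) {
    assert_scalar_num(log_base, "log_base", lo = 1 + 1e-12)
    vals <- log_base^vals
  }
  expression_matrix(vals, gene_ids, times)
}

#' Write an expression matrix as TSV
#' @param m an [expression_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE)
  colnames(df) <- c("gene_id", as.character(m$times))
  write_tsv(df, path)
}

#' Equalize time-point means
#'
#' Rescales every time-point column so all column means equal the grand mean
#' of the input. This removes array-to-array intensity drift in unreplicated
#' time courses while preserving within-array profile shape. Idempotent.
#'
#' @param m an [expression_matrix()] with strictly positive values.
#' @return Normalized [expression_matrix()].
#' @export
normalize_timepoints <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (any(m$values <= 0))
    stopf("normalization requires strictly positive values")
  col_means <- colMeans(m$values)
  if (any(col_means <= 0)) stopf("non-positive column mean")
  grand <- mean(m$values)
  scaled <- sweep(m$values, 2L, grand / col_means, `*`)
  expression_matrix(scaled, m$gene_ids, m$times)
}
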