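#' Read gene models from GFF3/GTF
#'
#' Imports `gene`-type features and derives the start-codon coordinate
#' (leftmost base on `+`, rightmost on `-`). The attributes `feature_type`
#' (CDS/sRNA/tRNA/rRNA/misc_RNA; defaults to CDS when absent) and
#' `operon_id` are picked up when present.
#'
#' @param path GFF3 or GTF file.
#' @return data.frame: gene_id, chrom, strand, start, end, start_codon_pos,
#'   feature_type, operon_id.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) stopf("no gene features in %s", path)
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    if ("gene_id" %in% names(md)) as.character(md$gene_id) else
      stopf("gene features lack ID/gene_id attributes")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) stopf("gene without strand")
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    start_codon_pos = ifelse(strand == "+", BiocGenerics::start(gr),
                             BiocGenerics::end(gr)),
    feature_type = if ("feature_type" %in% names(md))
      as.character(md$feature_type) else "CDS",
    operon_id = if ("operon_id" %in% names(md))
      as.character(md$operon_id) else NA_character_,
    stringsAsFactors = FALSE)
}

#' Read ChIP-seq peak calls
#'
#' Two dialects: `"tsv"` is a MACS2-xls-like 1-based table with columns
#' chrom, start, end, summit, neg_log10_pvalue, fold_enrichment (and an
#' optional name); `"narrowPeak"` is the ENCODE 10-column BED variant,
#' 0-based half-open, whose coordinates are converted to 1-based inclusive
#' (summit = chromStart + peak offset + 1).
#'
#' @param path peak file.
#' @param format "tsv" or "narrowPeak".
#' @return data.frame: chrom, start, end, summit, p_value, fold_enrichment,
#'   name.
#' @export
read_peaks <- function(path, format = c("tsv", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv(path)
    need <- c("chrom", "start", "end", "summit", "neg_log10_pvalue",
              "fold_enrichment")
    if (!all(need %in% colnames(df)))
      stopf("peak TSV must have columns: %s", paste(need, collapse = ", "))
    peaks <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                        summit = df$summit,
                        p_value = 10^(-df$neg_log10_pvalue),
                        fold_enrichment = df$fold_enrichment,
                        name = df$name %||%
                          sprintf("peak_%d", seq_len(nrow(df))),
                        stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 10) stopf("narrowPeak requires 10 columns")
    colnames(df)[1:10] <- c("chrom", "chromStart", "chromEnd", "name",
                            "score", "strand", "signalValue", "pValue",
                            "qValue", "peak")
    if (any(df$peak < 0)) stopf("narrowPeak summit offset missing (-1)")
    peaks <- data.frame(chrom = df$chrom, start = df$chromStart + 1L,
                        end = df$chromEnd,
                        summit = df$chromStart + df$peak + 1L,
                        p_value = 10^(-df$pValue),
                        fold_enrichment = df$signalValue, name = df$name,
                        stringsAsFactors = FALSE)
  }
  validate_peaks(peaks)
  peaks
}

#' @keywords internal
#' @noRd
validate_peaks <- function(peaks) {
  if (nrow(peaks) == 0) return(invisible(peaks))
  if (any(peaks$start > peaks$summit | peaks$summit > peaks$end))
    stopf("peak summit outside [start, end]")
  if (any(peaks$p_value <= 0 | peaks$p_value > 1))
    stopf("peak p_value outside (0, 1]")
  if (any(peaks$fold_enrichment <= 0)) stopf("non-positive fold enrichment")
  invisible(peaks)
}

#' Filter peaks on significance and fold enrichment
#'
#' Keeps peaks with P < `p_max` (strict) and fold enrichment >= `fe_min`
#' (inclusive), preserving input order.
#'
#' @param peaks data.frame as from [read_peaks()].
#' @param p_max P-value cutoff (default 0.05, exclusive).
#' @param fe_min fold-enrichment cutoff (default 2.0, inclusive).
#' @return filtered data.frame.
#' @export
filter_peaks <- function(peaks, p_max = 0.05, fe_min = 2.0) {
  validate_peaks(peaks)
  peaks[peaks$p_value < p_max & peaks$fold_enrichment >= fe_min, ,
        drop = FALSE]
}

#' Assign peak summits to genes by upstream distance
#'
#' A gene is assigned a peak when the summit lies on the gene's chromosome
#' at a strand-aware upstream distance d = start_codon_pos - summit (on
#' `+`) or summit - start_codon_pos (on `-`) with 0 <= d <= `max_upstream`
#' (both bounds inclusive; a summit exactly on the start codon counts).
#' One summit may serve several genes (divergent promoters).
#'
#' @param peaks filtered peaks data.frame.
#' @param genes gene models as from [read_gene_models()].
#' @param max_upstream assignment cutoff in bp (default 300).
#' @return regulon table data.frame: gene_id, peak name, distance,
#'   source = "direct".
#' @export
assign_peaks_to_genes <- function(peaks, genes, max_upstream = 300) {
  validate_peaks(peaks)
  if (nrow(peaks) > 0 && !all(peaks$chrom %in% genes$chrom))
    stopf("peak chromosome(s) absent from gene annotation: %s",
          paste(setdiff(unique(peaks$chrom), genes$chrom), collapse = ", "))
  empty <- data.frame(gene_id = character(0), peak = character(0),
                      distance = numeric(0), source = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) return(empty)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    d <- ifelse(g$strand == "+", g$start_codon_pos - peaks$summit[i],
                peaks$summit[i] - g$start_codon_pos)
    hit <- which(d >= 0 & d <= max_upstream)
    if (length(hit) == 0) return(NULL)
    data.frame(gene_id = g$gene_id[hit], peak = peaks$name[i],
               distance = d[hit], source = "direct",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Expand direct assignments over operon membership
#'
#' If any directly assigned gene belongs to an operon, every member of that
#' operon enters the regulon table; genes added this way are flagged
#' `source = "operon"`. Genes already present directly are not duplicated.
#' Idempotent.
#'
#' @param direct regulon table from [assign_peaks_to_genes()] (possibly
#'   already expanded).
#' @param operons data.frame with columns operon_id, gene_id (and
#'   optionally rank).
#' @param genes optional gene models; when given, operon gene ids are
#'   checked against it.
#' @return expanded regulon table.
#' @export
expand_operons <- function(direct, operons, genes = NULL) {
  if (!is.null(genes) && !all(operons$gene_id %in% genes$gene_id))
    stopf("operon table references unknown gene(s): %s",
          paste(setdiff(operons$gene_id, genes$gene_id), collapse = ", "))
  if (nrow(direct) == 0 || nrow(operons) == 0) return(direct)
  hit_ops <- unique(operons$operon_id[operons$gene_id %in% direct$gene_id])
  members <- unique(operons$gene_id[operons$operon_id %in% hit_ops])
  add <- setdiff(members, direct$gene_id)
  if (length(add) == 0) return(direct)
  rbind(direct,
        data.frame(gene_id = add, peak = NA_character_, distance = NA_real_,
                   source = "operon", stringsAsFactors = FALSE))
}

#' Summarize a regulon table by feature type
#'
#' @param table regulon table (one or more rows per gene).
#' @param genes gene models providing feature_type and operon_id.
#' @return list: `by_feature_type` (named counts over distinct genes),
#'   `n_genes` (distinct genes), `n_operons` (distinct operons touched).
#' @export
summarize_regulon <- function(table, genes) {
  ids <- unique(table$gene_id)
  ft <- genes$feature_type[match(ids, genes$gene_id)]
  ops <- genes$operon_id[match(ids, genes$gene_id)]
  levels_ft <- c("CDS", "sRNA", "tRNA", "rRNA", "misc_RNA")
  counts <- table(factor(ft, levels = union(levels_ft, unique(ft))))
  list(by_feature_type = setNames(as.integer(counts), names(counts)),
       n_genes = length(ids),
       n_operons = length(unique(stats::na.omit(ops))))
}
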