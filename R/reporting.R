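#' Fold abundance of functional categories inside a gene set
#'
#' For a gene set of size m drawn from a genome of `genome_total` genes,
#' each category with K genes genome-wide and k genes inside the set gets
#' fold = (k / K) / (m / genome_total): how over-represented the category
#' is in the set relative to the genome. Categories with K = 0 are
#' omitted. No significance test is attached; this is descriptive.
#'
#' @param gene_set character vector of gene ids (the regulon subset).
#' @param category_map data.frame with columns gene_id, category (one row
#'   per gene per level; genes may be absent = uncategorized).
#' @param genome_total total number of genes in the genome (>= set size).
#' @return data.frame: category, k, K, fold, sorted by decreasing fold.
#' @export
category_fold_abundance <- function(gene_set, category_map, genome_total) {
  assert_scalar_num(genome_total, "genome_total", lo = 1)
  gene_set <- unique(gene_set)
  if (genome_total < length(gene_set))
    stopf("genome_total (%g) smaller than set size (%d)", genome_total,
          length(gene_set))
  m <- length(gene_set)
  cats <- unique(category_map$category)
  rows <- lapply(cats, function(cat) {
    members <- unique(category_map$gene_id[category_map$category == cat])
    K <- length(members)
    if (K == 0) return(NULL)
    k <- sum(gene_set %in% members)
    data.frame(category = cat, k = k, K = K,
               fold = (k / K) / (m / genome_total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category = character(0), k = integer(0),
                      K = integer(0), fold = numeric(0)))
  out[order(-out$fold), , drop = FALSE]
}

#' Run configuration for the full pipeline
#'
#' @param expression path to the expression TSV (gene_id + time columns).
#' @param genes path to the GFF3 gene annotation.
#' @param peaks path to the peak table.
#' @param operons path to the operon TSV (operon_id, gene_id, rank).
#' @param tss optional TSS TSV path (promoter stats skipped when NULL).
#' @param genome optional genome FASTA path.
#' @param regulator_gene,cofactor_gene gene ids of the sigma factor and
#'   cofactor inside the expression table.
#' @param outdir output directory.
#' @param log_base de-log base for the expression table (NULL = linear).
#' @param p_max,fe_min,max_upstream peak filtering/assignment settings.
#' @param fit a [fit_config()].
#' @param run_fpr also run the permutation false-positive estimate.
#' @param category_map optional data.frame (gene_id, category) for fold
#'   abundance; requires `genome_total`.
#' @param genome_total total gene count backing the fold-abundance
#'   denominator.
#' @param seed master seed; overrides `fit$seed`.
#' @return a `run_config` list.
#' @export
run_config <- function(expression, genes, peaks, operons, tss = NULL,
                       genome = NULL, regulator_gene, cofactor_gene,
                       outdir, log_base = NULL, p_max = 0.05, fe_min = 2.0,
                       max_upstream = 300, fit = fit_config(),
                       run_fpr = FALSE, category_map = NULL,
                       genome_total = NULL, seed = 1L) {
  cfg <- as.list(environment())
  cfg$fit$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Run the complete regulon analysis
#'
#' Stages: peak filtering and gene/operon assignment; expression loading,
#' normalization and smoothing; kinetic classification of every regulon
#' gene present in the expression table (the regulator and cofactor rows
#' are used as the model inputs, never as targets); optional permutation
#' false-positive estimate; optional promoter -10/GG statistics; optional
#' category fold abundance. Writes TSV tables plus a JSON summary whose
#' category counts partition the modeled genes, and returns the bundle.
#'
#' @param cfg a [run_config()].
#' @param verbose log per-stage progress to standard error.
#' @return list: `regulon`, `classifications`, `summary`, and (when
#'   configured) `fpr`, `promoter`, `fold_abundance`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, "secs"))
    out
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  genes <- stage("annotation", read_gene_models(cfg$genes))
  operons <- stage("operons", read_tsv(cfg$operons))
  regulon <- stage("mapping", {
    pk <- filter_peaks(read_peaks(cfg$peaks), cfg$p_max, cfg$fe_min)
    expand_operons(assign_peaks_to_genes(pk, genes, cfg$max_upstream),
                   operons, genes)
  })
  write_tsv(regulon, file.path(cfg$outdir, "regulon.tsv"))

  m <- stage("expression", {
    normalize_timepoints(read_expression_matrix(cfg$expression,
                                                cfg$log_base))
  })
  for (g in c(cfg$regulator_gene, cfg$cofactor_gene))
    if (!g %in% m$gene_ids) stopf("regulator/cofactor '%s' not in expression", g)
  reg_prof <- smooth_profile(m$values[cfg$regulator_gene, ], m$times,
                             gene_id = cfg$regulator_gene)
  cof_prof <- smooth_profile(m$values[cfg$cofactor_gene, ], m$times,
                             gene_id = cfg$cofactor_gene)

  target_ids <- setdiff(intersect(unique(regulon$gene_id), m$gene_ids),
                        c(cfg$regulator_gene, cfg$cofactor_gene))
  cls <- stage("classification", {
    if (length(target_ids) == 0) {
      data.frame(gene_id = character(0), category = character(0),
                 improvement = numeric(0), tier = character(0),
                 rmse_constant = numeric(0), rmse_direct = numeric(0),
                 rmse_cooperative = numeric(0))
    } else {
      sub <- expression_matrix(m$values[target_ids, , drop = FALSE],
                               target_ids, m$times)
      classify_genes(sub, reg_prof, cof_prof, cfg$fit, verbose = verbose)
    }
  })
  write_tsv(cls, file.path(cfg$outdir, "classifications.tsv"))

  out <- list(regulon = regulon, classifications = cls)
  if (isTRUE(cfg$run_fpr) && length(target_ids) > 0) {
    out$fpr <- stage("fpr", {
      sub <- expression_matrix(m$values[target_ids, , drop = FALSE],
                               target_ids, m$times)
      estimate_false_positive_rate(sub, m$values[cfg$regulator_gene, ],
                                   m$times, cfg$fit)
    })
    write_tsv(out$fpr$detail, file.path(cfg$outdir, "fpr_detail.tsv"))
  }
  if (!is.null(cfg$tss) && !is.null(cfg$genome)) {
    out$promoter <- stage("promoter", {
      promoter_gg_report(read_genome_fasta(cfg$genome), read_tss(cfg$tss),
                         unique(regulon$gene_id))
    })
  }
  if (!is.null(cfg$category_map) && !is.null(cfg$genome_total)) {
    out$fold_abundance <- stage("fold_abundance", {
      regulated_ids <- cls$gene_id[cls$category %in%
                                     c("regulated", "complex_only")]
      category_fold_abundance(regulated_ids, cfg$category_map,
                              cfg$genome_total)
    })
    write_tsv(out$fold_abundance,
              file.path(cfg$outdir, "fold_abundance.tsv"))
  }

  cat_counts <- vapply(c("constitutive", "regulated", "complex_only",
                         "not_modeled"),
                       function(k) sum(cls$category == k), integer(1))
  tier_counts <- vapply(c("ge10", "ge20"), function(k)
    sum(cls$category == "regulated" &
          (if (k == "ge10") cls$tier %in% c("ge10", "ge20")
           else cls$tier == "ge20")), integer(1))
  out$summary <- list(
    n_regulon_genes = length(unique(regulon$gene_id)),
    n_modeled = nrow(cls), categories = as.list(cat_counts),
    tiers = as.list(tier_counts),
    fpr = if (!is.null(out$fpr))
      list(fraction_accepted = out$fpr$fraction_accepted,
           fpr = out$fpr$fpr) else NULL,
    promoter = if (!is.null(out$promoter))
      list(f_gg = out$promoter$f_gg,
           dependent_counts = as.list(out$promoter$dependent$counts),
           independent_counts = as.list(out$promoter$independent$counts),
           expected_gg = out$promoter$expected_gg$raw,
           fisher_p = out$promoter$fisher_p) else NULL,
    settings = list(epsilon = cfg$fit$epsilon, p_max = cfg$p_max,
                    fe_min = cfg$fe_min, max_upstream = cfg$max_upstream,
                    seed = cfg$seed))
  jsonlite::write_json(out$summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  out
}
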