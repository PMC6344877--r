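# Shared builders for unit tests. Everything is generated in code; no
# fixture files.

# reduced annealing budget for unit tests (polish does the convergence)
quick_fit_config <- function(seed = 1L, ...) {
  fit_config(n_steps = 250, n_restarts = 2, seed = seed, ...)
}

# small synthetic world: short grid work is done on the full 32-point grid
# only where a test needs it
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             n_genes = c(constant = 3L, direct = 3L, cooperative = 3L),
             genome_length = 24000L, n_genomic_genes = 15L, ...)
}

# write an expression TSV and return its path
write_expression_tsv <- function(values, gene_ids, times,
                                 path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = gene_ids, values, check.names = FALSE)
  colnames(df) <- c("gene_id", as.character(times))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# hand-built gene model table
toy_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1", strand = c("+", "-", "+"),
    start = c(1000, 2401, 5000), end = c(1599, 3000, 5599),
    start_codon_pos = c(1000, 3000, 5000),
    feature_type = c("CDS", "CDS", "sRNA"),
    operon_id = c("op1", "op1", NA_character_),
    stringsAsFactors = FALSE)
}

toy_peak <- function(summit, p = 0.01, fe = 3, chrom = "chr1",
                     name = "pk") {
  data.frame(chrom = chrom, start = summit - 50, end = summit + 50,
             summit = summit, p_value = p, fold_enrichment = fe,
             name = name, stringsAsFactors = FALSE)
}

# independent Fisher oracle: two-sided exact P by hypergeometric
# enumeration over all tables with the observed margins
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
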