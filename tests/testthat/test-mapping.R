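test_that("filter_peaks applies P < 0.05 strictly and FE >= 2 inclusively", {
  peaks <- rbind(toy_peak(100, p = 0.01, fe = 2.5, name = "a"),
                 toy_peak(200, p = 0.20, fe = 3.0, name = "b"),
                 toy_peak(300, p = 0.01, fe = 1.8, name = "c"),
                 toy_peak(400, p = 0.01, fe = 2.0, name = "d"))
  kept <- filter_peaks(peaks)
  expect_equal(kept$name, c("a", "d"))    # FE exactly 2.0 is kept
  expect_equal(nrow(filter_peaks(peaks[0, ])), 0)
})

test_that("summit-to-start-codon assignment is strand-aware with inclusive bounds", {
  genes <- toy_genes()
  # + strand gene at 1000: summit 800 -> d = 200
  expect_equal(assign_peaks_to_genes(toy_peak(800), genes)$gene_id, "gA")
  # summit downstream of + strand start codon -> no assignment
  expect_equal(nrow(assign_peaks_to_genes(toy_peak(1001), genes)), 0)
  # - strand gene at 3000: summit 3250 -> d = 250
  expect_equal(assign_peaks_to_genes(toy_peak(3250), genes)$gene_id, "gB")
  # boundary: d = 300 in, d = 301 out; d = 0 in
  expect_equal(assign_peaks_to_genes(toy_peak(700), genes)$distance, 300)
  expect_equal(nrow(assign_peaks_to_genes(toy_peak(699), genes)), 0)
  expect_equal(assign_peaks_to_genes(toy_peak(1000), genes)$distance, 0)
  expect_error(assign_peaks_to_genes(toy_peak(5, chrom = "chrX"), genes),
               "chromosome")
})

test_that("one summit can serve divergent genes", {
  genes <- data.frame(gene_id = c("left", "right"), chrom = "chr1",
                      strand = c("-", "+"),
                      start = c(401, 1200), end = c(1000, 1799),
                      start_codon_pos = c(1000, 1200),
                      feature_type = "CDS", operon_id = NA_character_,
                      stringsAsFactors = FALSE)
  hits <- assign_peaks_to_genes(toy_peak(1100), genes)
  expect_setequal(hits$gene_id, c("left", "right"))
})

test_that("operon expansion adds whole operons once and is idempotent", {
  genes <- toy_genes()
  operons <- data.frame(operon_id = "op1", gene_id = c("gA", "gB"),
                        rank = 1:2, stringsAsFactors = FALSE)
  direct <- assign_peaks_to_genes(toy_peak(800), genes)
  ex <- expand_operons(direct, operons, genes)
  expect_setequal(ex$gene_id, c("gA", "gB"))
  expect_equal(ex$source[ex$gene_id == "gB"], "operon")
  expect_identical(expand_operons(ex, operons, genes), ex)
  # gene without operon unchanged
  solo <- assign_peaks_to_genes(toy_peak(4900), genes)
  expect_identical(expand_operons(solo, operons, genes), solo)
  bad <- data.frame(operon_id = "opX", gene_id = "ghost", rank = 1)
  expect_error(expand_operons(direct, bad, genes), "unknown")
})

test_that("summarize_regulon counts by feature type", {
  genes <- toy_genes()
  tab <- data.frame(gene_id = c("gA", "gB", "gC"), peak = NA, distance = NA,
                    source = "direct")
  s <- summarize_regulon(tab, genes)
  expect_equal(s$by_feature_type[["CDS"]], 2)
  expect_equal(s$by_feature_type[["sRNA"]], 1)
  expect_equal(s$n_genes, 3)
  expect_equal(sum(s$by_feature_type), s$n_genes)
  empty <- summarize_regulon(tab[0, ], genes)
  expect_equal(empty$n_genes, 0)
  expect_true(all(empty$by_feature_type == 0))
})

test_that("filtering and assignment commute", {
  cfg <- small_sim_config(seed = 15)
  fx <- make_genomic_fixtures(cfg)
  tmp <- tempfile(); paths <- write_genomic_fixtures(fx, tmp)
  peaks <- read_peaks(paths[["peaks"]])
  genes <- read_gene_models(paths[["genes"]])
  a <- assign_peaks_to_genes(filter_peaks(peaks), genes)
  b <- assign_peaks_to_genes(peaks, genes)
  keep <- peaks$name[peaks$p_value < 0.05 & peaks$fold_enrichment >= 2]
  b <- b[b$peak %in% keep, , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[order(a$gene_id, a$peak), ], b[order(b$gene_id, b$peak), ],
               ignore_attr = TRUE)
})

test_that("fixture round-trip reproduces planted regulon truth exactly", {
  cfg <- small_sim_config(seed = 16)
  fx <- make_genomic_fixtures(cfg)
  tmp <- tempfile(); paths <- write_genomic_fixtures(fx, tmp)
  genes <- read_gene_models(paths[["genes"]])
  operons <- read.delim(paths[["operons"]])
  peaks <- filter_peaks(read_peaks(paths[["peaks"]]))
  tab <- expand_operons(assign_peaks_to_genes(peaks, genes), operons, genes)
  got <- sort(unique(tab$gene_id))
  want <- sort(fx$truth$regulon$gene_id)
  expect_identical(got, want)   # precision = recall = 1
  direct_got <- sort(unique(tab$gene_id[tab$source == "direct"]))
  expect_identical(direct_got,
                   sort(fx$truth$regulon$gene_id[fx$truth$regulon$direct]))
})

test_that("narrowPeak input converts 0-based coordinates", {
  np <- data.frame(chrom = "chr1", chromStart = 799, chromEnd = 950,
                   name = "pk1", score = 100, strand = ".",
                   signalValue = 3.2, pValue = 4.0, qValue = 3.0,
                   peak = 50)
  f <- tempfile(fileext = ".narrowPeak")
  write.table(np, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  pk <- read_peaks(f, format = "narrowPeak")
  expect_equal(pk$start, 800)
  expect_equal(pk$summit, 850)     # chromStart + peak offset, 1-based
  expect_equal(pk$p_value, 1e-4)
  expect_equal(pk$fold_enrichment, 3.2)
})
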