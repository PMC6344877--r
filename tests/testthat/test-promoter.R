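test_that("filter_primary_tss keeps only primary records in order", {
  tss <- data.frame(chrom = "c", position = c(10, 20, 30),
                    strand = "+", category = c("primary", "internal",
                                               "primary"),
                    gene_id = c("a", "b", "c"))
  got <- filter_primary_tss(tss)
  expect_equal(got$gene_id, c("a", "c"))
  expect_equal(nrow(filter_primary_tss(tss[0, ])), 0)
})

test_that("extract_windows is inclusive and strand-aware", {
  #            123456789012345678901234567890
  genome <- c(chr = "ACGTACGTACGTACGTACGTACGTACGTAC")
  tss <- data.frame(chrom = "chr", position = 25, strand = "+",
                    category = "primary", gene_id = "g1")
  w <- extract_windows(tss, genome, -20, 0)
  expect_equal(nchar(w$sequence), 21)
  expect_equal(w$sequence, unname(substr(genome, 5, 25)))

  w35 <- extract_windows(tss, genome, -20, -5)
  expect_equal(nchar(w35$sequence), 16)

  # minus strand: window is the reverse complement of the + slice
  tssm <- data.frame(chrom = "chr", position = 6, strand = "-",
                     category = "primary", gene_id = "g2")
  wm <- extract_windows(tssm, genome, -20, 0)
  plus_slice <- unname(substr(genome, 6, 26))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_slice)))
  expect_equal(wm$sequence, rc)

  # out-of-contig window skipped with warning
  tss_edge <- data.frame(chrom = "chr", position = 5, strand = "+",
                         category = "primary", gene_id = "g3")
  expect_warning(out <- extract_windows(tss_edge, genome, -20, 0),
                 "skipping")
  expect_equal(nrow(out), 0)
})

test_that("pattern scan anchors the leftmost TANNNT and drops non-matches", {
  win <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr",
                    position = 100, strand = "+", from_off = -20, to_off = 0,
                    sequence = c("CCCCCCCCTACGGTCCCCCCC",   # one match at 9
                                 "CCCCCCCCCCCCCCCCCCCCC",   # none
                                 "TACGGTCCTAAAATCCCCCCC"),  # two: leftmost
                    stringsAsFactors = FALSE)
  got <- scan_motif(win, "TANNNT")
  expect_equal(got$gene_id, c("a", "c"))
  expect_equal(got$anchor_index, c(9L, 1L))
  expect_equal(got$anchor_offset, c(-12L, -20L))
  expect_equal(got$site, c("TACGGT", "TACGGT"))
})

test_that("PWM scan P-values match exhaustive hexamer enumeration", {
  # sharp TANNNT-like PWM
  pwm <- matrix(0.25 / 3, nrow = 4, ncol = 6,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["T", 1] <- 0.85; pwm[c("A", "C", "G"), 1] <- 0.05
  pwm["A", 2] <- 0.85; pwm[c("T", "C", "G"), 2] <- 0.05
  pwm["T", 6] <- 0.85; pwm[c("A", "C", "G"), 6] <- 0.05
  pwm[, 3:5] <- 0.25
  win <- data.frame(gene_id = "a", chrom = "chr", position = 100,
                    strand = "+", from_off = -20, to_off = 0,
                    sequence = "CCCCCCCCTACGGTCCCCCCC",
                    stringsAsFactors = FALSE)
  got <- scan_motif(win, pwm)
  expect_equal(got$anchor_index, 9L)

  # oracle: enumerate all 4096 hexamers under uniform background
  bases <- c("A", "C", "G", "T")
  hex <- as.matrix(do.call(expand.grid,
                           c(rep(list(bases), 6),
                             stringsAsFactors = FALSE)))
  score <- function(ch) sum(log(pwm[cbind(match(ch, bases), 1:6)] + 1e-12))
  all_scores <- apply(hex, 1, score)
  best <- score(strsplit("TACGGT", "")[[1]])
  p_oracle <- sum(all_scores >= best - 1e-12) / 4096
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
})

test_that("classify_gg groups by the two bases ahead of the anchor", {
  mk <- function(seqs, anchor) {
    data.frame(gene_id = paste0("g", seq_along(seqs)), chrom = "chr",
               position = 100, strand = "+", from_off = -20, to_off = 0,
               sequence = seqs, anchor_index = anchor,
               anchor_offset = -21 + anchor,
               site = substr(seqs, anchor, anchor + 5),
               p_value = NA_real_, stringsAsFactors = FALSE)
  }
  sites <- mk(c("CCCCCCGGTACGGTCCCCCCC",    # GG before anchor at 9
                "CCCCCCGATACGGTCCCCCCC",    # GA -> one G
                "CCCCCCAGTACGGTCCCCCCC",    # AG -> one G
                "CCCCCCAATACGGTCCCCCCC"),   # noG
              9L)
  cl <- classify_gg(sites)
  expect_equal(unname(cl$counts), c(1L, 2L, 1L))
  expect_equal(sum(cl$counts), cl$n_sites)
  expect_equal(unname(cl$base_at_minus12[["T"]]), 4L)

  # anchor too close to the edge is skipped with a message
  edge <- mk("TACGGTCCCCCCCCCCCCCCC", 1L)
  expect_message(cl2 <- classify_gg(edge), "skipped")
  expect_equal(cl2$n_sites, 0)
  expect_equal(cl2$n_skipped, 1)
})

test_that("genome_gg_frequency counts overlapping dinucleotides", {
  expect_equal(genome_gg_frequency("GGG"), 1.0)
  expect_equal(genome_gg_frequency("ATAT"), 0)
  expect_equal(genome_gg_frequency("GGAT"), 1 / 3)
  # multiple contigs pool counts and denominators
  expect_equal(genome_gg_frequency(c("GGG", "GGAT")), (2 + 1) / (2 + 3))
  expect_error(genome_gg_frequency(character(0)), "empty")

  # i.i.d. uniform genome: f_GG ~ 1/16 within 3 sigma
  set.seed(77)
  g <- paste(sample(c("A", "C", "G", "T"), 40000, replace = TRUE),
             collapse = "")
  f <- genome_gg_frequency(g)
  sigma <- sqrt((1 / 16) * (15 / 16) / 39999)
  expect_lt(abs(f - 1 / 16), 3 * sigma * 2)  # overlapping counts widen var
})

test_that("expected_gg_sites reproduces the worked example", {
  e <- expected_gg_sites(0.114, 954)
  expect_equal(e$raw, 108.756, tolerance = 1e-12)
  expect_equal(e$rounded, 109)
  expect_equal(expected_gg_sites(0, 100)$raw, 0)
  expect_equal(expected_gg_sites(1, 10)$raw, 10)
})

test_that("fisher_gg_enrichment matches the hypergeometric oracle", {
  expect_equal(fisher_gg_enrichment(10, 10, 10, 10), 1)
  expect_equal(fisher_gg_enrichment(5, 0, 0, 5), 2 / 252,
               tolerance = 1e-12)
  set.seed(19)
  for (i in 1:25) {
    tab <- rpois(4, 8)
    if (sum(tab) == 0) next
    expect_equal(fisher_gg_enrichment(tab[1], tab[2], tab[3], tab[4]),
                 fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
  expect_error(fisher_gg_enrichment(0, 0, 0, 0), "zero")
})

test_that("promoter report round-trips the planted fixture truth", {
  cfg <- small_sim_config(seed = 21, motif_plant_rate = 1)
  fx <- make_genomic_fixtures(cfg)
  rep <- promoter_gg_report(fx$genome, fx$tss,
                            fx$truth$regulon$gene_id)
  tp <- fx$truth$promoters
  dep_truth <- tp[tp$dependent & tp$motif_planted, ]
  ind_truth <- tp[!tp$dependent & tp$motif_planted, ]
  expect_equal(rep$dependent$n_sites, nrow(dep_truth))
  expect_equal(rep$independent$n_sites, nrow(ind_truth))
  expect_equal(unname(rep$dependent$counts[["GG"]]),
               sum(dep_truth$gg_class == "GG"))
  expect_equal(unname(rep$independent$counts[["GG"]]),
               sum(ind_truth$gg_class == "GG"))
  expect_equal(sum(rep$dependent$counts), rep$dependent$n_sites)
  expect_gt(rep$f_gg, 0)
  expect_equal(rep$expected_gg$raw, rep$f_gg * rep$dependent$n_sites)
})
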