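test_that("regulator profiles have the stated shapes", {
  cfg <- sim_config()
  regs <- make_regulator_profiles(cfg)
  span <- range(cfg$time_grid)
  tt <- seq(span[1], span[2], length.out = 400)
  a <- profile_values(regs$regulator, tt)
  b <- profile_values(regs$cofactor, tt)
  expect_true(all(a > 0) && all(b > 0))
  third <- diff(span) / 3
  expect_lt(tt[which.max(a)], span[1] + third)        # early peak
  expect_gt(tt[which.max(b)], span[2] - third)        # late peak
  expect_lt(tt[which.max(a)], tt[which.max(b)])
  # unimodal: rises then falls
  da <- diff(a)
  expect_equal(sum(diff(sign(da[abs(da) > 1e-10])) != 0), 1)

  # zero cofactor amplitude -> flat positive baseline
  flat <- make_regulator_profiles(sim_config(cofactor_amplitude = 0))
  bv <- profile_values(flat$cofactor, tt)
  expect_lt(diff(range(bv)), 1e-6)
  expect_gt(min(bv), 0)

  # determinism
  regs2 <- make_regulator_profiles(sim_config())
  expect_equal(profile_values(regs2$regulator, tt), a)
})

test_that("simulate_targets obeys closed forms when noiseless", {
  cfg <- sim_config(noise_sd = 0, n_genes = c(constant = 0L, direct = 0L,
                                              cooperative = 0L))
  regs <- make_regulator_profiles(cfg)
  tg <- cfg$time_grid

  pl <- list(ss = kinetic_params("constant", k1 = 2, k2 = 1, x0 = 2),
             dec = kinetic_params("constant", k1 = 0, k2 = 1, x0 = 1),
             d0 = kinetic_params("direct", k1 = 3, k2 = 0.5, w = 0, b = 0.4,
                                 x0 = 2))
  out <- simulate_targets(cfg, pl, regs)
  expect_equal(unname(out$matrix$values["ss", ]), rep(2, 32),
               tolerance = 1e-8)
  # pure decay: x(t) = e^-(t - t0); at t - t0 = 1 this is 0.3679
  # (compared at the solver default relative tolerance)
  expect_equal(unname(out$matrix$values["dec", ]), exp(-(tg - tg[1])),
               tolerance = 1e-5)
  expect_equal(unname(out$matrix$values["dec", "21"]), exp(-1),
               tolerance = 1e-5)
  # direct with w = 0 equals constant synthesis at k1 * sigmoid(b)
  k1_eff <- 3 / (1 + exp(-0.4))
  closed <- k1_eff / 0.5 + (2 - k1_eff / 0.5) * exp(-0.5 * (tg - tg[1]))
  expect_equal(unname(out$matrix$values["d0", ]), closed, tolerance = 1e-5)
  expect_equal(out$truth$model_kind, c("constant", "constant", "direct"))
})

test_that("simulated series are seed-deterministic with planted truth counts", {
  cfg <- small_sim_config(seed = 33)
  s1 <- simulate_targets(cfg)
  s2 <- simulate_targets(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  tab <- table(s1$truth$model_kind)
  expect_equal(as.integer(tab[c("constant", "direct", "cooperative")]),
               as.integer(cfg$n_genes[c("constant", "direct",
                                        "cooperative")]))
  # noise is multiplicative: all values positive
  expect_true(all(s1$matrix$values > 0))
})

test_that("genomic fixtures are consistent, deterministic and truthful", {
  cfg <- small_sim_config(seed = 12)
  fx <- make_genomic_fixtures(cfg)
  L <- unname(nchar(fx$genome))
  expect_equal(L, cfg$genome_length)
  expect_true(all(fx$tss$position >= 1 & fx$tss$position <= L))
  expect_equal(nrow(fx$genes), cfg$n_genomic_genes)

  # planted motifs occupy TSS offsets -12..-7 as TANNNT
  chars <- strsplit(fx$genome, "")[[1]]
  tp <- fx$truth$promoters
  planted <- tp[tp$motif_planted, ]
  for (i in seq_len(nrow(planted))) {
    win <- if (planted$strand[i] == "+")
      chars[(planted$tss_pos[i] - 12):(planted$tss_pos[i] - 7)]
    else {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      rev(unname(comp[chars[(planted$tss_pos[i] + 7):
                              (planted$tss_pos[i] + 12)]]))
    }
    expect_equal(win[c(1, 2, 6)], c("T", "A", "T"))
  }

  # determinism
  fx2 <- make_genomic_fixtures(cfg)
  expect_identical(fx$genome, fx2$genome)
  expect_identical(fx$peaks, fx2$peaks)

  # peak truth: distances and filter flags consistent
  expect_true(all(fx$truth$peaks$assignable == (fx$truth$peaks$distance <= 300)))
  p <- 10^(-fx$peaks$neg_log10_pvalue)
  expect_equal(p < 0.05 & fx$peaks$fold_enrichment >= 2,
               fx$truth$peaks$passes_filter)
})

test_that("gg_rate 1 plants GG at every dependent-class site", {
  cfg <- small_sim_config(seed = 13, gg_rate_dependent = 1)
  fx <- make_genomic_fixtures(cfg)
  tp <- fx$truth$promoters
  dep <- tp[tp$dependent & tp$motif_planted, ]
  expect_gt(nrow(dep), 0)
  expect_true(all(dep$gg_class == "GG"))
})

test_that("fixture files are written as valid plain-text formats", {
  cfg <- small_sim_config(seed = 14)
  fx <- make_genomic_fixtures(cfg)
  outdir <- tempfile()
  paths <- write_genomic_fixtures(fx, outdir)
  expect_true(all(file.exists(paths)))
  genome <- read_genome_fasta(paths[["genome"]])
  expect_equal(unname(as.character(genome[[1]])), unname(fx$genome))
  genes <- read_gene_models(paths[["genes"]])
  expect_setequal(genes$gene_id, fx$genes$gene_id)
  expect_equal(genes$start_codon_pos[match(fx$genes$gene_id, genes$gene_id)],
               fx$genes$start_codon_pos)

  # byte-identical FASTA under the same seed
  outdir2 <- tempfile()
  write_genomic_fixtures(make_genomic_fixtures(cfg), outdir2)
  expect_identical(readLines(file.path(outdir, "genome.fasta")),
                   readLines(file.path(outdir2, "genome.fasta")))
})
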