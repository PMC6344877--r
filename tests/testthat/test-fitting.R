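test_that("rmse is the root-mean-square difference", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(5, 2), 3)
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("fit_model recovers a constant-model target", {
  tt <- default_time_grid()
  p <- kinetic_params("constant", k1 = 3, k2 = 0.5, x0 = 2)
  target <- simulate_kinetics(p, list(), tt)
  fr <- fit_model("constant", target, list(), tt, quick_fit_config(3), "c1")
  expect_true(fr$accepted)
  expect_lt(fr$rmse, fr$scale * 0.05)
  # steady state k1/k2 recovered within 10%
  expect_lt(abs(fr$params$k1 / fr$params$k2 - 6) / 6, 0.1)
})

test_that("fit_model recovers a direct-model target and is seed-deterministic", {
  cfg <- sim_config()
  tt <- cfg$time_grid
  regs <- make_regulator_profiles(cfg)
  p <- kinetic_params("direct", k1 = 1, k2 = 0.5, w = 2, b = -1, x0 = 1)
  clean <- simulate_kinetics(p, list(regs$regulator), tt)
  set.seed(21)
  noisy <- clean * exp(rnorm(32, 0, 0.05))
  prof <- smooth_profile(noisy, tt, gene_id = "d1")
  fc <- quick_fit_config(5)
  fr <- fit_model("direct", prof, list(regs$regulator), tt, fc, "d1")
  expect_true(fr$accepted)
  # mean-regulator steady-state ratio recovered within 10% of truth
  ybar <- mean(profile_values(regs$regulator, tt, clip = TRUE))
  ss_hat <- fr$params$k1 / (1 + exp(-(fr$params$w * ybar + fr$params$b))) /
    fr$params$k2
  ss_true <- 1 / (1 + exp(-(2 * ybar - 1))) / 0.5
  expect_lt(abs(ss_hat - ss_true) / ss_true, 0.1)

  fr2 <- fit_model("direct", prof, list(regs$regulator), tt, fc, "d1")
  expect_identical(unclass(fr$params), unclass(fr2$params))
  expect_identical(fr$rmse, fr2$rmse)
})

test_that("degenerate flat target returns an exact constant fit", {
  tt <- default_time_grid()
  fr <- fit_model("constant", rep(4, 32), list(), tt, quick_fit_config(), "f")
  expect_true(fr$accepted)
  expect_equal(fr$rmse, 0)
})

test_that("classification cascade assigns the expected categories", {
  cfg <- small_sim_config(seed = 2)
  regs <- make_regulator_profiles(cfg)
  tt <- cfg$time_grid
  fc <- quick_fit_config(2)

  flat <- classify_gene(rep(2.5, 32) * exp(rnorm(32, 0, 0.01)),
                        regs$regulator, regs$cofactor, tt, fc, "flat")
  expect_equal(flat$category, "constitutive")

  p <- kinetic_params("direct", k1 = 4, k2 = 0.5, w = 3, b = -3.5, x0 = 4)
  target <- simulate_kinetics(p, list(regs$regulator), tt)
  cl <- classify_gene(target, regs$regulator, regs$cofactor, tt, fc, "d1")
  expect_equal(cl$category, "regulated")
  expect_false(is.null(cl$fits$cooperative))
})

test_that("every gene gets exactly one category and tiers nest", {
  cfg <- small_sim_config(seed = 4)
  regs <- make_regulator_profiles(cfg)
  sim <- simulate_targets(cfg, regulators = regs)
  cl <- classify_genes(sim$matrix, regs$regulator, regs$cofactor,
                       quick_fit_config(4))
  expect_equal(nrow(cl), length(sim$matrix$gene_ids))
  expect_true(all(cl$category %in% c("constitutive", "regulated",
                                     "complex_only", "not_modeled")))
  counts <- table(cl$category)
  expect_equal(sum(counts), nrow(cl))
  # ge20 implies improvement also >= 0.10 tier-wise
  expect_true(all(cl$tier[cl$tier == "ge20"] != "ge10"))
  expect_true(all(is.na(cl$improvement) |
                    (cl$tier == "ge20") == (cl$improvement >= 0.2)))
})

test_that("loosening epsilon never shrinks the accepted set", {
  cfg <- small_sim_config(seed = 6)
  regs <- make_regulator_profiles(cfg)
  sim <- simulate_targets(cfg, regulators = regs)
  tt <- cfg$time_grid
  acc <- function(eps) {
    fc <- quick_fit_config(6, epsilon = eps)
    vapply(seq_along(sim$matrix$gene_ids), function(i)
      fit_model("direct",
                smooth_profile(sim$matrix$values[i, ], tt),
                list(regs$regulator), tt, fc,
                sim$matrix$gene_ids[i])$accepted, logical(1))
  }
  tight <- acc(0.1)
  loose <- acc(0.3)
  expect_true(all(loose[tight]))
})

test_that("false-positive estimate is coherent and reproducible", {
  cfg <- small_sim_config(seed = 8)
  tt <- cfg$time_grid
  regs <- make_regulator_profiles(cfg)
  reg_raw <- profile_values(regs$regulator, tt, clip = TRUE)
  # regulator-independent targets: constant-model relaxations
  set.seed(8)
  targets <- lapply(1:4, function(i) {
    p <- kinetic_params("constant", k1 = runif(1, 1, 4), k2 = runif(1, 0.3, 1),
                        x0 = runif(1, 1, 6))
    simulate_kinetics(p, list(), tt) * exp(rnorm(32, 0, 0.05))
  })
  fc <- quick_fit_config(8, n_randomizations = 3)
  r1 <- estimate_false_positive_rate(targets, reg_raw, tt, fc)
  expect_lte(r1$fpr, r1$fraction_accepted)
  expect_equal(nrow(r1$detail), 3)
  expect_true(all(r1$detail$fraction_accepted_w <=
                    r1$detail$fraction_accepted))
  r2 <- estimate_false_positive_rate(targets, reg_raw, tt, fc)
  expect_identical(r1$detail, r2$detail)
})

test_that("identically-zero targets yield only no-control acceptances", {
  tt <- default_time_grid()
  targets <- list(rep(0, 32), rep(0, 32))
  fc <- quick_fit_config(9, n_randomizations = 2)
  set.seed(9)
  r <- estimate_false_positive_rate(targets, runif(32, 0.5, 2), tt, fc)
  expect_equal(r$fpr, 0)
})
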