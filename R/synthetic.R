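#' Default sampling grid of the emulated time course
#'
#' 32 time points between 20 and 60 h: hourly from 20 to 44, then every
#' second hour. This irregular grid matches dense sampling through the
#' vegetative/transition phases and sparser sampling late in growth.
#' @return numeric vector of 32 hours.
#' @export
default_time_grid <- function() {
  c(20:24, 26:44, seq(46, 60, by = 2))
}

#' Configuration of the synthetic benchmark world
#'
#' Describes every knob of the synthetic data: the sampling grid, the
#' multiplicative log-normal noise, the two regulator profile shapes (a
#' sigma factor peaking early then slowly decaying, and a cofactor peaking
#' late), the number of target genes generated from each kinetic model, and
#' the toy-genome parameters (length, GC content, motif plant rate, and the
#' probability of a GG dinucleotide at the two positions upstream of the
#' -10 element in the dependent and independent promoter classes).
#'
#' @param time_grid strictly increasing sample times (hours).
#' @param noise_sd sd of multiplicative log-normal noise (0.05 = 5% noise).
#' @param seed integer master seed.
#' @param n_genes named integer vector: targets per generating model.
#' @param regulator_peak,regulator_width,regulator_amplitude,regulator_baseline
#'   shape of the sigma-factor profile (Gaussian bump + baseline).
#' @param cofactor_peak,cofactor_width,cofactor_amplitude,cofactor_baseline
#'   shape of the late-peaking cofactor profile.
#' @param genome_length toy genome size in bp (>= 1000).
#' @param gc_fraction genome GC content (high-GC actinomycete-like default).
#' @param n_genomic_genes genes placed on the toy genome.
#' @param motif_plant_rate probability a primary TSS gets a planted TANNNT
#'   -10 element at offsets -12..-7.
#' @param gg_rate_dependent,gg_rate_independent probability of GG at
#'   -14/-13 for promoters of bound (dependent) vs unbound genes.
#' @param bound_fraction fraction of genomic genes given a passing ChIP
#'   peak within assignable distance.
#' @param peak_distance_range summit-to-start-codon distances (bp) of
#'   assignable planted peaks.
#' @param far_peak_distance_range distances of planted peaks beyond the
#'   assignment cutoff (truth marks them non-assignable).
#' @param n_far_peaks,n_weak_peaks planted non-assignable peaks and peaks
#'   failing the P/fold-enrichment filter.
#' @return A `sim_config` object.
#' @export
sim_config <- function(time_grid = default_time_grid(), noise_sd = 0.05,
                       seed = 1L,
                       n_genes = c(constant = 50L, direct = 50L,
                                   cooperative = 50L),
                       regulator_peak = 26, regulator_width = 14,
                       regulator_amplitude = 2, regulator_baseline = 0.4,
                       cofactor_peak = 54, cofactor_width = 12,
                       cofactor_amplitude = 2, cofactor_baseline = 0.3,
                       genome_length = 60000L, gc_fraction = 0.72,
                       n_genomic_genes = 40L, motif_plant_rate = 0.9,
                       gg_rate_dependent = 0.23, gg_rate_independent = 0.114,
                       bound_fraction = 0.5,
                       peak_distance_range = c(20, 280),
                       far_peak_distance_range = c(301, 450),
                       n_far_peaks = 5L, n_weak_peaks = 5L) {
  if (length(time_grid) < 2 || any(diff(time_grid) <= 0))
    stopf("time_grid must be strictly increasing")
  assert_scalar_num(noise_sd, "noise_sd", lo = 0)
  for (r in c(motif_plant_rate = motif_plant_rate,
              gg_rate_dependent = gg_rate_dependent,
              gg_rate_independent = gg_rate_independent,
              gc_fraction = gc_fraction, bound_fraction = bound_fraction)) {
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  }
  if (genome_length < 1000) stopf("genome_length must be >= 1000")
  if (is.null(names(n_genes)) ||
      !all(names(n_genes) %in% c("constant", "direct", "cooperative")))
    stopf("n_genes must be named by model kind")
  structure(list(time_grid = as.numeric(time_grid), noise_sd = noise_sd,
                 seed = as.integer(seed), n_genes = n_genes,
                 regulator_peak = regulator_peak,
                 regulator_width = regulator_width,
                 regulator_amplitude = regulator_amplitude,
                 regulator_baseline = regulator_baseline,
                 cofactor_peak = cofactor_peak,
                 cofactor_width = cofactor_width,
                 cofactor_amplitude = cofactor_amplitude,
                 cofactor_baseline = cofactor_baseline,
                 genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction,
                 n_genomic_genes = as.integer(n_genomic_genes),
                 motif_plant_rate = motif_plant_rate,
                 gg_rate_dependent = gg_rate_dependent,
                 gg_rate_independent = gg_rate_independent,
                 bound_fraction = bound_fraction,
                 peak_distance_range = peak_distance_range,
                 far_peak_distance_range = far_peak_distance_range,
                 n_far_peaks = as.integer(n_far_peaks),
                 n_weak_peaks = as.integer(n_weak_peaks)),
            class = "sim_config")
}

#' Synthetic regulator and cofactor expression profiles
#'
#' Positive, unimodal Gaussian-bump-plus-baseline curves over the span of
#' the configured time grid: the sigma factor (`regulator`) peaks in the
#' first third of the span and then slowly decays; the cofactor peaks in
#' the last third. Their divergence late in the time course is what makes
#' complex-driven targets distinguishable from directly driven ones.
#'
#' @param config a [sim_config()].
#' @return list of two `smoothed_profile`s: `regulator`, `cofactor`.
#' @export
make_regulator_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  span <- range(config$time_grid)
  bump <- function(peak, width, amp, base) {
    force(peak); force(width); force(amp); force(base)
    function(t) base + amp * exp(-((t - peak) / width)^2)
  }
  reg <- profile_from_function(
    bump(config$regulator_peak, config$regulator_width,
         config$regulator_amplitude, config$regulator_baseline),
    span, gene_id = "regulator")
  cof <- profile_from_function(
    bump(config$cofactor_peak, config$cofactor_width,
         config$cofactor_amplitude, config$cofactor_baseline),
    span, gene_id = "cofactor")
  list(regulator = reg, cofactor = cof)
}

#' Draw kinetic parameters for synthetic target genes
#'
#' Parameter ranges are chosen so that regulated targets carry a clear
#' kinetic signature: the regulatory input w*y + b sweeps several logistic
#' units across the time course, so synthesis genuinely switches rather
#' than sitting on a plateau.
#' @keywords internal
#' @noRd
draw_params <- function(model_kind, i, config, regulators) {
  set.seed(derive_seed(config$seed, "params", model_kind, i))
  tg <- config$time_grid
  reg_vals <- profile_values(regulators$regulator, tg, clip = TRUE)
  reg_mid <- stats::median(reg_vals)
  k2 <- runif(1, 0.2, 0.8)
  if (model_kind == "constant") {
    k1 <- runif(1, 1, 8)
    x0 <- k1 / k2 * runif(1, 0.6, 1.4)
    return(kinetic_params("constant", k1 = k1, k2 = k2, x0 = x0))
  }
  w <- runif(1, 2.5, 5)
  b <- -w * reg_mid + runif(1, -0.5, 0.5) # switch near the regulator's midlevel
  k1 <- runif(1, 2, 8)
  if (model_kind == "direct") {
    y0 <- reg_vals[1]
    x0 <- k1 / k2 * plogis_safe(w * y0 + b)
    return(kinetic_params("direct", k1 = k1, k2 = k2, w = w, b = b, x0 = x0))
  }
  # cooperative: complex-scale weights; small q keeps the complex min-like
  cof_vals <- profile_values(regulators$cofactor, tg, clip = TRUE)
  q <- runif(1, 0.01, 0.2)
  yab <- complex_concentration(reg_vals, cof_vals, q)
  w <- runif(1, 6, 12)
  b <- -w * stats::median(yab) + runif(1, -0.5, 0.5)
  x0 <- k1 / k2 * plogis_safe(w * yab[1] + b)
  kinetic_params("cooperative", k1 = k1, k2 = k2, w = w, b = b, q = q,
                 x0 = x0)
}

#' @keywords internal
#' @noRd
plogis_safe <- function(z) 1 / (1 + exp(-pmin(pmax(z, -500), 500)))

#' Simulate target-gene expression series
#'
#' Forward-simulates each gene's kinetic model on the configured grid and
#' applies multiplicative log-normal noise: value * exp(N(0, noise_sd)).
#'
#' @param config a [sim_config()].
#' @param params_list named list of [kinetic_params()], one per gene; if
#'   `NULL`, `n_genes[kind]` parameter sets per model kind are drawn
#'   automatically (gene ids `constant_1`, `direct_1`, ...).
#' @param regulators list with `regulator` and `cofactor` profiles, as from
#'   [make_regulator_profiles()].
#' @return list: `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame of gene_id, model_kind and generating parameters).
#' @export
simulate_targets <- function(config, params_list = NULL,
                             regulators = make_regulator_profiles(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(params_list)) {
    params_list <- list()
    for (kind in names(config$n_genes)) {
      n <- config$n_genes[[kind]]
      if (n > 0) for (i in seq_len(n))
        params_list[[sprintf("%s_%d", kind, i)]] <-
          draw_params(kind, i, config, regulators)
    }
  }
  if (is.null(names(params_list)) || anyDuplicated(names(params_list)))
    stopf("params_list must have unique names")
  tg <- config$time_grid
  rows <- matrix(NA_real_, nrow = length(params_list), ncol = length(tg))
  truth <- vector("list", length(params_list))
  for (i in seq_along(params_list)) {
    p <- params_list[[i]]
    stopifnot(inherits(p, "kinetic_params"))
    regs <- switch(p$model_kind, constant = list(),
                   direct = list(regulators$regulator),
                   cooperative = list(regulators$regulator,
                                      regulators$cofactor))
    clean <- simulate_kinetics(p, regs, tg)
    if (config$noise_sd > 0) {
      set.seed(derive_seed(config$seed, "noise", names(params_list)[i]))
      clean <- clean * exp(rnorm(length(clean), 0, config$noise_sd))
    }
    rows[i, ] <- clean
    truth[[i]] <- data.frame(gene_id = names(params_list)[i],
                             model_kind = p$model_kind,
                             k1 = p$k1, k2 = p$k2,
                             w = p$w %||% NA_real_, b = p$b %||% NA_real_,
                             q = p$q %||% NA_real_, x0 = p$x0,
                             stringsAsFactors = FALSE)
  }
  list(matrix = expression_matrix(rows, names(params_list), tg),
       truth = do.call(rbind, truth))
}
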