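#' Configuration for model fitting and classification
#'
#' Controls the simulated-annealing search, the goodness-of-fit acceptance
#' rule, the improvement tiers for complex-vs-direct comparison, the
#' "no control" weight threshold, and the permutation count of the
#' false-positive estimate.
#'
#' The acceptance rule is scale-free: a fit is accepted iff
#' rmse <= epsilon * mean(|target|). epsilon defaults to 0.2 (a model is
#' "good enough" when its typical residual is below 20% of the target's
#' mean absolute level).
#'
#' @param epsilon fit-acceptance factor in (0, 1).
#' @param improvement_thresholds two increasing values in (0, 1); a
#'   cooperative fit beats a direct fit by tier `ge10`/`ge20` when
#'   1 - rmse_coop/rmse_direct reaches them.
#' @param w_zero threshold below which |w| counts as "no control".
#' @param n_randomizations permutations used by
#'   [estimate_false_positive_rate()].
#' @param n_steps annealing steps per restart.
#' @param n_restarts independent annealing restarts (best fit kept).
#' @param t_init,t_final initial and final temperature of the geometric
#'   cooling schedule, in units of scaled cost (rmse / mean|target|).
#' @param seed integer base seed; every (gene, model, restart) gets its own
#'   derived stream, so results are reproducible and order-independent.
#' @param reltol,abstol ODE integrator tolerances used during fitting.
#' @return A `fit_config` object.
#' @export
fit_config <- function(epsilon = 0.2, improvement_thresholds = c(0.10, 0.20),
                       w_zero = 1e-4, n_randomizations = 20,
                       n_steps = 1200, n_restarts = 4,
                       t_init = 0.5, t_final = 1e-3, seed = 1L,
                       reltol = 1e-5, abstol = 1e-8) {
  assert_scalar_num(epsilon, "epsilon", lo = 1e-12, hi = 1 - 1e-12)
  if (length(improvement_thresholds) != 2 ||
      any(improvement_thresholds <= 0) || any(improvement_thresholds >= 1) ||
      diff(improvement_thresholds) <= 0)
    stopf("improvement_thresholds must be two increasing values in (0,1)")
  if (n_restarts < 1) stopf("n_restarts must be >= 1")
  structure(list(epsilon = epsilon,
                 improvement_thresholds = improvement_thresholds,
                 w_zero = w_zero, n_randomizations = n_randomizations,
                 n_steps = as.integer(n_steps),
                 n_restarts = as.integer(n_restarts),
                 t_init = t_init, t_final = t_final,
                 seed = as.integer(seed), reltol = reltol, abstol = abstol),
            class = "fit_config")
}

#' Root-mean-square error between two equal-length series
#' @param simulated,observed numeric vectors of equal length >= 1.
#' @return sqrt(mean((simulated - observed)^2)).
#' @export
rmse <- function(simulated, observed) {
  if (length(simulated) != length(observed) || length(simulated) < 1)
    stopf("rmse: series must have equal length >= 1")
  sqrt(mean((simulated - observed)^2))
}

#' Default parameter bounds, scale-aware
#'
#' k1 in \[0, 10 max(target)\]; k2 in \[0, 10\]/h; w in +/- 100/max(reg);
#' b in \[-100, 100\]; q in \[0, 100 max(regs)\]. Generous boxes that adapt
#' to the data scale; override via the `bounds` argument of [fit_model()].
#' @keywords internal
#' @noRd
default_bounds <- function(model_kind, target_values, reg_max) {
  tmax <- max(abs(target_values), 1e-8)
  lower <- c(k1 = 0, k2 = 0)
  upper <- c(k1 = 10 * tmax, k2 = 10)
  if (model_kind %in% c("direct", "cooperative")) {
    wcap <- 100 / max(reg_max, 1e-8)
    lower <- c(lower, w = -wcap, b = -100)
    upper <- c(upper, w = wcap, b = 100)
  }
  if (model_kind == "cooperative") {
    lower <- c(lower, q = 0)
    upper <- c(upper, q = 100 * max(reg_max, 1e-8))
  }
  list(lower = lower, upper = upper)
}

#' @keywords internal
#' @noRd
target_scale <- function(values) mean(abs(values))

#' @keywords internal
#' @noRd
params_from_vector <- function(model_kind, par, x0) {
  switch(model_kind,
    constant = kinetic_params("constant", k1 = par[1], k2 = par[2], x0 = x0),
    direct = kinetic_params("direct", k1 = par[1], k2 = par[2], w = par[3],
                            b = par[4], x0 = x0),
    cooperative = kinetic_params("cooperative", k1 = par[1], k2 = par[2],
                                 w = par[3], b = par[4], q = par[5], x0 = x0))
}

#' Fit one kinetic model to one target series
#'
#' Maximum a-posteriori estimation under a uniform prior over the bound box
#' and Gaussian residuals, i.e. bounded rmse minimization, by simulated
#' annealing with geometric cooling and restarts. The initial level x0 is
#' pinned to the target's value at the first time point (not optimized).
#' A fit is `accepted` iff rmse <= epsilon * mean(|target|).
#'
#' @param model_kind "constant", "direct" or "cooperative".
#' @param target a `smoothed_profile` (sampled at `times`) or a numeric
#'   vector of target values at `times`.
#' @param regulators list of regulator `smoothed_profile`s matching the
#'   model kind (0/1/2).
#' @param times the observation grid the residuals are evaluated on.
#' @param cfg a [fit_config()].
#' @param gene_id label used for the per-gene RNG stream.
#' @param bounds optional list(lower, upper) overriding the defaults.
#' @return A `fit_result`: list with `gene_id`, `model_kind`, `params`
#'   ([kinetic_params()]), `rmse`, `scale`, `accepted`, `no_control`
#'   (accepted direct/cooperative fit with |w| below `w_zero`).
#' @export
fit_model <- function(model_kind = c("constant", "direct", "cooperative"),
                      target, regulators = list(), times,
                      cfg = fit_config(), gene_id = "gene",
                      bounds = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(cfg, "fit_config"))
  if (inherits(regulators, "smoothed_profile")) regulators <- list(regulators)
  need <- n_regulators(model_kind)
  if (length(regulators) != need)
    stopf("%s model needs %d regulator(s)", model_kind, need)
  tv <- if (inherits(target, "smoothed_profile"))
    profile_values(target, times) else as.numeric(target)
  if (length(tv) != length(times)) stopf("target/times length mismatch")

  x0 <- tv[1]
  scale <- target_scale(tv)
  # degenerate flat target: the constant model solves it exactly
  if (diff(range(tv)) < 1e-12 * max(1, abs(tv[1]))) {
    par <- switch(model_kind, constant = c(tv[1], 1),
                  direct = c(2 * tv[1], 1, 0, 0),
                  cooperative = c(2 * tv[1], 1, 0, 0, 1))
    params <- params_from_vector(model_kind, par, x0)
    return(structure(list(gene_id = gene_id, model_kind = model_kind,
                          params = params, rmse = 0, scale = scale,
                          accepted = TRUE, no_control = model_kind != "constant"),
                     class = "fit_result"))
  }

  fine <- if (need > 0) profile_fine_grid(regulators[[1]]) else
    list(t = numeric(0), v = numeric(0))
  rB <- if (need == 2) profile_values(regulators[[2]], fine$t, clip = TRUE)
        else numeric(0)
  reg_max <- if (need > 0) max(c(fine$v, rB), 1e-8) else 1
  if (is.null(bounds)) bounds <- default_bounds(model_kind, tv, reg_max)
  if (length(bounds$lower) != length(bounds$upper) ||
      length(bounds$lower) == 0 || any(bounds$upper < bounds$lower))
    stopf("invalid bounds")

  seeds <- vapply(seq_len(cfg$n_restarts), function(r)
    derive_seed(cfg$seed, gene_id, model_kind, r), integer(1))
  kind_code <- model_kind_code(model_kind)
  lower <- as.numeric(bounds$lower)
  upper <- as.numeric(bounds$upper)
  # q is a scale parameter spanning decades: search it on log10 scale
  # (lower bound 0 is represented by a floor of 1e-6 * regulator scale,
  # where the complex is indistinguishable from the q -> 0 limit)
  q_log <- model_kind == "cooperative"
  if (q_log) {
    qfloor <- 1e-6 * reg_max
    lower[5] <- log10(max(lower[5], qfloor))
    upper[5] <- log10(max(upper[5], qfloor * 10))
  }
  # two informed starts ahead of the random restarts: the sigmoid is only
  # responsive on the narrow ridge |w y + b| ~ few units, which a uniform
  # draw over the generous default box almost never hits
  inits <- NULL
  if (model_kind != "constant") {
    yv <- if (model_kind == "cooperative")
      complex_concentration(fine$v, rB, stats::median(fine$v)) else fine$v
    ybar <- mean(yv)
    yspan <- max(diff(range(yv)), 1e-8)
    mk_init <- function(w0) {
      base <- c(2 * scale * 0.5, 0.5, w0, -w0 * ybar)
      if (model_kind == "cooperative")
        base <- c(base, log10(max(0.05 * reg_max, 1e-10)))
      base
    }
    inits <- cbind(mk_init(6 / yspan), mk_init(-6 / yspan))
  }
  res <- cpp_fit_anneal(kind_code, as.numeric(times), tv,
                        x0, fine$t, fine$v, rB, lower, upper,
                        cfg$n_steps, cfg$t_init, cfg$t_final, seeds,
                        cfg$reltol, cfg$abstol, q_log, inits)
  # local polish: bounded quasi-Newton from the annealing optimum and from
  # the informed starts; the annealer explores the box, L-BFGS-B converges
  # the last decimal places
  costf <- function(p)
    cpp_fit_cost(kind_code, p, as.numeric(times), tv, x0, fine$t, fine$v,
                 rB, cfg$reltol, cfg$abstol, q_log)
  starts <- cbind(res$par, inits)
  for (s in seq_len(ncol(starts))) {
    p0 <- pmin(pmax(starts[, s], lower), upper)
    polished <- tryCatch(
      stats::optim(p0, costf, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(polished) && polished$value < res$rmse) {
      res$par <- polished$par
      res$rmse <- polished$value
    }
  }
  par <- res$par
  if (q_log) par[5] <- 10^par[5]
  names(par) <- names(bounds$lower)
  params <- params_from_vector(model_kind, par, x0)
  accepted <- res$rmse <= cfg$epsilon * scale
  no_control <- accepted && model_kind != "constant" &&
    abs(params$w) < cfg$w_zero
  structure(list(gene_id = gene_id, model_kind = model_kind, params = params,
                 rmse = res$rmse, scale = scale, accepted = accepted,
                 no_control = no_control),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s / %s: rmse=%.4g (scale %.4g) %s\n", x$gene_id,
              x$model_kind, x$rmse, x$scale,
              if (x$accepted) "ACCEPTED" else "rejected"))
  invisible(x)
}

#' Classify one gene through the model cascade
#'
#' Models of increasing complexity are tried in order; a gene only proceeds
#' to a more complex model when the simpler one does not fit well enough:
#' \enumerate{
#'   \item constant model accepted -> `constitutive`;
#'   \item otherwise both the direct and the cooperative model are fitted;
#'     direct accepted -> `regulated`, with an improvement tier
#'     1 - rmse_coop/rmse_direct (when the cooperative fit is also
#'     accepted) cut at the configured thresholds (`ge10`, `ge20`);
#'   \item only the cooperative model accepted -> `complex_only`;
#'   \item nothing accepted -> `not_modeled`.
#' }
#'
#' @param target `smoothed_profile` or numeric values at `times`.
#' @param regulator sigma-factor `smoothed_profile`.
#' @param cofactor cofactor `smoothed_profile`.
#' @param times observation grid.
#' @param cfg a [fit_config()].
#' @param gene_id label.
#' @return A `gene_classification`: `gene_id`, `category`, `improvement`
#'   (NA unless both direct and cooperative fits accepted), `tier`
#'   ("none", "ge10", "ge20"), and the underlying `fits` list.
#' @export
classify_gene <- function(target, regulator, cofactor, times,
                          cfg = fit_config(), gene_id = "gene") {
  fits <- list()
  fits$constant <- fit_model("constant", target, list(), times, cfg, gene_id)
  improvement <- NA_real_
  tier <- "none"
  if (fits$constant$accepted) {
    category <- "constitutive"
  } else {
    fits$direct <- fit_model("direct", target, list(regulator), times, cfg,
                             gene_id)
    fits$cooperative <- fit_model("cooperative", target,
                                  list(regulator, cofactor), times, cfg,
                                  gene_id)
    if (fits$direct$accepted) {
      category <- "regulated"
      if (fits$cooperative$accepted && fits$direct$rmse > 0) {
        improvement <- 1 - fits$cooperative$rmse / fits$direct$rmse
        th <- cfg$improvement_thresholds
        tier <- if (improvement >= th[2]) "ge20"
                else if (improvement >= th[1]) "ge10" else "none"
      }
    } else if (fits$cooperative$accepted) {
      category <- "complex_only"
    } else {
      category <- "not_modeled"
    }
  }
  structure(list(gene_id = gene_id, category = category,
                 improvement = improvement, tier = tier, fits = fits),
            class = "gene_classification")
}

#' Classify every gene of an expression matrix
#'
#' Smooths each row, runs [classify_gene()], and returns one row per gene.
#'
#' @param m an [expression_matrix()] of target genes.
#' @param regulator,cofactor `smoothed_profile`s spanning `m$times`.
#' @param cfg a [fit_config()].
#' @param n_anchors anchors for target smoothing.
#' @param verbose log per-gene progress to standard error.
#' @return data.frame: gene_id, category, improvement, tier, and rmse /
#'   accepted columns per attempted model.
#' @export
classify_genes <- function(m, regulator, cofactor, cfg = fit_config(),
                           n_anchors = 4, verbose = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  rows <- lapply(seq_along(m$gene_ids), function(i) {
    gid <- m$gene_ids[i]
    if (verbose) message(sprintf("[classify] %s (%d/%d)", gid, i,
                                 length(m$gene_ids)))
    prof <- smooth_profile(m$values[i, ], m$times, n_anchors = n_anchors,
                           gene_id = gid)
    cl <- classify_gene(prof, regulator, cofactor, m$times, cfg, gid)
    get_rmse <- function(k) if (is.null(cl$fits[[k]])) NA_real_ else
      cl$fits[[k]]$rmse
    data.frame(gene_id = gid, category = cl$category,
               improvement = cl$improvement, tier = cl$tier,
               rmse_constant = get_rmse("constant"),
               rmse_direct = get_rmse("direct"),
               rmse_cooperative = get_rmse("cooperative"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Permutation-based false-positive estimate
#'
#' The regulator's raw observed values are permuted uniformly at random
#' over the time points (preserving the marginal distribution),
#' re-smoothed, and the direct model is fitted to every target against the
#' shuffled regulator. Repeating this `n_randomizations` times yields, per
#' replicate, the fraction of targets whose fit passes the acceptance rule
#' and the fraction that passes with |w| >= w_zero (weights below w_zero
#' indicate "no control" and are excluded from the false-positive count).
#'
#' @param targets list of `smoothed_profile`s or an [expression_matrix()]
#'   (rows smoothed internally with 4 anchors).
#' @param regulator_values raw regulator series at `times` (pre-smoothing).
#' @param times observation grid.
#' @param cfg a [fit_config()]; uses `n_randomizations`, `w_zero`, `seed`.
#' @return list with `fraction_accepted`, `fpr` (accepted with
#'   |w| >= w_zero), and a per-replicate data.frame `detail`.
#' @export
estimate_false_positive_rate <- function(targets, regulator_values, times,
                                         cfg = fit_config()) {
  if (inherits(targets, "expression_matrix")) {
    m <- targets
    targets <- lapply(seq_along(m$gene_ids), function(i)
      smooth_profile(m$values[i, ], m$times, gene_id = m$gene_ids[i]))
  }
  if (length(targets) < 1) stopf("need at least one target")
  if (length(regulator_values) != length(times))
    stopf("regulator_values/times length mismatch")
  tv <- lapply(targets, function(p)
    if (inherits(p, "smoothed_profile")) profile_values(p, times) else
      as.numeric(p))
  ids <- vapply(seq_along(targets), function(i) {
    g <- if (inherits(targets[[i]], "smoothed_profile"))
      targets[[i]]$gene_id else NA_character_
    if (is.na(g)) paste0("target_", i) else g
  }, character(1))

  detail <- lapply(seq_len(cfg$n_randomizations), function(rep_i) {
    perm_seed <- derive_seed(cfg$seed, "fpr_perm", rep_i)
    set.seed(perm_seed)
    shuffled <- sample(regulator_values)
    reg_prof <- smooth_profile(shuffled, times,
                               gene_id = sprintf("perm_%d", rep_i))
    rep_cfg <- cfg
    rep_cfg$seed <- derive_seed(cfg$seed, "fpr_fit", rep_i)
    acc <- logical(length(tv))
    acc_w <- logical(length(tv))
    for (i in seq_along(tv)) {
      fr <- fit_model("direct", tv[[i]], list(reg_prof), times, rep_cfg,
                      gene_id = ids[i])
      acc[i] <- fr$accepted
      acc_w[i] <- fr$accepted && abs(fr$params$w) >= cfg$w_zero
    }
    data.frame(replicate = rep_i, fraction_accepted = mean(acc),
               fraction_accepted_w = mean(acc_w))
  })
  detail <- do.call(rbind, detail)
  list(fraction_accepted = mean(detail$fraction_accepted),
       fpr = mean(detail$fraction_accepted_w),
       detail = detail)
}
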