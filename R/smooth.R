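#' Least-squares cubic-spline smoothing of one expression series
#'
#' Unreplicated expression time courses are noisy; the kinetic models are
#' fitted against a smooth trend rather than the raw points. The trend is a
#' least-squares piecewise cubic spline whose pieces are delimited by
#' `n_anchors` anchor points spaced evenly across the observed span (the
#' two outer anchors sit on the span ends; the inner ones become interior
#' knots of a cubic B-spline basis). The curve is C2-continuous and is never
#' extrapolated outside the observed span.
#'
#' @param values numeric observations.
#' @param times sampling times (hours), strictly increasing, same length.
#' @param n_anchors number of anchor points (>= 2); the default 4 gives a
#'   three-piece cubic. Requires `length(values) >= n_anchors + 2`.
#' @param gene_id optional label carried along.
#' @return A `smoothed_profile` object: evaluable via [profile_values()],
#'   with fields `gene_id`, `t_range`, `anchors`, `knots`, `coef`.
#' @export
smooth_profile <- function(values, times, n_anchors = 4, gene_id = NA_character_) {
  if (length(values) != length(times)) stopf("values/times length mismatch")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (n_anchors < 2) stopf("n_anchors must be >= 2")
  if (length(values) < n_anchors + 2)
    stopf("need >= %d observations for %d anchors, got %d", n_anchors + 2,
          n_anchors, length(values))
  if (anyNA(values) || any(!is.finite(values))) stopf("non-finite values")
  boundary <- range(times)
  anchors <- seq(boundary[1], boundary[2], length.out = n_anchors)
  knots <- if (n_anchors > 2) anchors[-c(1L, n_anchors)] else numeric(0)
  basis <- splines::bs(times, knots = knots, degree = 3L, intercept = TRUE,
                       Boundary.knots = boundary)
  fit <- stats::lm.fit(basis, values)
  structure(list(gene_id = gene_id, t_range = boundary, anchors = anchors,
                 knots = knots, coef = fit$coefficients,
                 n_obs = length(values)),
            class = "smoothed_profile")
}

#' Evaluate a smoothed profile
#'
#' @param profile a `smoothed_profile`.
#' @param t evaluation times; must lie inside the profile's fitted span
#'   (no extrapolation).
#' @param clip if `TRUE`, negative curve values are truncated to 0. Used
#'   wherever the curve stands in for a concentration (regulator inputs to
#'   the kinetic models); residual computations use the unclipped curve.
#' @return numeric vector of curve values.
#' @export
profile_values <- function(profile, t, clip = FALSE) {
  stopifnot(inherits(profile, "smoothed_profile"))
  tol <- 1e-9 * max(1, abs(profile$t_range))
  if (any(t < profile$t_range[1] - tol) || any(t > profile$t_range[2] + tol))
    stopf("evaluation outside fitted span [%g, %g]", profile$t_range[1],
          profile$t_range[2])
  t <- pmin(pmax(t, profile$t_range[1]), profile$t_range[2])
  basis <- splines::bs(t, knots = profile$knots, degree = 3L,
                       intercept = TRUE, Boundary.knots = profile$t_range)
  v <- drop(basis %*% profile$coef)
  if (clip) v <- pmax(v, 0)
  v
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat(sprintf(
    "<smoothed_profile> %s: [%g, %g] h, %d anchors, fitted on %d points\n",
    x$gene_id, x$t_range[1], x$t_range[2], length(x$anchors), x$n_obs))
  invisible(x)
}

#' Build a smoothed_profile directly from a function (exact sampling)
#'
#' Convenience for constructing regulator profiles with known shape: the
#' function is sampled densely and splined with enough anchors to make the
#' representation error negligible.
#' @keywords internal
#' @noRd
profile_from_function <- function(f, t_range, n_anchors = 12,
                                  gene_id = NA_character_) {
  tt <- seq(t_range[1], t_range[2], length.out = 20 * n_anchors)
  smooth_profile(f(tt), tt, n_anchors = n_anchors, gene_id = gene_id)
}

#' Sample a profile on a dense grid for the compiled ODE core
#'
#' The integrator interpolates regulator concentrations linearly on this
#' grid; 25 points per hour keeps the interpolation error far below the
#' solver tolerance for spline-smooth inputs.
#' @keywords internal
#' @noRd
profile_fine_grid <- function(profile, per_hour = 25) {
  span <- profile$t_range
  n <- max(50L, ceiling((span[2] - span[1]) * per_hour))
  tt <- seq(span[1], span[2], length.out = n)
  list(t = tt, v = profile_values(profile, tt, clip = TRUE))
}
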