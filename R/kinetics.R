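#' Kinetic parameter set for the transcription models
#'
#' Three models of mRNA accumulation x(t) are supported:
#' \describe{
#'   \item{constant}{dx/dt = k1 - k2 x; synthesis independent of any
#'     regulator.}
#'   \item{direct}{dx/dt = k1 / (1 + exp(-(w y + b))) - k2 x, with y the
#'     regulator (sigma factor) concentration profile.}
#'   \item{cooperative}{as `direct`, but y is the concentration of the
#'     equilibrium sigma-factor/cofactor complex, computed from the two
#'     constituent profiles and an equilibrium constant q
#'     (see [complex_concentration()]).}
#' }
#'
#' @param model_kind one of "constant", "direct", "cooperative".
#' @param k1 maximal synthesis rate (expression units per hour, >= 0).
#' @param k2 mRNA decay rate constant (1/h, >= 0).
#' @param w regulatory weight (per regulator unit; direct/cooperative).
#' @param b bias of the sigmoid (dimensionless; direct/cooperative).
#' @param q equilibrium constant of the complex (regulator units, >= 0;
#'   cooperative only).
#' @param x0 initial target level at the first sampled time.
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(model_kind = c("constant", "direct", "cooperative"),
                           k1, k2, w = NULL, b = NULL, q = NULL, x0 = 0) {
  model_kind <- match.arg(model_kind)
  assert_scalar_num(k1, "k1", lo = 0)
  assert_scalar_num(k2, "k2", lo = 0)
  assert_scalar_num(x0, "x0")
  p <- list(model_kind = model_kind, k1 = k1, k2 = k2, x0 = x0)
  if (model_kind %in% c("direct", "cooperative")) {
    if (is.null(w) || is.null(b)) stopf("%s model requires w and b", model_kind)
    assert_scalar_num(w, "w")
    assert_scalar_num(b, "b")
    p$w <- w
    p$b <- b
  } else if (!is.null(w) || !is.null(b) || !is.null(q)) {
    stopf("constant model takes no w/b/q")
  }
  if (model_kind == "cooperative") {
    if (is.null(q)) stopf("cooperative model requires q")
    assert_scalar_num(q, "q", lo = 0)
    p$q <- q
  } else if (!is.null(q)) {
    stopf("q is only meaningful for the cooperative model")
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  extras <- setdiff(names(x), c("model_kind"))
  cat(sprintf("<kinetic_params> %s: %s\n", x$model_kind,
              paste(sprintf("%s=%.4g", extras,
                            unlist(x[extras])), collapse = ", ")))
  invisible(x)
}

#' Equilibrium concentration of a two-protein complex
#'
#' For total constituent concentrations yA, yB and dissociation-style
#' equilibrium constant q (q = yA_free * yB_free / yAB), the complex
#' concentration is the smaller root of
#' y^2 - (yA + yB + q) y + yA yB = 0.
#' It interpolates between min(yA, yB) as q -> 0 (tight binding) and 0 as
#' q -> Inf (no binding). The implementation uses the rationalized root
#' 2 yA yB / (S + sqrt(S^2 - 4 yA yB)), S = yA + yB + q, which stays
#' accurate when q dwarfs the concentrations; the textbook
#' (S - sqrt(...)) / 2 form cancels catastrophically there.
#'
#' @param yA,yB total constituent concentrations (>= 0); recycled.
#' @param q equilibrium constant (>= 0); recycled.
#' @return Complex concentration(s), guaranteed within \[0, min(yA, yB)\].
#' @export
complex_concentration <- function(yA, yB, q) {
  if (any(!is.finite(yA)) || any(!is.finite(yB)) || any(!is.finite(q)))
    stopf("complex_concentration: inputs must be finite")
  if (any(yA < 0) || any(yB < 0) || any(q < 0))
    stopf("complex_concentration: negative input")
  cpp_complex_concentration(as.numeric(yA), as.numeric(yB), as.numeric(q))
}

#' @keywords internal
#' @noRd
model_kind_code <- function(model_kind) {
  match(model_kind, c("constant", "direct", "cooperative")) - 1L
}

#' @keywords internal
#' @noRd
n_regulators <- function(model_kind) {
  c(constant = 0L, direct = 1L, cooperative = 2L)[[model_kind]]
}

#' Forward-simulate a kinetic model
#'
#' Integrates the model ODE from x(times\[1\]) = x0 with an adaptive
#' embedded Runge-Kutta scheme and returns the solution at the requested
#' times. Regulator profiles are evaluated (negative values clipped to 0,
#' as concentrations) on a dense internal grid.
#'
#' @param params a [kinetic_params()].
#' @param regulators list of `smoothed_profile`s: none for "constant", one
#'   for "direct", two (sigma factor, cofactor) for "cooperative".
#' @param times strictly increasing output times, inside every regulator's
#'   fitted span.
#' @param reltol,abstol local error tolerances of the integrator.
#' @return Numeric vector of x(t) at `times`.
#' @export
simulate_kinetics <- function(params, regulators = list(), times,
                              reltol = 1e-6, abstol = 1e-9) {
  stopifnot(inherits(params, "kinetic_params"))
  if (inherits(regulators, "smoothed_profile")) regulators <- list(regulators)
  need <- n_regulators(params$model_kind)
  if (length(regulators) != need)
    stopf("%s model needs %d regulator(s), got %d", params$model_kind, need,
          length(regulators))
  if (length(times) < 1 || any(diff(times) <= 0))
    stopf("times must be strictly increasing")
  for (r in regulators) {
    if (!inherits(r, "smoothed_profile")) stopf("regulators must be smoothed_profile")
    if (min(times) < r$t_range[1] - 1e-9 || max(times) > r$t_range[2] + 1e-9)
      stopf("times outside regulator domain [%g, %g]", r$t_range[1],
            r$t_range[2])
  }
  fine <- if (need > 0) profile_fine_grid(regulators[[1]]) else
    list(t = numeric(0), v = numeric(0))
  rB <- if (need == 2) profile_values(regulators[[2]], fine$t, clip = TRUE)
        else numeric(0)
  par <- c(params$k1, params$k2, params$w %||% 0, params$b %||% 0,
           params$q %||% 0)
  cpp_simulate(model_kind_code(params$model_kind), par, params$x0,
               as.numeric(times), fine$t, fine$v, rB, reltol, abstol)
}
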