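#' Periodic linearization of the forced model at extinction
#'
#' Linearizes the seasonally forced system at the trivial (extinction)
#' solution and splits it into a nonnegative recruitment matrix `F(t)`
#' (new eggs: single nonzero row with `(1-eta) phi(T(t))` in the
#' solitarious-adult column and `(1-eta) psi phi(T(t))` in the
#' gregarious-adult column) and a transfer matrix `V(t)` (stage outflows
#' `c1(T)..c5(T)` on the diagonal, hatching, fledging and phase-exchange
#' couplings off it, so that `-V(t)` is cooperative). Both are periodic
#' with the forcing period `365/omega` days.
#'
#' @param thermal a [build_thermal_param_set()] object.
#' @param forcing a [temperature_forcing()] object.
#' @param constants named constants `theta`, `beta_1`, `beta_2`, `psi`,
#'   `eta`, `K`; baseline values when omitted.
#' @return object of class `periodic_linearization`: list with functions
#'   `Fmat(t)`, `Vmat(t)` and the `period` in days.
#' @export
periodic_linearization <- function(thermal, forcing, constants = NULL) {
  stopifnot(inherits(thermal, "thermal_param_set"),
            inherits(forcing, "temperature_forcing"))
  if (is.null(constants)) {
    bp <- locust_params()
    constants <- bp[c("theta", "beta_1", "beta_2", "psi", "eta", "K")]
  }
  cst <- as.list(constants)
  params_at <- function(t) {
    rates <- eval_thermal_rates(thermal, seasonal_temperature(forcing, t))
    locust_params(c(as.list(rates),
                    cst[c("theta", "beta_1", "beta_2", "psi", "eta", "K")]))
  }
  structure(list(
    Fmat = function(t) ngm_matrices(params_at(t))$R,
    Vmat = function(t) ngm_matrices(params_at(t))$V,
    params_at = params_at,
    period = forcing_period(forcing)
  ), class = "periodic_linearization")
}

#' Spectral radius of the lambda-scaled monodromy matrix
#'
#' Integrates the matrix system `dW/dt = (-V(t) + F(t)/lambda) W` from
#' `W(0) = I` over one forcing period and returns the spectral radius of
#' `W(period)`. As a function of `lambda > 0` this spectral radius is
#' continuous and nonincreasing, and the value of `lambda` at which it
#' crosses 1 is the basic offspring ratio of the periodic system.
#'
#' @param lin a [periodic_linearization()].
#' @param lambda positive scaling of the recruitment term.
#' @param rtol,atol integration tolerances (column-wise adaptive
#'   integration of the 25 matrix entries).
#' @return spectral radius (dimensionless).
#' @export
monodromy_spectral_radius <- function(lin, lambda = 1,
                                      rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(lin, "periodic_linearization"))
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  deriv <- function(t, w, parms) {
    W <- matrix(w, 5, 5)
    A <- -lin$Vmat(t) + lin$Fmat(t) / lambda
    list(as.vector(A %*% W))
  }
  sol <- deSolve::ode(y = as.vector(diag(5)), times = c(0, lin$period),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("monodromy integration failed")
  W <- matrix(unclass(sol)[2, -1], 5, 5)
  max(abs(eigen(W, only.values = TRUE)$values))
}

#' Basic offspring ratio of the seasonally forced system
#'
#' The periodic-environment analogue of the basic offspring number: the
#' spectral radius of the next-generation operator on periodic functions,
#' computed as the unique `lambda` for which the monodromy of the scaled
#' linear system `dW/dt = (-V(t) + F(t)/lambda) W` has spectral radius 1
#' (bracketed root finding). With zero-amplitude forcing it coincides with
#' the autonomous basic offspring number; the sign of `N0_omega - 1`
#' matches the Floquet stability of the unscaled linearization.
#'
#' @param lin a [periodic_linearization()].
#' @param bracket search interval for `lambda`, default `c(1e-6, 1e3)`.
#' @param tol root-finding tolerance, default 1e-6 (relative).
#' @param rtol,atol integration tolerances passed to
#'   [monodromy_spectral_radius()].
#' @return `N0_omega` (dimensionless); 0 when recruitment is identically
#'   zero.
#' @export
periodic_offspring_ratio <- function(lin, bracket = c(1e-6, 1e3),
                                     tol = 1e-6, rtol = 1e-10,
                                     atol = 1e-12) {
  stopifnot(inherits(lin, "periodic_linearization"))
  tgrid <- seq(0, lin$period, length.out = 25)
  fmax <- max(vapply(tgrid, function(t) max(lin$Fmat(t)), numeric(1)))
  if (fmax == 0) {
    rho0 <- monodromy_spectral_radius(lin, lambda = 1, rtol = rtol,
                                      atol = atol)
    if (rho0 >= 1) stop("zero recruitment but non-decaying transfer")
    return(0)
  }
  f <- function(lam)
    monodromy_spectral_radius(lin, lam, rtol = rtol, atol = atol) - 1
  # expand outward from lambda = 1: evaluating far below the root would
  # overflow the monodromy (growth ~ exp(F * period / lambda))
  lo <- hi <- 1
  flo <- fhi <- f(1)
  while (fhi > 0 && hi < bracket[2]) {
    hi <- min(hi * 4, bracket[2]); fhi <- f(hi)
  }
  while (flo < 0 && lo > bracket[1]) {
    lo <- max(lo / 4, bracket[1]); flo <- f(lo)
  }
  if (flo < fhi - 1e-12)
    stop("spectral radius is not decreasing over the bracket")
  if (flo < 0 || fhi > 0)
    stop(sprintf(
      "bracket [%g, %g] does not straddle the root (rho-1: %.3g, %.3g)",
      bracket[1], bracket[2], flo, fhi))
  root <- stats::uniroot(f, interval = c(lo, hi), f.lower = flo,
                         f.upper = fhi, tol = tol, check.conv = TRUE)
  root$root
}
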