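#' Generate a synthetic temperature-rate table from a known curve
#'
#' Draws noisy samples of a thermal response curve on a temperature grid,
#' standing in for unpublished temperature-versus-rate source data. Noise
#' is additive Gaussian, truncated at zero (rates cannot be negative).
#'
#' @param curve a [thermal_curve()] giving the generating truth.
#' @param temperatures temperature grid (degC), nonempty.
#' @param noise_sd Gaussian noise standard deviation in rate units, >= 0.
#' @param seed integer seed (mandatory; no hidden global randomness).
#' @return data.frame with columns `T_celsius`, `rate_per_day`.
#' @examples
#' tr <- fitted_thermal_curve("sigma")
#' tab <- generate_fixture_table(tr, seq(16, 42, by = 2), 0.005, seed = 1)
#' @export
generate_fixture_table <- function(curve, temperatures, noise_sd = 0, seed) {
  if (length(temperatures) == 0L) stop("empty temperature grid")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (missing(seed)) stop("an explicit seed is required")
  truth <- eval_thermal(curve, temperatures)
  noise <- withr::with_seed(seed, stats::rnorm(length(truth), 0, noise_sd))
  if (noise_sd == 0) noise <- rep(0, length(truth))
  data.frame(T_celsius = temperatures,
             rate_per_day = pmax(truth + noise, 0))
}

default_fit_setup <- function(family) {
  switch(family,
    gaussian = list(
      lower = c(Emax = 1e-8, Topt = 0, Tw = 0.5),
      upper = c(Emax = 50, Topt = 50, Tw = 30)),
    allahyari = list(
      lower = c(P = 1e-8, n = 1e-3, m = 1e-3, Tmin = 0, Tmax = 35),
      upper = c(P = 5, n = 10, m = 10, Tmin = 25, Tmax = 60)),
    mortality_window = list(
      lower = c(M = 1e-6, Q = 0.1, Tmin = 0, Tmax = 35),
      upper = c(M = 2, Q = 10, Tmin = 25, Tmax = 60)),
    stop("unsupported family for fitting: ", family)
  )
}

# Starting values read off the data: lethal bounds bracket the support of
# the observed nonzero rates, the scale matches the observed maximum.
data_driven_start <- function(table, family, lo, hi) {
  Tn <- table$T_celsius
  r <- table$rate_per_day
  p0 <- (lo + hi) / 2
  span <- diff(range(Tn))
  pos <- r > 0.05 * max(r)
  if (family == "gaussian") {
    p0["Emax"] <- max(r)
    p0["Topt"] <- Tn[which.max(r)]
    p0["Tw"] <- max(span / 4, 1)
  } else if (family == "allahyari") {
    p0["Tmin"] <- min(Tn[pos]) - 0.05 * span
    p0["Tmax"] <- max(Tn[pos]) + 0.05 * span
    p0["n"] <- 1.5
    p0["m"] <- 0.8
    shape <- allahyari_rate(Tn, 1, p0["n"], p0["m"], p0["Tmin"],
                            p0["Tmax"])
    p0["P"] <- max(r) / max(shape, 1e-8)
  } else if (family == "mortality_window") {
    interior <- r < 0.5 * max(r)
    p0["M"] <- 1 - min(r)
    p0["Q"] <- 2
    if (any(interior)) {
      p0["Tmin"] <- min(Tn[interior]) - 0.02 * span
      p0["Tmax"] <- max(Tn[interior]) + 0.02 * span
    }
  }
  p0
}

#' Fit a thermal response curve by bounded nonlinear least squares
#'
#' Estimates curve parameters from a two-column temperature-rate table by
#' minimizing the residual sum of squares in rate space, using
#' Levenberg-Marquardt with box constraints
#' ([minpack.lm::nls.lm()]). Any subset of parameters may be held fixed
#' (e.g. the falling-limb exponent `m = 0.5`, as in the published
#' egg-hatching and hopper-development fits).
#'
#' @param table data.frame with columns `T_celsius` and `rate_per_day`.
#' @param family `"gaussian"`, `"allahyari"` or `"mortality_window"`.
#' @param fixed named numeric vector of parameters to hold fixed.
#' @param lower,upper named bounds for the free parameters (defaults per
#'   family; see Details of the methods vignette).
#' @param start named initial guess; default mid-bounds.
#' @return list of class `thermal_fit` with elements `par` (full parameter
#'   vector including fixed entries), `free`, `fixed`, `sse`, `converged`,
#'   `family`, `message`, `fitted`.
#' @examples
#' truth <- fitted_thermal_curve("sigma")
#' tab <- generate_fixture_table(truth, seq(16, 42, by = 1), 0, seed = 1)
#' fit <- fit_thermal_curve(tab, "allahyari", fixed = c(m = 0.5))
#' @export
fit_thermal_curve <- function(table, family, fixed = NULL,
                              lower = NULL, upper = NULL, start = NULL) {
  stopifnot(all(c("T_celsius", "rate_per_day") %in% names(table)))
  setup <- default_fit_setup(family)
  all_names <- names(setup$lower)
  fixed <- if (is.null(fixed)) numeric(0) else fixed
  free_names <- setdiff(all_names, names(fixed))
  if (nrow(table) < length(free_names) + 1L)
    stop("need at least ", length(free_names) + 1L, " data points")

  lo <- setup$lower; hi <- setup$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  p0 <- data_driven_start(table, family, lo, hi)
  if (!is.null(start)) p0[names(start)] <- start
  p0 <- pmin(pmax(p0, lo), hi)

  assemble <- function(free) {
    full <- c(free, fixed)[all_names]
    names(full) <- all_names
    full
  }
  predict_rate <- function(full, T) {
    switch(family,
      gaussian  = gaussian_fecundity(T, full["Emax"], full["Topt"],
                                     full["Tw"]),
      allahyari = allahyari_rate(T, full["P"], full["n"], full["m"],
                                 full["Tmin"], full["Tmax"]),
      mortality_window = mortality_window(T, full["M"], full["Q"],
                                          full["Tmin"], full["Tmax"])
    )
  }
  resid_fn <- function(free) {
    names(free) <- free_names
    predict_rate(assemble(free), table$T_celsius) - table$rate_per_day
  }
  # small multistart around the data-driven guess guards against local
  # minima of the unimodal-curve objective
  starts <- list(p0[free_names])
  for (fac in c(0.6, 1.5)) {
    alt <- p0
    if ("n" %in% names(alt)) alt["n"] <- alt["n"] * fac
    if ("P" %in% names(alt)) alt["P"] <- alt["P"] * fac
    if ("Q" %in% names(alt)) alt["Q"] <- alt["Q"] * fac
    if ("Tw" %in% names(alt)) alt["Tw"] <- alt["Tw"] * fac
    starts <- c(starts, list(pmin(pmax(alt[free_names], lo[free_names]),
                                  hi[free_names])))
  }
  fit <- NULL
  for (s in starts) {
    cand <- minpack.lm::nls.lm(
      par = s, lower = lo[free_names], upper = hi[free_names],
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
  }
  free <- fit$par
  names(free) <- free_names
  full <- assemble(free)
  res <- predict_rate(full, table$T_celsius) - table$rate_per_day
  converged <- fit$info %in% 1:4
  out <- list(par = full, free = free, fixed = fixed,
              sse = sum(res^2), converged = converged,
              family = family, message = fit$message,
              fitted = predict_rate(full, table$T_celsius))
  class(out) <- "thermal_fit"
  if (!converged)
    warning("nonlinear least squares did not converge: ", fit$message)
  out
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf("Thermal curve fit (%s), SSE = %.3g, converged = %s\n",
              x$family, x$sse, x$converged))
  print(signif(x$par, 6))
  invisible(x)
}
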