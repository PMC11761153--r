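state_names <- c("E", "H", "B", "S", "G")

as_stage_state <- function(x) {
  if (!is.numeric(x) || length(x) != 5L)
    stop("a stage state has five components (E, H, B, S, G)")
  x <- as.numeric(x)
  names(x) <- state_names
  x
}

#' Right-hand side of the autonomous locust model
#'
#' Derivatives of the five compartments (eggs E, solitarious hoppers H,
#' gregarious bands B, solitarious adults S, gregarious swarms G) under
#' constant vital rates:
#' \deqn{E' = (1-\eta)\phi(1 - E/K)(S + \psi G) - (\sigma + \mu_e)E}
#' \deqn{H' = \theta\sigma E - (\gamma_h + \mu_h)H}
#' \deqn{B' = (1-\theta)\sigma E - (\gamma_b + \mu_b)B}
#' \deqn{S' = \gamma_h H + \beta_2 G - (\beta_1 + \mu_s)S}
#' \deqn{G' = \gamma_b B + \beta_1 S - (\beta_2 + \mu_g)G}
#'
#' @param state numeric vector (E, H, B, S, G), densities per m^2.
#' @param params a [locust_params()] set.
#' @return named derivative vector, m^-2 day^-1.
#' @export
rhs_autonomous <- function(state, params) {
  s <- as_stage_state(state)
  p <- as.list(unclass(params))
  with(c(p, as.list(s)), {
    c(E = (1 - eta) * phi * (1 - E / K) * (S + psi * G) -
        (sigma + mu_e) * E,
      H = theta * sigma * E - (gamma_h + mu_h) * H,
      B = (1 - theta) * sigma * E - (gamma_b + mu_b) * B,
      S = gamma_h * H + beta_2 * G - (beta_1 + mu_s) * S,
      G = gamma_b * B + beta_1 * S - (beta_2 + mu_g) * G)
  })
}

#' Right-hand side of the seasonally forced locust model
#'
#' Evaluates the seasonal temperature at time `t`, then every
#' temperature-dependent rate from the thermal set, and applies the same
#' stage-structure equations as [rhs_autonomous()]. With an all-constant
#' thermal set the result is identical to the autonomous right-hand side
#' at any time.
#'
#' @param t time in days.
#' @param state numeric vector (E, H, B, S, G).
#' @param thermal a [build_thermal_param_set()] object.
#' @param forcing a [temperature_forcing()] object.
#' @param constants named vector/list with the temperature-independent
#'   constants `theta`, `beta_1`, `beta_2`, `psi`, `eta`, `K`.
#' @return named derivative vector.
#' @export
rhs_nonautonomous <- function(t, state, thermal, forcing, constants) {
  Tt <- seasonal_temperature(forcing, t)
  rates <- eval_thermal_rates(thermal, Tt)
  cst <- as.list(constants)
  p <- locust_params(c(as.list(rates), cst[c("theta", "beta_1", "beta_2",
                                             "psi", "eta", "K")]))
  rhs_autonomous(state, p)
}

#' Integrate the locust model
#'
#' Adaptive Runge-Kutta integration (Dormand-Prince 4(5) by default, the
#' classical `ode45` pair) of either the autonomous or the seasonally
#' forced system.
#'
#' @param initial initial state (E, H, B, S, G), all >= 0.
#' @param model either a [locust_params()] object (autonomous run) or a
#'   list `list(thermal = , forcing = , constants = )` for a forced run
#'   (`constants` defaults to the baseline values of the six
#'   temperature-independent parameters when omitted).
#' @param times output time grid in days (increasing).
#' @param method [deSolve::ode()] method, default `"ode45"`.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param neg_tol negativity guard: components within `-neg_tol` of zero
#'   (relative to the problem scale, i.e. multiplied by
#'   `max(1, max(initial))`) are solver rounding noise and are clipped to
#'   0; anything more negative raises an integration error.
#' @return a `locust_trajectory`: data.frame with columns `t_days`, the
#'   five compartments, total `N`, and `T_celsius` for forced runs;
#'   solver settings in attribute `"metadata"`.
#' @examples
#' p <- locust_params(phi = 25, mu_h = 0.25, mu_b = 0.3)
#' tr <- simulate_locusts(c(1000, 0, 0, 10, 10), p, times = seq(0, 200, 5))
#' @export
simulate_locusts <- function(initial, model, times = seq(0, 365, by = 1),
                             method = "ode45", rtol = 1e-8, atol = 1e-10,
                             neg_tol = 1e-9) {
  y0 <- as_stage_state(initial)
  if (any(y0 < 0)) stop("initial state must be nonnegative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  autonomous <- inherits(model, "locust_params")
  if (autonomous) {
    fn <- function(t, y, parms) list(rhs_autonomous(y, model))
  } else {
    stopifnot(is.list(model), !is.null(model$thermal),
              !is.null(model$forcing))
    cst <- model$constants
    if (is.null(cst)) {
      bp <- locust_params()
      cst <- bp[c("theta", "beta_1", "beta_2", "psi", "eta", "K")]
    }
    fn <- function(t, y, parms)
      list(rhs_nonautonomous(t, y, model$thermal, model$forcing, cst))
  }
  sol <- deSolve::ode(y = y0, times = times, func = fn, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  attrs <- attributes(sol)
  if (!is.null(attrs$istate) && attrs$istate[1] < 0)
    stop("ODE integration failed (istate = ", attrs$istate[1], ")")
  mat <- unclass(sol)
  states <- mat[, state_names, drop = FALSE]
  worst <- min(states)
  neg_tol <- neg_tol * max(1, max(y0))
  if (worst < -neg_tol)
    stop(sprintf(
      "negative component beyond tolerance (min = %.3e at t = %.2f)",
      worst, mat[which(states == worst, arr.ind = TRUE)[1], "time"]))
  states[states < 0] <- 0
  out <- data.frame(t_days = mat[, "time"], states)
  out$N <- rowSums(states)
  if (!autonomous)
    out$T_celsius <- seasonal_temperature(model$forcing, out$t_days)
  attr(out, "metadata") <- list(
    model = if (autonomous) "autonomous" else "nonautonomous",
    method = method, rtol = rtol, atol = atol, initial = y0)
  class(out) <- c("locust_trajectory", "data.frame")
  out
}

#' Write a trajectory to CSV
#'
#' @param trajectory a `locust_trajectory`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
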