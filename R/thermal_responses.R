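#' Gaussian temperature-dependent fecundity
#'
#' Egg oviposition rate as a Gaussian function of temperature,
#' `Emax * exp(-((T - Topt)/Tw)^2)`: maximal at the optimal temperature
#' `Topt` and symmetric about it.
#'
#' @param T temperature in degC (vectorized).
#' @param Emax maximum fecundity (eggs female^-1 day^-1), >= 0.
#' @param Topt optimal temperature (degC).
#' @param Tw width of the optimal range (degC), > 0.
#' @return fecundity rate(s), eggs female^-1 day^-1.
#' @examples
#' gaussian_fecundity(30, Emax = 4.4444, Topt = 30, Tw = 8)  # 4.4444
#' @export
gaussian_fecundity <- function(T, Emax, Topt, Tw) {
  if (Emax < 0) stop("Emax must be nonnegative")
  if (Tw <= 0) stop("Tw must be positive")
  Emax * exp(-((T - Topt) / Tw)^2)
}

#' Allahyari unimodal development-rate curve
#'
#' Development (or hatching) rate between lethal temperature limits,
#' `P * x^n * (1 - x^m)` with `x = (T - Tmin)/(Tmax - Tmin)`, clamped to
#' zero outside `(Tmin, Tmax)`. The curve rises from zero at `Tmin` to a
#' single interior maximum and falls back to zero at `Tmax`.
#'
#' @param T temperature in degC (vectorized).
#' @param P scale factor (day^-1), >= 0.
#' @param n rising-limb exponent, > 0.
#' @param m falling-limb exponent, > 0.
#' @param Tmin,Tmax minimum and maximum lethal temperatures (degC),
#'   `Tmin < Tmax`.
#' @return nonnegative rate(s) in day^-1.
#' @examples
#' # fitted egg-hatching parameters
#' allahyari_rate(30, P = 0.2658, n = 1.5818, m = 0.5,
#'                Tmin = 15.1, Tmax = 42.9187)
#' @export
allahyari_rate <- function(T, P, n, m, Tmin, Tmax) {
  if (P < 0) stop("P must be nonnegative")
  if (n <= 0 || m <= 0) stop("exponents must be positive")
  if (Tmin >= Tmax) stop("Tmin must be below Tmax")
  x <- (T - Tmin) / (Tmax - Tmin)
  r <- ifelse(x <= 0 | x >= 1, 0, P * x^n * (1 - x^m))
  pmax(r, 0)
}

#' Lethal-window mortality curve
#'
#' U-shaped temperature-dependent mortality between lower and upper lethal
#' temperatures. The `"normalized"` variant (default) is
#' `clamp(1 - M * exp(1 - (1 + exp((Tmin - T)/Q)) * (1 + exp((T - Tmax)/Q))), 0, 1)`:
#' approximately `1 - M` in the window interior, rising to 1 beyond either
#' lethal bound, pointwise non-increasing in `M` before clamping. The
#' `"as_printed"` variant evaluates
#' `1 - M * exp((1 + exp((Tmin - T)/Q)) * (1 + exp((T - Tmax)/Q)))`
#' verbatim; its values can leave \[0, 1\] and are returned unclamped with
#' attribute `"out_of_range"` flagging them.
#'
#' @param T temperature in degC (vectorized).
#' @param M magnitude constant (dimensionless).
#' @param Q steepness (degC), > 0.
#' @param Tmin,Tmax lower and upper lethal temperatures, `Tmin < Tmax`.
#' @param variant `"normalized"` (default) or `"as_printed"`.
#' @return mortality rate(s); a fraction in \[0, 1\] for the normalized
#'   variant.
#' @examples
#' mortality_window(25, M = 0.5, Q = 1.5, Tmin = 15, Tmax = 35)  # ~0.5
#' @export
mortality_window <- function(T, M, Q, Tmin, Tmax,
                             variant = c("normalized", "as_printed")) {
  variant <- match.arg(variant)
  if (Q <= 0) stop("Q must be positive")
  if (Tmin >= Tmax) stop("Tmin must be below Tmax")
  window <- (1 + exp((Tmin - T) / Q)) * (1 + exp((T - Tmax) / Q))
  if (variant == "as_printed") {
    out <- 1 - M * exp(window)
    attr(out, "out_of_range") <- any(out < 0 | out > 1)
    return(out)
  }
  pmin(pmax(1 - M * exp(1 - window), 0), 1)
}

# Interior minimum of the normalized window with M = 1 (used for anchoring
# the adult curve at its baseline): minimized where the window product is
# smallest, found numerically inside (Tmin, Tmax).
window_interior_min <- function(Q, Tmin, Tmax) {
  opt <- stats::optimize(function(T) {
    mortality_window(T, M = 1, Q = Q, Tmin = Tmin, Tmax = Tmax)
  }, interval = c(Tmin, Tmax))
  list(T = opt$minimum, value = opt$objective)
}

#' Adult mortality anchored at a baseline rate
#'
#' Temperature-dependent adult mortality with no published functional form:
#' a lethal-window shape rescaled so that its interior minimum equals the
#' published baseline daily mortality and its value saturates at 1 beyond
#' the lethal bounds, `baseline + (1 - baseline) * w(T)` where `w` is the
#' `M = 1` normalized window shifted to 0 at its interior minimum.
#'
#' @param T temperature in degC (vectorized).
#' @param baseline baseline adult mortality (day^-1), in (0, 1).
#' @param Q steepness (degC), default 2.
#' @param Tmin,Tmax lethal bounds (degC); defaults 20 and 40, the optimal
#'   adult activity range.
#' @return mortality rate(s) in day^-1, minimum equal to `baseline`.
#' @examples
#' adult_mortality(30, baseline = 0.0083)
#' @export
adult_mortality <- function(T, baseline, Q = 2, Tmin = 20, Tmax = 40) {
  if (!is.finite(baseline) || baseline <= 0 || baseline >= 1)
    stop("baseline must lie strictly in (0, 1)")
  g <- mortality_window(T, M = 1, Q = Q, Tmin = Tmin, Tmax = Tmax)
  gmin <- window_interior_min(Q, Tmin, Tmax)$value
  w <- pmin(pmax((g - gmin) / (1 - gmin), 0), 1)
  baseline + (1 - baseline) * w
}

# ---- thermal curve descriptors -------------------------------------------

curve_families <- c("constant", "gaussian", "allahyari",
                    "mortality_window", "anchored_window")

required_curve_args <- list(
  constant         = "value",
  gaussian         = c("Emax", "Topt", "Tw"),
  allahyari        = c("P", "n", "m", "Tmin", "Tmax"),
  mortality_window = c("M", "Q", "Tmin", "Tmax"),
  anchored_window  = c("baseline", "Q", "Tmin", "Tmax")
)

#' Describe one thermal response curve
#'
#' Builds a curve descriptor used inside a [thermal_param_set()]. Supported
#' families: `"constant"` (`value`), `"gaussian"` (`Emax`, `Topt`, `Tw`),
#' `"allahyari"` (`P`, `n`, `m`, `Tmin`, `Tmax`), `"mortality_window"`
#' (`M`, `Q`, `Tmin`, `Tmax`, optional `variant`) and `"anchored_window"`
#' (`baseline`, `Q`, `Tmin`, `Tmax`).
#'
#' @param family curve family name.
#' @param ... family parameters (see above).
#' @return an object of class `thermal_curve`.
#' @examples
#' thermal_curve("allahyari", P = 0.2658, n = 1.5818, m = 0.5,
#'               Tmin = 15.1, Tmax = 42.9187)
#' @export
thermal_curve <- function(family, ...) {
  if (!family %in% curve_families)
    stop("unknown curve family: ", family)
  pars <- list(...)
  need <- required_curve_args[[family]]
  miss <- setdiff(need, names(pars))
  if (length(miss))
    stop("curve family '", family, "' is missing parameter(s): ",
         paste(miss, collapse = ", "))
  structure(list(family = family, pars = pars), class = "thermal_curve")
}

#' Evaluate a thermal curve at given temperatures
#'
#' @param curve a [thermal_curve()] (a bare number is treated as constant).
#' @param T temperature(s) in degC.
#' @return rate(s) in day^-1.
#' @export
eval_thermal <- function(curve, T) {
  if (is.numeric(curve)) return(rep_len(curve, length(T)))
  stopifnot(inherits(curve, "thermal_curve"))
  p <- curve$pars
  switch(curve$family,
    constant  = rep_len(p$value, length(T)),
    gaussian  = gaussian_fecundity(T, p$Emax, p$Topt, p$Tw),
    allahyari = allahyari_rate(T, p$P, p$n, p$m, p$Tmin, p$Tmax),
    mortality_window = mortality_window(T, p$M, p$Q, p$Tmin, p$Tmax,
      variant = if (is.null(p$variant)) "normalized" else p$variant),
    anchored_window = adult_mortality(T, p$baseline, p$Q, p$Tmin, p$Tmax)
  )
}

#' @export
print.thermal_curve <- function(x, ...) {
  cat(sprintf("thermal_curve(%s): %s\n", x$family,
              paste(names(x$pars), unlist(x$pars), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

thermal_rate_symbols <- c("phi", "sigma", "gamma_h", "gamma_b",
                          "mu_e", "mu_h", "mu_b", "mu_s", "mu_g")

#' Fitted default curve for one temperature-dependent rate
#'
#' Convenience constructors for the published fitted response curves:
#' Gaussian fecundity (solitarious Emax 4.4444, gregarious 1.5556, Topt
#' 30 degC, Tw 8 degC), Allahyari egg hatching (P 0.2658, n 1.5818, m 0.5,
#' lethal limits 15.1 / 42.9187 degC), Allahyari hopper and band
#' development (P 0.1192, n 1.3176, m 0.5, limits 15 / 45.012 degC),
#' egg mortality windows (solitarious M 1.19, gregarious M 0.91, Q 1.5,
#' limits as for hatching), hopper mortality windows (M 0.1525
#' solitarious / 0.282 gregarious, Q 2, limits 15 / 35 degC), and
#' baseline-anchored adult mortality windows.
#'
#' @param symbol one of `"phi"`, `"sigma"`, `"gamma_h"`, `"gamma_b"`,
#'   `"mu_e"`, `"mu_h"`, `"mu_b"`, `"mu_s"`, `"mu_g"`.
#' @param phase `"solitarious"` or `"gregarious"`, for the rates that have
#'   phase-specific parameters (`phi`, `mu_e`); for `phi` the solitarious
#'   curve is the default since the model's single `phi(T)` is the
#'   solitarious rate modified by `psi` for swarms.
#' @return a [thermal_curve()].
#' @export
fitted_thermal_curve <- function(symbol,
                                 phase = c("solitarious", "gregarious")) {
  phase <- match.arg(phase)
  switch(symbol,
    phi = thermal_curve("gaussian",
      Emax = if (phase == "solitarious") 4.4444 else 1.5556,
      Topt = 30, Tw = 8),
    sigma = thermal_curve("allahyari", P = 0.2658, n = 1.5818, m = 0.5,
      Tmin = 15.1, Tmax = 42.9187),
    gamma_h = ,
    gamma_b = thermal_curve("allahyari", P = 0.1192, n = 1.3176, m = 0.5,
      Tmin = 15, Tmax = 45.012),
    mu_e = thermal_curve("mortality_window",
      M = if (phase == "solitarious") 1.19 else 0.91,
      Q = 1.5, Tmin = 15.1, Tmax = 42.9187),
    mu_h = thermal_curve("mortality_window", M = 0.1525, Q = 2,
      Tmin = 15, Tmax = 35),
    mu_b = thermal_curve("mortality_window", M = 0.282, Q = 2,
      Tmin = 15, Tmax = 35),
    mu_s = thermal_curve("anchored_window", baseline = 0.0083, Q = 2,
      Tmin = 20, Tmax = 40),
    mu_g = thermal_curve("anchored_window", baseline = 0.0111, Q = 2,
      Tmin = 20, Tmax = 40),
    stop("unknown rate symbol: ", symbol)
  )
}

#' Assemble the full set of temperature-dependent rates
#'
#' Combines the nine temperature-dependent rate symbols of the forced model
#' (`phi`, `sigma`, `gamma_h`, `gamma_b`, `mu_e`, `mu_h`, `mu_b`, `mu_s`,
#' `mu_g`) into one evaluable set. Each entry may be a bare number
#' (temperature-independent), a [thermal_curve()], or a list
#' `list(family = ..., <parameters>)`. Symbols left unspecified default to
#' the baseline constants from [locust_params()].
#'
#' @param config named list of curve specifications (may be empty).
#' @param params constants used for unspecified symbols; default baseline.
#' @return an object of class `thermal_param_set`.
#' @examples
#' # only the hatching rate varies with temperature:
#' ts <- build_thermal_param_set(list(sigma = fitted_thermal_curve("sigma")))
#' eval_thermal_rates(ts, 30)
#' @export
build_thermal_param_set <- function(config = list(),
                                    params = locust_params()) {
  bad <- setdiff(names(config), thermal_rate_symbols)
  if (length(bad))
    stop("unknown rate symbol(s) in thermal config: ",
         paste(bad, collapse = ", "))
  set <- lapply(thermal_rate_symbols, function(sym) {
    spec <- config[[sym]]
    if (is.null(spec))
      return(thermal_curve("constant", value = unname(params[[sym]])))
    if (inherits(spec, "thermal_curve")) return(spec)
    if (is.numeric(spec) && length(spec) == 1L)
      return(thermal_curve("constant", value = spec))
    if (is.list(spec) && !is.null(spec$family)) {
      fam <- spec$family
      args <- spec[setdiff(names(spec), "family")]
      return(do.call(thermal_curve, c(list(family = fam), args)))
    }
    stop("invalid curve specification for symbol '", sym, "'")
  })
  names(set) <- thermal_rate_symbols
  structure(set, class = "thermal_param_set")
}

#' Evaluate all temperature-dependent rates at a temperature
#'
#' @param set a [build_thermal_param_set()] object.
#' @param T a single temperature in degC.
#' @return named numeric vector of the nine rates (day^-1).
#' @export
eval_thermal_rates <- function(set, T) {
  stopifnot(inherits(set, "thermal_param_set"), length(T) == 1L)
  out <- vapply(set, eval_thermal, numeric(1), T = T)
  if (any(!is.finite(out)) || any(out < 0))
    stop("thermal rate evaluation must be finite and nonnegative")
  out
}

#' Sample a thermal curve on a temperature grid
#'
#' @param curve a [thermal_curve()].
#' @param temperatures grid of temperatures in degC.
#' @return data.frame with columns `T_celsius` and `rate_per_day`.
#' @export
sample_thermal_curve <- function(curve, temperatures) {
  data.frame(T_celsius = temperatures,
             rate_per_day = eval_thermal(curve, temperatures))
}
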