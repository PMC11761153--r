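#' Constant-parameter set of the autonomous locust model
#'
#' Builds the parameter vector of the stage-structured dual-phase model.
#' Defaults are the published baseline values; any subset can be overridden
#' by name. All rates are per day, densities per square metre.
#'
#' @param ... named overrides of the baseline values. Valid names:
#'   `phi` (egg oviposition rate, day^-1), `psi` (gregarious fecundity
#'   modification, dimensionless in \[0,1\]), `eta` (adult male ratio,
#'   dimensionless in \[0,1\]), `K` (egg carrying capacity, m^-2),
#'   `sigma` (egg hatching rate), `mu_e` (egg mortality), `theta`
#'   (proportion of hatchlings that become solitarious hoppers),
#'   `gamma_h`, `gamma_b` (solitarious hopper / band development rates),
#'   `mu_h`, `mu_b` (hopper / band mortality), `mu_s`, `mu_g`
#'   (solitarious / gregarious adult mortality), `beta_1` (gregarisation
#'   rate), `beta_2` (dissociation rate).
#' @param beta_unit unit in which `beta_1`, `beta_2` are given; `"per_day"`
#'   (default) or `"per_hour"` (values multiplied by 24).
#'
#' @return an object of class `locust_params`: a named numeric vector of the
#'   fifteen model constants.
#' @examples
#' p <- locust_params()                 # baseline
#' p9 <- locust_params(phi = 1.75)      # extinction scenario
#' @export
locust_params <- function(..., beta_unit = c("per_day", "per_hour")) {
  beta_unit <- match.arg(beta_unit)
  base <- c(
    phi = 3.556, psi = 0.35, eta = 0.483, K = 80000,
    sigma = 0.0714, mu_e = 0.33, theta = 0.65,
    gamma_h = 0.0263, gamma_b = 0.0243,
    mu_h = 0.7332, mu_b = 0.8575,
    mu_s = 0.0083, mu_g = 0.0111,
    beta_1 = 0.25, beta_2 = 0.25
  )
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    base[names(over)] <- vapply(over, as.numeric, numeric(1))
  }
  if (beta_unit == "per_hour") {
    base[c("beta_1", "beta_2")] <- 24 * base[c("beta_1", "beta_2")]
  }
  validate_locust_params(structure(base, class = "locust_params"))
}

validate_locust_params <- function(p) {
  if (any(!is.finite(p))) stop("non-finite parameter value")
  if (any(p < 0)) stop("parameters must be nonnegative")
  for (nm in c("psi", "eta", "theta"))
    if (p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  if (p[["K"]] <= 0) stop("K must be positive")
  p
}

#' @export
print.locust_params <- function(x, ...) {
  cat("Desert locust model parameters (rates per day):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Aggregate hopper/band mortality from an instar survival schedule
#'
#' Total stage mortality through a series of instars and moults, computed as
#' one minus the product of the per-instar survivals and the per-moult
#' survival raised to the number of moults.
#'
#' @param instar_mortalities per-instar mortality fractions in \[0,1\].
#' @param moult_mortality per-moult mortality fraction in \[0,1\].
#' @param n_moults number of moults (>= 0).
#' @return aggregate mortality fraction in \[0,1\].
#' @examples
#' # published band schedule: 70/20/10/10/10 % instar losses, 5 % per moult
#' aggregate_stage_mortality(c(0.7, 0.2, 0.1, 0.1, 0.1), 0.05, 4)  # 0.8575
#' @export
aggregate_stage_mortality <- function(instar_mortalities, moult_mortality,
                                      n_moults) {
  if (length(instar_mortalities) == 0L)
    stop("empty instar schedule")
  fr <- c(instar_mortalities, moult_mortality)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("mortality fractions must lie in [0, 1]")
  if (n_moults < 0) stop("n_moults must be >= 0")
  s_total <- (1 - moult_mortality)^n_moults * prod(1 - instar_mortalities)
  1 - s_total
}

#' Solitarious hopper mortality from band mortality
#'
#' Solitarious hoppers pass through one fewer moult stage than bands; the
#' published derivation scales the band mortality by one extra moult and
#' instar survival factor, `mu_b * 0.95 * 0.9`.
#'
#' @param mu_b band aggregate mortality fraction in \[0,1\].
#' @return solitarious hopper mortality fraction.
#' @examples
#' solitarious_hopper_mortality(0.8575)  # 0.7332
#' @export
solitarious_hopper_mortality <- function(mu_b) {
  if (!is.finite(mu_b) || mu_b < 0 || mu_b > 1)
    stop("mu_b must lie in [0, 1]")
  mu_b * 0.95 * 0.9
}

#' Daily fecundity rate from eggs per generation and lifespan
#'
#' @param eggs_per_generation eggs laid per female over a generation.
#' @param lifespan_months adult lifespan in months (30-day months).
#' @return fecundity rate in eggs female^-1 day^-1.
#' @examples
#' fecundity_from_lifespan(400, 3)  # 4.4444, solitarious upper bound
#' fecundity_from_lifespan(140, 5)  # 0.9333, gregarious lower bound
#' @export
fecundity_from_lifespan <- function(eggs_per_generation, lifespan_months) {
  if (eggs_per_generation < 0) stop("egg count must be nonnegative")
  if (!is.finite(lifespan_months) || lifespan_months <= 0)
    stop("lifespan must be positive")
  eggs_per_generation / (lifespan_months * 30)
}

#' Baseline parameter set with its life-history derivations cross-checked
#'
#' Recomputes the derived baseline entries (band and hopper mortality from
#' the instar schedule, the fecundity modification psi = 140/400, the egg
#' carrying capacity K = 160 eggs x 500 pods, the gregarious adult mortality
#' 1/90) from their primary life-history quantities and checks each against
#' the published value to four decimals before returning the baseline set.
#'
#' @return a `locust_params` baseline set, with attribute `"derivation"`:
#'   a data.frame of derived quantities, their recomputed full-precision
#'   values and the published rounded values.
#' @export
derive_baseline_params <- function() {
  mu_b_full <- aggregate_stage_mortality(c(0.7, 0.2, 0.1, 0.1, 0.1), 0.05, 4)
  mu_h_full <- solitarious_hopper_mortality(mu_b_full)
  der <- data.frame(
    quantity = c("mu_b", "mu_h", "psi", "K", "mu_g", "sigma",
                 "phi_sol_max", "phi_greg_max"),
    derived = c(mu_b_full, mu_h_full, 140 / 400, 160 * 500, 1 / 90, 1 / 14,
                fecundity_from_lifespan(400, 3),
                fecundity_from_lifespan(140, 3)),
    published = c(0.8575, 0.7332, 0.35, 80000, 0.0111, 0.0714,
                  4.4444, 1.5556)
  )
  ok <- abs(round(der$derived, 4) - der$published) < 5e-5 |
    abs(der$derived - der$published) / pmax(1, der$published) < 5e-5
  if (!all(ok))
    stop("derived baseline value disagrees with published value: ",
         paste(der$quantity[!ok], collapse = ", "))
  p <- locust_params()
  attr(p, "derivation") <- der
  p
}
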