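#' Seasonal mean-temperature forcing
#'
#' Cosine forcing of the daily mean temperature that drives every
#' temperature-dependent vital rate of the seasonally forced model.
#' Two variants are available:
#' \describe{
#'   \item{multiplicative}{`T(t) = T0 * (1 + T1 * cos(2*pi*(omega*t + kappa)/365))`,
#'     with `T1` a dimensionless relative amplitude.}
#'   \item{additive}{`T(t) = T0 + T1 * cos(2*pi*(omega*t + kappa)/365)`,
#'     with `T1` an amplitude in degrees Celsius.}
#' }
#' The signal is periodic with period `365/omega` days.
#'
#' @param T0 mean annual temperature (degC), > 0.
#' @param T1 amplitude (dimensionless for the multiplicative variant,
#'   degC for the additive one).
#' @param omega periodicity multiplier (cycles per 365 days), > 0.
#' @param kappa phase shift (days).
#' @param variant `"multiplicative"` (default) or `"additive"`.
#' @return an object of class `temperature_forcing`.
#' @examples
#' f <- temperature_forcing(T0 = 20, T1 = 0.1)
#' seasonal_temperature(f, 0)    # 22
#' @export
temperature_forcing <- function(T0, T1 = 0, omega = 1, kappa = 0,
                                variant = c("multiplicative", "additive")) {
  variant <- match.arg(variant)
  vals <- c(T0, T1, omega, kappa)
  if (any(!is.finite(vals))) stop("forcing parameters must be finite")
  if (T0 <= 0) stop("T0 must be positive")
  if (omega <= 0) stop("omega must be positive")
  structure(list(T0 = T0, T1 = T1, omega = omega, kappa = kappa,
                 variant = variant),
            class = "temperature_forcing")
}

#' Evaluate the seasonal temperature signal
#'
#' @param forcing a [temperature_forcing()] object.
#' @param t time in days (vectorized).
#' @return temperature(s) in degrees Celsius.
#' @export
seasonal_temperature <- function(forcing, t) {
  stopifnot(inherits(forcing, "temperature_forcing"))
  if (any(!is.finite(t))) stop("t must be finite")
  osc <- cos(2 * pi * (forcing$omega * t + forcing$kappa) / 365)
  out <- switch(forcing$variant,
    multiplicative = forcing$T0 * (1 + forcing$T1 * osc),
    additive       = forcing$T0 + forcing$T1 * osc
  )
  if (any(!is.finite(out))) stop("non-finite temperature value")
  out
}

#' Period of a temperature forcing, in days
#' @param forcing a [temperature_forcing()] object.
#' @return period `365/omega` in days.
#' @export
forcing_period <- function(forcing) {
  stopifnot(inherits(forcing, "temperature_forcing"))
  365 / forcing$omega
}

#' @export
print.temperature_forcing <- function(x, ...) {
  cat(sprintf(
    "Seasonal temperature forcing (%s): T0 = %g degC, T1 = %g, omega = %g, kappa = %g (period %g d)\n",
    x$variant, x$T0, x$T1, x$omega, x$kappa, 365 / x$omega))
  invisible(x)
}
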