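#' Parameter ranges for sensitivity analysis
#'
#' Published sampling ranges for the model constants; parameters without a
#' published range (`psi`, `mu_h`, `mu_b`) default to +/-20 % of their
#' baseline value and are flagged as assumed. Parameters given as a single
#' value are held fixed and excluded from sampling.
#'
#' @param ... named overrides: either `c(low, high)` ranges or single
#'   fixed values.
#' @return object of class `parameter_ranges`: data.frame with columns
#'   `parameter`, `low`, `high`, `fixed`, `assumed`.
#' @export
parameter_ranges <- function(...) {
  base <- locust_params()
  rng <- list(
    phi = c(0.933, 4.44), eta = c(0.302, 0.501), K = c(16000, 80000),
    sigma = c(0.0154, 0.1), mu_e = c(0.05, 0.65), theta = c(0, 1),
    gamma_h = c(0.0208, 0.0333), gamma_b = c(0.0175, 0.04),
    mu_s = c(0.0067, 0.0111), mu_g = c(0.0067, 0.0111),
    beta_1 = c(0.125, 0.25), beta_2 = c(0.125, 0.25),
    psi = 0.35 * c(0.8, 1.2), mu_h = 0.7332 * c(0.8, 1.2),
    mu_b = 0.8575 * c(0.8, 1.2)
  )
  assumed <- c("psi", "mu_h", "mu_b")
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  rng[names(over)] <- over
  out <- do.call(rbind, lapply(names(base), function(nm) {
    v <- rng[[nm]]
    if (is.null(v)) v <- unname(base[[nm]])
    if (length(v) == 1L)
      data.frame(parameter = nm, low = v, high = v, fixed = TRUE,
                 assumed = FALSE)
    else {
      if (v[1] >= v[2]) stop("invalid range for ", nm)
      data.frame(parameter = nm, low = v[1], high = v[2], fixed = FALSE,
                 assumed = nm %in% assumed)
    }
  }))
  structure(out, class = c("parameter_ranges", "data.frame"))
}

#' Latin hypercube sample of the parameter space
#'
#' Stratified uniform sample: each ranged parameter is divided into `n`
#' equal-probability bins with one draw per bin, permuted independently
#' across parameters ([lhs::randomLHS()]). Fixed parameters are replicated
#' at their value.
#'
#' @param ranges a [parameter_ranges()] object.
#' @param n number of samples, >= 2.
#' @param seed integer seed (mandatory).
#' @return data.frame of `n` rows, one column per model parameter.
#' @export
lhs_sample <- function(ranges, n, seed) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  if (n < 2) stop("n must be >= 2")
  if (missing(seed)) stop("an explicit seed is required")
  varying <- ranges[!ranges$fixed, ]
  cube <- withr::with_seed(seed, lhs::randomLHS(n, nrow(varying)))
  draws <- as.data.frame(
    sweep(sweep(cube, 2, varying$high - varying$low, `*`),
          2, varying$low, `+`))
  names(draws) <- varying$parameter
  for (i in which(ranges$fixed))
    draws[[ranges$parameter[i]]] <- ranges$low[i]
  draws[ranges$parameter]
}

#' Partial rank correlation coefficients
#'
#' For each sampled parameter, the correlation between (a) the residuals of
#' its ranks regressed on the ranks of all other parameters and (b) the
#' residuals of the output ranks regressed on the same covariates. Ranks
#' use average tie handling. Measures the monotone association between a
#' parameter and the output while adjusting for the other parameters.
#'
#' @param draws data.frame of parameter draws (constant columns are
#'   excluded from the design and receive `NA` coefficients).
#' @param outputs numeric response vector, one value per row of `draws`.
#' @param output_name label for the response, used in printing.
#' @return object of class `prcc_result`: data.frame with columns
#'   `parameter` and `prcc`, with attributes `n` and `output`.
#' @examples
#' rng <- parameter_ranges()
#' draws <- lhs_sample(rng, 200, seed = 42)
#' n0 <- apply(draws, 1, function(r) offspring_number(locust_params(
#'   as.list(r)))$N0)
#' prcc(draws, n0)
#' @export
prcc <- function(draws, outputs, output_name = "N0") {
  if (nrow(draws) != length(outputs))
    stop("outputs must have one value per draw")
  varying <- names(draws)[vapply(draws, function(x) stats::var(x) > 0,
                                 logical(1))]
  if (nrow(draws) < length(varying) + 3L)
    stop("need at least ", length(varying) + 3L, " rows")
  X <- apply(draws[varying], 2, rank)
  y <- rank(outputs)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L)
    stop("degenerate design: rank-deficient regressor matrix")
  coefs <- vapply(seq_along(varying), function(j) {
    Z <- cbind(1, X[, -j, drop = FALSE])
    rx <- stats::lsfit(Z, X[, j], intercept = FALSE)$residuals
    ry <- stats::lsfit(Z, y, intercept = FALSE)$residuals
    stats::cor(rx, ry)
  }, numeric(1))
  out <- data.frame(parameter = names(draws),
                    prcc = coefs[match(names(draws), varying)])
  attr(out, "n") <- nrow(draws)
  attr(out, "output") <- output_name
  class(out) <- c("prcc_result", "data.frame")
  out
}

#' PRCC of the basic offspring number over the published ranges
#'
#' Convenience driver: Latin hypercube sample of the published parameter
#' ranges, closed-form `N0` as the response, PRCC per parameter.
#'
#' @param n sample size, default 1000.
#' @param seed integer seed (mandatory).
#' @param ranges a [parameter_ranges()] object.
#' @return a [prcc()] result with attribute `"draws"` (the sample).
#' @export
prcc_offspring_number <- function(n = 1000, seed,
                                  ranges = parameter_ranges()) {
  draws <- lhs_sample(ranges, n, seed)
  n0 <- apply(draws, 1, function(r)
    offspring_number(locust_params(as.list(r)))$N0)
  res <- prcc(draws, n0, output_name = "N0")
  attr(res, "draws") <- draws
  res
}

#' @export
print.prcc_result <- function(x, ...) {
  cat(sprintf("PRCC against %s (n = %d):\n",
              attr(x, "output"), attr(x, "n")))
  df <- as.data.frame(x)
  df <- df[order(-abs(df$prcc)), ]
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}
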