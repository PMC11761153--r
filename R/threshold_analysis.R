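#' Stage rate aggregates c1..c5
#'
#' Total outflow rates of the five compartments:
#' `c1 = sigma + mu_e`, `c2 = gamma_h + mu_h`, `c3 = gamma_b + mu_b`,
#' `c4 = beta_1 + mu_s`, `c5 = beta_2 + mu_g`.
#'
#' @param params a [locust_params()] set.
#' @return named numeric vector `c1`..`c5` (day^-1).
#' @export
rate_aggregates <- function(params) {
  p <- as.list(unclass(params))
  with(p, c(c1 = sigma + mu_e, c2 = gamma_h + mu_h, c3 = gamma_b + mu_b,
            c4 = beta_1 + mu_s, c5 = beta_2 + mu_g))
}

#' Basic offspring number, closed form
#'
#' Expected number of female offspring produced by one female over her
#' lifetime, split into the solitarious and gregarious reproduction routes:
#' \deqn{N_{0S} = \frac{(1-\eta)\phi\,(\theta\sigma\gamma_h c_3 c_5 +
#'  (1-\theta)\sigma\gamma_b\beta_2 c_2)}{c_1 c_2 c_3 (c_4 c_5 -
#'  \beta_1\beta_2)}}
#' \deqn{N_{0G} = \frac{(1-\eta)\psi\phi\,((1-\theta)\sigma\gamma_b c_2 c_4
#'  + \theta\sigma\gamma_h\beta_1 c_3)}{c_1 c_2 c_3 (c_4 c_5 -
#'  \beta_1\beta_2)}}
#' and `N0 = N0S + N0G`. `N0` is linear in `phi` and in `1 - eta` and does
#' not depend on `K`. The threshold `N0 = 1` separates extinction from
#' persistence of the population.
#'
#' @param params a [locust_params()] set; requires
#'   `c4*c5 - beta_1*beta_2 > 0`.
#' @return object of class `offspring_numbers`: list with `N0S`, `N0G`,
#'   `N0` and the `aggregates`.
#' @examples
#' offspring_number(locust_params(phi = 1.75))
#' @export
offspring_number <- function(params) {
  p <- as.list(unclass(params))
  cc <- rate_aggregates(params)
  den_adult <- cc[["c4"]] * cc[["c5"]] - p$beta_1 * p$beta_2
  if (den_adult <= 0)
    stop("invalid adult balance: beta_1*beta_2 >= c4*c5 ",
         "(phase-exchange faster than total adult outflow)")
  den <- cc[["c1"]] * cc[["c2"]] * cc[["c3"]] * den_adult
  N0S <- (1 - p$eta) * p$phi *
    (p$theta * p$sigma * p$gamma_h * cc[["c3"]] * cc[["c5"]] +
       (1 - p$theta) * p$sigma * p$gamma_b * p$beta_2 * cc[["c2"]]) / den
  N0G <- (1 - p$eta) * p$psi * p$phi *
    ((1 - p$theta) * p$sigma * p$gamma_b * cc[["c2"]] * cc[["c4"]] +
       p$theta * p$sigma * p$gamma_h * p$beta_1 * cc[["c3"]]) / den
  structure(list(N0S = N0S, N0G = N0G, N0 = N0S + N0G, aggregates = cc),
            class = "offspring_numbers")
}

#' @export
print.offspring_numbers <- function(x, ...) {
  cat(sprintf("Basic offspring number N0 = %.6g (solitarious %.6g + gregarious %.6g)\n",
              x$N0, x$N0S, x$N0G))
  invisible(x)
}

ngm_matrices <- function(params) {
  p <- as.list(unclass(params))
  cc <- rate_aggregates(params)
  R <- matrix(0, 5, 5, dimnames = list(state_names, state_names))
  R[1, 4] <- (1 - p$eta) * p$phi
  R[1, 5] <- (1 - p$eta) * p$phi * p$psi
  V <- matrix(0, 5, 5, dimnames = list(state_names, state_names))
  diag(V) <- cc
  V[2, 1] <- -p$theta * p$sigma
  V[3, 1] <- -(1 - p$theta) * p$sigma
  V[4, 2] <- -p$gamma_h
  V[4, 5] <- -p$beta_2
  V[5, 3] <- -p$gamma_b
  V[5, 4] <- -p$beta_1
  list(R = R, V = V)
}

#' Basic offspring number via the next-generation matrix
#'
#' Independent route to `N0`: assembles the recruitment matrix `R` (new
#' eggs) and the transfer matrix `V` of the linearization at the extinction
#' equilibrium and returns the spectral radius of `R V^-1`. Serves as the
#' numerical oracle for the closed form of [offspring_number()].
#'
#' @param params a [locust_params()] set.
#' @return spectral radius of the next-generation matrix (dimensionless).
#' @export
offspring_number_ngm <- function(params) {
  m <- ngm_matrices(params)
  Vinv <- tryCatch(solve(m$V),
                   error = function(e) stop("transfer matrix V is singular"))
  max(abs(eigen(m$R %*% Vinv, only.values = TRUE)$values))
}

#' Critical egg-laying rate phi*
#'
#' The oviposition rate at which `N0 = 1`:
#' \deqn{\phi^* = \frac{c_1 c_2 c_3 (\mu_s c_5 + \beta_1\mu_g)}
#'  {(1-\eta)\sigma(\theta\gamma_h c_3(\beta_1\psi + c_5) +
#'   (1-\theta)\gamma_b c_2(\beta_2 + c_4\psi))}}
#' obtained by solving `N0 = 1` for `phi` (note `mu_s c5 + beta_1 mu_g`
#' equals `c4 c5 - beta_1 beta_2`). The identity `N0(phi = phi*) = 1` is
#' verified against the closed form at call time and a warning is raised
#' if it fails beyond 1e-8, so a silently wrong threshold cannot
#' propagate.
#'
#' @param params a [locust_params()] set with `sigma > 0`.
#' @return the critical rate (day^-1).
#' @export
phi_star <- function(params) {
  p <- as.list(unclass(params))
  cc <- rate_aggregates(params)
  if (p$sigma <= 0) stop("phi* undefined: sigma must be positive")
  den <- (1 - p$eta) * p$sigma *
    (p$theta * p$gamma_h * cc[["c3"]] * (p$beta_1 * p$psi + cc[["c5"]]) +
       (1 - p$theta) * p$gamma_b * cc[["c2"]] *
         (p$beta_2 + cc[["c4"]] * p$psi))
  if (den <= 0) stop("phi* undefined: zero denominator")
  ps <- cc[["c1"]] * cc[["c2"]] * cc[["c3"]] *
    (p$mu_s * cc[["c5"]] + p$beta_1 * p$mu_g) / den
  check <- offspring_number(locust_params(modifyList(p, list(phi = ps))))$N0
  if (abs(check - 1) > 1e-8)
    warning(sprintf("N0 at phi* deviates from 1 by %.3g", check - 1))
  ps
}

#' Nontrivial (persistence) equilibrium
#'
#' For `N0 > 1` the model has a positive equilibrium with
#' `E** = K (1 - 1/N0)`, `H** = theta sigma E**/c2`,
#' `B** = (1-theta) sigma E**/c3`, and adult densities solving the linear
#' adult balance `c4 S = gamma_h H + beta_2 G`,
#' `c5 G = gamma_b B + beta_1 S`. The returned state zeroes the autonomous
#' right-hand side to within 1e-9 K (checked).
#'
#' @param params a [locust_params()] set with `N0 > 1`.
#' @return named equilibrium state vector (E, H, B, S, G).
#' @export
nontrivial_equilibrium <- function(params) {
  p <- as.list(unclass(params))
  on <- offspring_number(params)
  if (on$N0 <= 1)
    stop(sprintf("no positive equilibrium: N0 = %.4g <= 1", on$N0))
  cc <- on$aggregates
  E <- p$K * (1 - 1 / on$N0)
  H <- p$theta * p$sigma * E / cc[["c2"]]
  B <- (1 - p$theta) * p$sigma * E / cc[["c3"]]
  A <- rbind(c(cc[["c4"]], -p$beta_2), c(-p$beta_1, cc[["c5"]]))
  sg <- solve(A, c(p$gamma_h * H, p$gamma_b * B))
  eq <- c(E = E, H = H, B = B, S = sg[1], G = sg[2])
  resid <- max(abs(rhs_autonomous(eq, params)))
  if (resid > 1e-9 * p$K)
    stop(sprintf("equilibrium residual %.3g exceeds 1e-9 K", resid))
  eq
}

#' Analytic Jacobian of the autonomous model
#'
#' @param params a [locust_params()] set.
#' @param state the state (E, H, B, S, G) at which to linearize.
#' @return 5x5 Jacobian matrix.
#' @export
locust_jacobian <- function(params, state) {
  s <- as_stage_state(state)
  p <- as.list(unclass(params))
  cc <- rate_aggregates(params)
  J <- matrix(0, 5, 5, dimnames = list(state_names, state_names))
  fec <- (1 - p$eta) * p$phi
  J[1, 1] <- -fec * (s[["S"]] + p$psi * s[["G"]]) / p$K - cc[["c1"]]
  J[1, 4] <- fec * (1 - s[["E"]] / p$K)
  J[1, 5] <- fec * p$psi * (1 - s[["E"]] / p$K)
  J[2, 1] <- p$theta * p$sigma;        J[2, 2] <- -cc[["c2"]]
  J[3, 1] <- (1 - p$theta) * p$sigma;  J[3, 3] <- -cc[["c3"]]
  J[4, 2] <- p$gamma_h; J[4, 4] <- -cc[["c4"]]; J[4, 5] <- p$beta_2
  J[5, 3] <- p$gamma_b; J[5, 4] <- p$beta_1;    J[5, 5] <- -cc[["c5"]]
  J
}

#' Local stability at an equilibrium
#'
#' Eigenvalues of the analytic Jacobian at a supplied equilibrium point and
#' a stability verdict (`stable` when the largest real part is below
#' -1e-9). For the origin the verdict is cross-checked against the
#' `N0`-versus-1 threshold rule.
#'
#' @param params a [locust_params()] set.
#' @param point an equilibrium state; its right-hand-side residual must be
#'   below `1e-6 * max(1, K)`.
#' @return list with `eigenvalues`, `max_re`, `stable`, `verdict`.
#' @export
stability_report <- function(params, point) {
  s <- as_stage_state(point)
  K <- unclass(params)[["K"]]
  resid <- max(abs(rhs_autonomous(s, params)))
  if (resid > 1e-6 * max(1, K))
    stop(sprintf("point is not an equilibrium (residual %.3g)", resid))
  ev <- eigen(locust_jacobian(params, s), only.values = TRUE)$values
  max_re <- max(Re(ev))
  stable <- max_re < -1e-9
  verdict <- if (stable) "locally asymptotically stable" else "unstable"
  if (all(s == 0)) {
    N0 <- offspring_number(params)$N0
    if (xor(stable, N0 < 1))
      warning(sprintf(
        "origin stability (%s) disagrees with N0 = %.4g threshold rule",
        verdict, N0))
  }
  list(eigenvalues = ev, max_re = max_re, stable = stable,
       verdict = verdict)
}

null_vector <- function(A) {
  sv <- svd(A)
  v <- sv$v[, ncol(A)]
  if (sv$d[ncol(A)] > 1e-6 * max(sv$d))
    stop("matrix has no (numerically) zero singular value")
  if (sv$d[ncol(A) - 1] < 1e-6 * max(sv$d))
    stop("zero eigenvalue is not simple: degenerate bifurcation")
  v
}

#' Transcritical bifurcation coefficients at phi = phi*
#'
#' Center-manifold (Castillo-Chavez and Song) analysis of the bifurcation
#' of the extinction equilibrium at the critical egg-laying rate. The right
#' (`u`) and left (`v`) null vectors of the Jacobian at `phi*` are computed
#' numerically (normalized so the fifth component equals 1) and the
#' coefficients
#' `a = -2 (1-eta) phi*/K * v1 u1 (u4 + psi u5)` and
#' `b = (1-eta) v1 (u4 + psi u5)`
#' are evaluated; `a` and `b` always carry opposite signs, fixed by the
#' sign of `v1`, which is also reported via the analytic rule
#' `sign((beta_2 mu_s - beta_1 mu_g)/(c5 - psi c4))` and cross-checked
#' against the numerical vector. `v1 > 0` (so `a < 0 < b`) gives a forward
#' (supercritical) bifurcation at `N0 = 1`.
#'
#' @param params a [locust_params()] set (its `phi` entry is replaced by
#'   `phi*` for the analysis).
#' @return object of class `bifurcation_report`: list with `phi_star`,
#'   `u`, `v`, `a`, `b`, `v1_sign`, `v1_sign_rule`, `classification`.
#' @export
bifurcation_coefficients <- function(params) {
  p <- as.list(unclass(params))
  ps <- suppressWarnings(phi_star(params))
  pstar <- locust_params(modifyList(p, list(phi = ps)))
  J <- locust_jacobian(pstar, rep(0, 5))
  u <- null_vector(J)
  v <- null_vector(t(J))
  u <- u / u[5]
  v <- v / v[5]
  cc <- rate_aggregates(pstar)
  rule_num <- p$beta_2 * p$mu_s - p$beta_1 * p$mu_g
  rule_den <- cc[["c5"]] - p$psi * cc[["c4"]]
  v1_rule <- sign(rule_num / rule_den)
  v1_num <- sign(v[1])
  if (abs(v[1]) > 1e-10 && v1_rule != 0 && v1_num != v1_rule)
    warning("numeric sign of v1 disagrees with the analytic sign rule")
  fac <- (1 - p$eta) * v[1] * (u[4] + p$psi * u[5])
  a <- -2 * ps / p$K * u[1] * fac
  b <- fac
  boundary <- abs(v[1]) <= 1e-10 || rule_num == 0
  classification <- if (boundary) {
    "degenerate (v1 = 0 boundary case)"
  } else if (v1_num > 0) {
    "forward bifurcation (a < 0, b > 0)"
  } else {
    "a > 0, b < 0: origin stabilizes above threshold, unstable positive branch"
  }
  structure(list(phi_star = ps, u = u, v = v, a = a, b = b,
                 v1_sign = v1_num, v1_sign_rule = v1_rule,
                 v1_boundary = boundary,
                 classification = classification),
            class = "bifurcation_report")
}

#' @export
print.bifurcation_report <- function(x, ...) {
  cat(sprintf("Bifurcation at phi* = %.6g: a = %.4g, b = %.4g (v1 sign %d)\n%s\n",
              x$phi_star, x$a, x$b, x$v1_sign, x$classification))
  invisible(x)
}
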