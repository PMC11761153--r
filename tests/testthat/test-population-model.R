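test_that("autonomous right-hand side matches the stage equations", {
  p <- locust_params()
  expect_equal(rhs_autonomous(rep(0, 5), p),
               c(E = 0, H = 0, B = 0, S = 0, G = 0))
  # eggs at carrying capacity, no adults: only outflow terms remain
  d <- rhs_autonomous(c(80000, 0, 0, 0, 0), p)
  expect_equal(unname(d["E"]), -(0.0714 + 0.33) * 80000)
  expect_equal(unname(d["H"]), 0.65 * 0.0714 * 80000)
  expect_equal(unname(d["B"]), 0.35 * 0.0714 * 80000)
  expect_equal(unname(d[c("S", "G")]), c(0, 0))
})

test_that("the positive equilibrium zeroes the right-hand side", {
  p <- locust_params(phi = 25, mu_h = 0.25, mu_b = 0.3)
  eq <- nontrivial_equilibrium(p)
  expect_lt(max(abs(rhs_autonomous(eq, p))), 1e-9 * 80000)
})

test_that("forced right-hand side reduces to the autonomous one for constants", {
  p <- locust_params(phi = 2.5)
  ts <- build_thermal_param_set(params = p)
  f <- temperature_forcing(30, 0.2, omega = 2, kappa = 30)
  cst <- p[c("theta", "beta_1", "beta_2", "psi", "eta", "K")]
  state <- c(5000, 800, 300, 120, 60)
  for (t in c(0, 57.5, 200))
    expect_equal(rhs_nonautonomous(t, state, ts, f, cst),
                 rhs_autonomous(state, p), tolerance = 1e-12)
})

test_that("forced right-hand side composes the thermal rates", {
  ts <- build_thermal_param_set(list(sigma = fitted_thermal_curve("sigma")))
  f <- temperature_forcing(30, 0)
  cst <- baseline_constants()
  d <- rhs_nonautonomous(0, c(1000, 0, 0, 0, 0), ts, f, cst)
  sigma30 <- allahyari_rate(30, 0.2658, 1.5818, 0.5, 15.1, 42.9187)
  expect_equal(unname(d["H"]), 0.65 * sigma30 * 1000)
  expect_equal(unname(d["E"]), -(sigma30 + 0.33) * 1000)
})

test_that("integration preserves the origin and nonnegativity", {
  p <- locust_params(phi = 1.75)
  tr0 <- simulate_locusts(rep(0, 5), p, seq(0, 365, 5))
  expect_true(all(as.matrix(tr0[, c("E", "H", "B", "S", "G")]) == 0))
  tr <- simulate_locusts(c(20000, 8000, 4000, 1600, 800), p,
                         seq(0, 2000, 20))
  expect_true(all(as.matrix(tr[, c("E", "H", "B", "S", "G")]) >= 0))
})

test_that("total population respects the analytic ultimate bound", {
  p <- locust_params(phi = 25, mu_h = 0.25, mu_b = 0.3)
  tr <- simulate_locusts(c(40000, 10000, 5000, 2000, 1000), p,
                         seq(0, 1500, 15))
  mu <- min(p[c("mu_e", "mu_h", "mu_b", "mu_s", "mu_g")])
  bound <- (1 - p[["eta"]]) * p[["phi"]] * 2 * p[["K"]] / mu
  expect_true(all(tr$N <= bound + 1e-6 * p[["K"]]))
})

test_that("constant thermal sets give the autonomous trajectory", {
  p <- locust_params(phi = 25, mu_h = 0.25, mu_b = 0.3)
  times <- seq(0, 200, 2)
  init <- c(1000, 100, 50, 20, 10)
  tra <- simulate_locusts(init, p, times)
  model <- list(thermal = build_thermal_param_set(params = p),
                forcing = temperature_forcing(25, 0.3, omega = 1),
                constants = p[c("theta", "beta_1", "beta_2", "psi",
                                "eta", "K")])
  trf <- simulate_locusts(init, model, times)
  diff <- abs(as.matrix(tra[, c("E", "H", "B", "S", "G")]) -
                as.matrix(trf[, c("E", "H", "B", "S", "G")]))
  expect_lt(max(diff), 1e-8 * p[["K"]])
  expect_true(all(trf$T_celsius == seasonal_temperature(model$forcing,
                                                        trf$t_days)))
})

test_that("supercritical forced dynamics settle onto a periodic orbit", {
  p <- locust_params(phi = 25, mu_h = 0.25, mu_b = 0.3)
  ts <- build_thermal_param_set(list(sigma = fitted_thermal_curve("sigma")),
                                params = p)
  f <- temperature_forcing(30, 5, omega = 2, variant = "additive")
  period <- forcing_period(f)
  times <- seq(0, 10 * period, by = period / 8)
  model <- list(thermal = ts, forcing = f,
                constants = p[c("theta", "beta_1", "beta_2", "psi",
                                "eta", "K")])
  tr <- simulate_locusts(c(2000, 500, 200, 100, 50), model, times)
  m <- as.matrix(tr[, c("E", "H", "B", "S", "G")])
  last <- m[(nrow(m) - 7):nrow(m), ]
  prev <- m[(nrow(m) - 15):(nrow(m) - 8), ]
  expect_lt(max(abs(last - prev) / pmax(abs(last), 1)), 1e-3)
})

test_that("invalid initial conditions and grids are rejected", {
  p <- locust_params()
  expect_error(simulate_locusts(c(-1, 0, 0, 0, 0), p), "nonnegative")
  expect_error(simulate_locusts(rep(1, 4), p), "five components")
  expect_error(simulate_locusts(rep(1, 5), p, times = c(0, 0, 1)),
               "increasing")
})
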