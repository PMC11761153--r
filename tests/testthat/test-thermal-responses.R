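test_that("Gaussian fecundity peaks at Topt with the stated width", {
  expect_equal(gaussian_fecundity(30, 4.4444, 30, 8), 4.4444)
  expect_equal(gaussian_fecundity(38, 2, 30, 8), 2 / exp(1))
  expect_equal(gaussian_fecundity(22, 2, 30, 8), 2 / exp(1))
  # one-sided hand evaluation: (46-30)/8 = 2, exponent 4
  expect_equal(gaussian_fecundity(46, 1.5556, 30, 8), 1.5556 * exp(-4))
  expect_equal(1.5556 * exp(-4), 0.0285, tolerance = 1e-3)
})

test_that("Gaussian fecundity is symmetric and decreasing away from Topt", {
  d <- seq(0.5, 20, by = 0.5)
  up <- gaussian_fecundity(30 + d, 3, 30, 8)
  dn <- gaussian_fecundity(30 - d, 3, 30, 8)
  expect_equal(up, dn)
  expect_true(all(diff(up) < 0))
})

test_that("Allahyari rate vanishes at the lethal bounds, matches hand oracle", {
  P <- 0.2658; n <- 1.5818; m <- 0.5; Tmin <- 15.1; Tmax <- 42.9187
  expect_equal(allahyari_rate(Tmin, P, n, m, Tmin, Tmax), 0)
  expect_equal(allahyari_rate(Tmax, P, n, m, Tmin, Tmax), 0)
  expect_equal(allahyari_rate(c(5, 50), P, n, m, Tmin, Tmax), c(0, 0))
  # independent scalar computation of x, x^n, x^m
  x <- (30 - Tmin) / (Tmax - Tmin)
  expect_equal(allahyari_rate(30, P, n, m, Tmin, Tmax),
               P * x^n * (1 - x^m))
  expect_equal(P * x^n * (1 - x^m), 0.0265, tolerance = 2e-3)
})

test_that("Allahyari curve has a unique interior maximum", {
  Tg <- seq(15, 45.012, length.out = 400)
  r <- allahyari_rate(Tg, 0.1192, 1.3176, 0.5, 15, 45.012)
  i <- which.max(r)
  expect_gt(i, 1); expect_lt(i, length(Tg))
  expect_true(all(diff(r[seq_len(i)]) >= 0))
  expect_true(all(diff(r[i:length(r)]) <= 0))
  expect_true(all(r >= 0))
})

test_that("normalized mortality window is U-shaped between lethal bounds", {
  # interior value ~ 1 - M
  expect_equal(mortality_window(25, 0.5, 1.5, 15, 35), 0.5,
               tolerance = 5e-3)
  # M > 1 clamps the interior to zero
  expect_equal(mortality_window(25, 1.19, 1.5, 15, 35), 0)
  # lower lethal bound: window product ~ 2
  expect_equal(mortality_window(15, 0.5, 1.5, 15, 35), 1 - 0.5 * exp(-1),
               tolerance = 2e-3)
  # U-shape: non-increasing then non-decreasing over the extended range
  Tg <- seq(15 - 5 * 1.5, 35 + 5 * 1.5, length.out = 300)
  v <- mortality_window(Tg, 0.5, 1.5, 15, 35)
  i <- which.min(v)
  expect_true(all(diff(v[seq_len(i)]) <= 1e-12))
  expect_true(all(diff(v[i:length(v)]) >= -1e-12))
  # pointwise non-increasing in M: gregarious eggs (M = 0.91) die at least
  # as fast as solitarious (M = 1.19) at every temperature
  Tg2 <- seq(5, 50, by = 0.5)
  greg <- mortality_window(Tg2, 0.91, 1.5, 15.1, 42.9187)
  sol <- mortality_window(Tg2, 1.19, 1.5, 15.1, 42.9187)
  expect_true(all(greg >= sol))
})

test_that("as-printed mortality variant is returned unclamped and flagged", {
  v <- mortality_window(25, 0.5, 1.5, 15, 35, variant = "as_printed")
  expect_lt(as.numeric(v), 0)
  expect_true(attr(v, "out_of_range"))
})

test_that("adult mortality is anchored at its baseline and saturates", {
  Tg <- seq(0, 60, by = 0.1)
  for (b in c(0.0083, 0.0111)) {
    mu <- adult_mortality(Tg, baseline = b)
    expect_equal(min(mu), b, tolerance = 1e-10)
    expect_true(all(mu <= 1 + 1e-12))
    expect_equal(adult_mortality(-20, b), 1, tolerance = 1e-6)
    expect_equal(adult_mortality(80, b), 1, tolerance = 1e-6)
  }
  # gregarious adults die faster than solitarious at every temperature
  expect_true(all(adult_mortality(Tg, 0.0111) >=
                    adult_mortality(Tg, 0.0083)))
  expect_error(adult_mortality(30, baseline = 1.2), "baseline")
  expect_error(adult_mortality(30, baseline = 0), "baseline")
})

test_that("thermal parameter sets default to constants and validate config", {
  ts <- build_thermal_param_set()
  r30 <- eval_thermal_rates(ts, 30)
  r10 <- eval_thermal_rates(ts, 10)
  expect_equal(r30, r10)  # all-constant set is temperature independent
  expect_equal(unname(r30["sigma"]), 0.0714)
  expect_error(build_thermal_param_set(list(bogus = 1)), "bogus")
  expect_error(build_thermal_param_set(list(sigma = list(
    family = "allahyari", P = 0.1))), "missing")
  expect_error(build_thermal_param_set(list(sigma = list(
    family = "weibull", a = 1))), "family")
})

test_that("a single-curve set reproduces the fitted curve pointwise", {
  ts <- build_thermal_param_set(list(sigma = fitted_thermal_curve("sigma")))
  r <- eval_thermal_rates(ts, 30)
  x <- (30 - 15.1) / (42.9187 - 15.1)
  expect_equal(unname(r["sigma"]), 0.2658 * x^1.5818 * (1 - sqrt(x)))
  # other symbols still at baseline constants
  expect_equal(unname(r["mu_e"]), 0.33)
})

test_that("thermal rates driven by a forcing cycle are bounded and periodic", {
  ts <- build_thermal_param_set(list(
    phi = fitted_thermal_curve("phi"),
    sigma = fitted_thermal_curve("sigma"),
    mu_e = fitted_thermal_curve("mu_e"),
    mu_s = fitted_thermal_curve("mu_s")))
  f <- temperature_forcing(28, 6, omega = 2, kappa = 50,
                           variant = "additive")
  t <- seq(0, forcing_period(f), length.out = 60)
  rates <- sapply(t, function(ti)
    eval_thermal_rates(ts, seasonal_temperature(f, ti)))
  rates2 <- sapply(t + forcing_period(f), function(ti)
    eval_thermal_rates(ts, seasonal_temperature(f, ti)))
  expect_true(all(is.finite(rates)) && all(rates >= 0))
  expect_equal(rates, rates2, tolerance = 1e-9)
})
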