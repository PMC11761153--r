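test_that("rate aggregates are the printed outflow sums", {
  cc <- rate_aggregates(locust_params())
  expect_equal(unname(cc["c1"]), 0.0714 + 0.33)
  expect_equal(unname(cc["c4"]), 0.25 + 0.0083)
  cc10 <- rate_aggregates(locust_params(mu_h = 0.25, mu_b = 0.3))
  expect_equal(unname(cc10["c2"]), 0.2763)
  expect_equal(unname(cc10["c3"]), 0.3243)
  czero <- rate_aggregates(locust_params(
    mu_e = 0, mu_h = 0, mu_b = 0, mu_s = 1e-9, mu_g = 1e-9,
    beta_1 = 0, beta_2 = 0))
  expect_equal(unname(czero["c2"]), 0.0263)
})

test_that("closed-form N0 behaves as a linear threshold quantity", {
  expect_equal(offspring_number(locust_params(phi = 0))$N0, 0)
  on <- offspring_number(locust_params(phi = 1.75))
  expect_equal(on$N0, on$N0S + on$N0G)
  # linear in phi
  on2 <- offspring_number(locust_params(phi = 3.5))
  expect_equal(on2$N0, 2 * on$N0, tolerance = 1e-12)
  # at the critical rate the offspring number is exactly one
  ps <- phi_star(locust_params())
  expect_equal(offspring_number(locust_params(phi = ps))$N0, 1,
               tolerance = 1e-10)
})

test_that("closed form agrees with the next-generation-matrix oracle", {
  expect_equal(offspring_number_ngm(locust_params(phi = 0)), 0)
  for (p in random_locust_params(200, seed = 101)) {
    cf <- offspring_number(p)$N0
    ngm <- offspring_number_ngm(p)
    expect_lt(abs(cf - ngm), 1e-10 * max(1, ngm))
  }
})

test_that("phi* scales inversely with the female fraction and needs sigma > 0", {
  p <- locust_params(eta = 0.6)
  p2 <- locust_params(eta = 0.2)  # doubles 1 - eta
  expect_equal(phi_star(p), 2 * phi_star(p2), tolerance = 1e-12)
  expect_error(phi_star(locust_params(sigma = 0)), "sigma")
})

test_that("positive equilibrium exists iff N0 > 1 and satisfies the balance", {
  p <- locust_params()
  ps <- phi_star(p)
  # N0 = 2 scenario: eggs settle at half the carrying capacity
  p2 <- locust_params(phi = 2 * ps)
  expect_equal(offspring_number(p2)$N0, 2, tolerance = 1e-10)
  eq2 <- nontrivial_equilibrium(p2)
  expect_equal(unname(eq2["E"]), 80000 / 2, tolerance = 1e-10)
  # persistence scenario: strictly positive state zeroing the ODE
  p10 <- locust_params(phi = 25, mu_h = 0.25, mu_b = 0.3)
  eq <- nontrivial_equilibrium(p10)
  expect_true(all(eq > 0))
  expect_lt(max(abs(rhs_autonomous(eq, p10))), 1e-9 * 80000)
  expect_error(nontrivial_equilibrium(locust_params(phi = 0.5 * ps)),
               "N0")
})

test_that("analytic Jacobian matches finite differences", {
  p <- locust_params(phi = 25, mu_h = 0.25, mu_b = 0.3)
  state <- c(30000, 5000, 2000, 8000, 7000)
  J <- locust_jacobian(p, state)
  h <- 1e-4
  for (j in 1:5) {
    up <- state; dn <- state
    up[j] <- up[j] + h * max(1, state[j])
    dn[j] <- dn[j] - h * max(1, state[j])
    fd <- (rhs_autonomous(up, p) - rhs_autonomous(dn, p)) /
      (up[j] - dn[j])
    expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-6)
  }
})

test_that("origin stability follows the N0-versus-one rule", {
  expect_true(stability_report(locust_params(phi = 1.75),
                               rep(0, 5))$stable)
  p10 <- locust_params(phi = 25, mu_h = 0.25, mu_b = 0.3)
  expect_false(stability_report(p10, rep(0, 5))$stable)
  expect_true(stability_report(p10, nontrivial_equilibrium(p10))$stable)
  expect_error(stability_report(p10, c(100, 100, 100, 100, 100)),
               "equilibrium")
  # randomized threshold consistency
  for (p in random_locust_params(60, seed = 77)) {
    st <- stability_report(p, rep(0, 5))
    expect_identical(st$stable, offspring_number(p)$N0 < 1)
  }
})

test_that("N0 is monotone in each vital rate and independent of K", {
  base <- locust_params()
  n0 <- function(p) offspring_number(p)$N0
  dirs <- c(phi = 1, sigma = 1, gamma_h = 1, gamma_b = 1, psi = 1,
            eta = -1, mu_e = -1, mu_h = -1, mu_b = -1, mu_s = -1,
            mu_g = -1)
  for (nm in names(dirs)) {
    h <- 1e-6 * max(base[[nm]], 0.01)
    up <- modifyList(as.list(unclass(base)), setNames(list(base[[nm]] + h), nm))
    dn <- modifyList(as.list(unclass(base)), setNames(list(base[[nm]] - h), nm))
    slope <- (n0(locust_params(up)) - n0(locust_params(dn))) / (2 * h)
    expect_gt(slope * dirs[[nm]], 0)
  }
  expect_equal(n0(locust_params(K = 20000)), n0(base), tolerance = 1e-14)
})

test_that("bifurcation at phi* is forward with opposite-signed coefficients", {
  rep <- suppressWarnings(bifurcation_coefficients(locust_params()))
  expect_equal(offspring_number(locust_params(phi = rep$phi_star))$N0, 1,
               tolerance = 1e-8)
  # Perron-Frobenius: both null vectors of the Metzler Jacobian positive
  expect_true(all(rep$u > 0))
  expect_true(all(rep$v > 0))
  expect_lt(rep$a, 0)
  expect_gt(rep$b, 0)
  expect_lt(rep$a * rep$b, 0)
  expect_match(rep$classification, "forward")
  # the printed sign heuristic is reported alongside for comparison
  expect_true(rep$v1_sign_rule %in% c(-1, 0, 1))
  # a = -(2 phi* u1 / K) b with positive phi*, u1, K
  expect_equal(rep$a,
               -2 * rep$phi_star * rep$u[1] / 80000 * rep$b,
               tolerance = 1e-10)
})

test_that("symmetric phase exchange flags the degenerate boundary", {
  p <- locust_params(mu_s = 0.009, mu_g = 0.009, beta_1 = 0.2,
                     beta_2 = 0.2)
  rep <- suppressWarnings(bifurcation_coefficients(p))
  expect_identical(rep$v1_sign_rule, 0)
  expect_true(rep$v1_boundary)
  expect_match(rep$classification, "degenerate")
})
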