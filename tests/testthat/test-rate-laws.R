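test_that("first-order decay matches closed-form expectations", {
  expect_equal(first_order_concentration(8.0e8, k = 0, t = 2), 8.0e8)
  expect_equal(first_order_concentration(1, k = log(2), t = 1), 0.5)
  # ES1 k1 at 673 K over one residence time
  expect_equal(first_order_concentration(8.0e8, k = 0.31, t = 2),
               8.0e8 * exp(-0.62))
  expect_error(first_order_concentration(-1, 0.1, 1), "nonnegative")
  expect_error(first_order_concentration(1, -0.1, 1), "nonnegative")
  expect_error(first_order_concentration(1, 0.1, -1), "nonnegative")
})

test_that("rate constant from yield ratio inverts the decay law", {
  expect_equal(k_from_yield_ratio(5, 5, t = 2), 0)
  expect_equal(k_from_yield_ratio(2, 1, t = 2), log(2) / 2)
  expect_equal(k_from_yield_ratio(8.0e8, 8.0e8 * exp(-0.62), t = 2), 0.31)
  expect_error(k_from_yield_ratio(1, 2, t = 2), "destruction")
  expect_error(k_from_yield_ratio(1, 0, t = 2), "positive")
})

test_that("decay/ratio round trip is the identity across parameters", {
  set.seed(11)
  for (i in 1:25) {
    c0 <- runif(1, 1e4, 1e9)
    k <- runif(1, 1e-4, 5)
    t <- runif(1, 0.1, 10)
    expect_equal(k_from_yield_ratio(c0, first_order_concentration(c0, k, t), t),
                 k, tolerance = 1e-10)
  }
})

test_that("Arrhenius expression reproduces hand-evaluated rate constants", {
  expect_equal(arrhenius_k(arrhenius_parameters(Ea = 0, A = 2.1e6), 673),
               2.1e6)
  expect_equal(arrhenius_k(es1_params(), 973),
               2.1e6 * exp(-108850 / (8.314 * 973)))
  expect_equal(arrhenius_k(sm1_params(), 673),
               3.0e7 * exp(-136520 / (8.314 * 673)))
  # strict monotonicity in T for positive Ea
  temps <- seq(400, 1200, by = 25)
  expect_true(all(diff(arrhenius_k(es1_params(), temps)) > 0))
  expect_error(arrhenius_k(es1_params(), -300), "positive")
})

test_that("modified Arrhenius reduces to plain Arrhenius at n = 0 and is monotone", {
  temps <- seq(400, 1200, by = 50)
  expect_equal(modified_arrhenius_k(es1_params(), n = 0, temps),
               arrhenius_k(es1_params(), temps))
  for (n in c(0, 0.5, 1.057)) {
    expect_true(all(diff(modified_arrhenius_k(sm1_params(), n, temps)) > 0))
  }
})

test_that("temperature exponent solve is the exact inverse of the modified form", {
  # plain Arrhenius rate constant implies n = 0
  k0 <- arrhenius_k(es1_params(), 810)
  expect_equal(solve_temperature_exponent(k0, es1_params(), 810), 0,
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:25) {
    p <- arrhenius_parameters(Ea = runif(1, 5e4, 2e5), A = 10^runif(1, 4, 9))
    n <- runif(1, -1, 2)
    temp <- runif(1, 450, 1100)
    k <- modified_arrhenius_k(p, n, temp)
    expect_equal(solve_temperature_exponent(k, p, temp), n,
                 tolerance = 1e-10)
  }
  expect_error(solve_temperature_exponent(-1, es1_params(), 673), "positive")
})

test_that("temperature exponents recompute from the printed 673 K rate constants", {
  # frozen closed-form evaluations: (ln k - ln A + Ea/RT)/ln T
  expect_equal(solve_temperature_exponent(0.74, sm1_params(), 673),
               1.056727, tolerance = 1e-6)
  expect_equal(solve_temperature_exponent(0.31, es1_params(), 673),
               0.5720617, tolerance = 1e-6)
  # and the exponents round-trip to the observed rate constants
  expect_equal(modified_arrhenius_k(sm1_params(), 1.056727, 673), 0.74,
               tolerance = 1e-5)
  expect_equal(modified_arrhenius_k(es1_params(), 0.5720617, 673), 0.31,
               tolerance = 1e-5)
})

test_that("Arrhenius regression recovers generating parameters exactly", {
  for (params in list(es1_params(), sm1_params())) {
    for (temps in list(seq(673, 973, 50), c(673, 973), seq(500, 900, 23))) {
      fit <- fit_arrhenius(exact_rate_table(params, temps))
      expect_equal(fit$Ea, params$Ea, tolerance = 1e-6)
      expect_equal(fit$A, params$A, tolerance = 1e-6)
      expect_equal(fit$r_squared, 1, tolerance = 1e-9)
      expect_identical(fit$n_points, length(temps))
    }
  }
})

test_that("two-point Arrhenius fit equals the closed-form solution", {
  k1 <- 0.31
  k2 <- 2.12
  fit <- fit_arrhenius(rate_constant_table(c(673, 973), c(k1, k2)))
  ea_closed <- 8.314 * log(k2 / k1) / (1 / 673 - 1 / 973)
  expect_equal(fit$Ea, ea_closed, tolerance = 1e-10)
})

test_that("flat rate table gives Ea = 0, A = k and degenerate inputs error", {
  fit <- fit_arrhenius(rate_constant_table(c(673, 773, 873), rep(0.5, 3)))
  expect_equal(fit$Ea, 0, tolerance = 1e-8)
  expect_equal(fit$A, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_arrhenius(rate_constant_table(673, 0.31)), "at least 2")
  expect_error(rate_constant_table(c(673, 673), c(0.3, 0.4)),
               "strictly increasing")
  expect_error(rate_constant_table(c(673, 773), c(0.3, -0.4)), "positive")
})
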