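test_that("nicotine decay follows the first integrated rate law", {
  m <- es1_model()
  expect_equal(nic_at(m, 0), 8.0e8)
  expect_equal(nic_at(m, 2), 8.0e8 * exp(-2.22))
  expect_lt(nic_at(m, 1e3) / m$nic0, 1e-12)
  expect_error(nic_at(m, -1), "nonnegative")
})

test_that("intermediate solution matches its frozen value and boundaries", {
  m <- es1_model()
  expect_equal(intermediate_at(m, 0), 0)
  # frozen closed-form evaluation with the printed rate constants
  expect_equal(intermediate_at(m, 2), 600254007, tolerance = 1e-6)
  expect_error(intermediate_at(m, -0.5), "nonnegative")
})

test_that("product solution satisfies boundary conditions and conservation", {
  m <- es1_model()
  expect_equal(product_at(m, 0), 0)
  expect_equal(product_at(m, 2),
               m$nic0 - nic_at(m, 2) - intermediate_at(m, 2),
               tolerance = 1e-12)
  ts <- seq(0, 20, by = 0.5)
  prod <- vapply(ts, function(t) product_at(m, t), numeric(1))
  expect_true(all(diff(prod) >= 0))
  expect_equal(product_at(m, 200) / m$nic0, 1, tolerance = 1e-10)
})

test_that("mass is conserved for arbitrary rate-constant combinations", {
  set.seed(7)
  for (i in 1:30) {
    m <- consecutive_model(k1 = runif(1, 0.01, 5), k2 = runif(1, 0.01, 5),
                           nic0 = runif(1, 1e6, 1e9))
    for (t in c(0, 0.3, 1, 2, 7)) {
      total <- nic_at(m, t) + intermediate_at(m, t) + product_at(m, t)
      expect_equal(total, m$nic0, tolerance = 1e-9)
    }
  }
})

test_that("analytic solutions agree with numerical integration across regimes", {
  times <- seq(0, 10, by = 0.25)
  for (ratio in c(0.1, 1, 10, 100)) {
    k2 <- 0.2
    k1 <- k2 * ratio
    m <- consecutive_model(k1, k2, nic0 = 8.0e8)
    traj <- consecutive_trajectory(m, times)
    nic_cf <- vapply(times, function(t) nic_at(m, t), numeric(1))
    int_cf <- vapply(times, function(t) intermediate_at(m, t), numeric(1))
    prod_cf <- vapply(times, function(t) product_at(m, t), numeric(1))
    # relative to the total pool, which bounds every species
    expect_lt(max(abs(traj$nic - nic_cf)) / m$nic0, 1e-6)
    expect_lt(max(abs(traj$intermediate - int_cf)) / m$nic0, 1e-6)
    expect_lt(max(abs(traj$product - prod_cf)) / m$nic0, 1e-6)
    expect_equal(traj$nic + traj$intermediate + traj$product,
                 rep(m$nic0, length(times)), tolerance = 1e-8)
  }
})

test_that("equal-rate branch matches the analytic limit and is continuous", {
  k <- 0.8
  m_eq <- consecutive_model(k, k, nic0 = 1e8)
  for (t in c(0.5, 1, 2, 5)) {
    expect_equal(intermediate_at(m_eq, t), 1e8 * k * t * exp(-k * t))
  }
  # continuity across the branch switch
  m_near <- consecutive_model(k * (1 + 1e-8), k, nic0 = 1e8)
  for (t in c(0.5, 2, 5)) {
    expect_equal(intermediate_at(m_near, t), intermediate_at(m_eq, t),
                 tolerance = 1e-6)
    expect_equal(product_at(m_near, t), product_at(m_eq, t),
                 tolerance = 1e-6)
  }
  # and against the ODE oracle at exactly equal rates
  times <- seq(0, 6, by = 0.5)
  traj <- consecutive_trajectory(m_eq, times)
  int_cf <- vapply(times, function(t) intermediate_at(m_eq, t), numeric(1))
  expect_lt(max(abs(traj$intermediate - int_cf)) / m_eq$nic0, 1e-6)
})

test_that("trajectory is constant when rates vanish and rejects bad grids", {
  m <- consecutive_model(1e-14, 1e-14, nic0 = 5e7)
  traj <- consecutive_trajectory(m, seq(0, 5, by = 1))
  expect_equal(traj$nic, rep(5e7, 6), tolerance = 1e-10)
  expect_equal(traj$product, rep(0, 6), tolerance = 1e-4)
  expect_error(consecutive_trajectory(m, c(2, 1, 0)), "ascending")
})

test_that("simplified product converges to the full solution as k1/k2 grows", {
  k2 <- 0.13
  gaps <- vapply(c(10, 30, 100, 300, 1000), function(ratio) {
    m <- consecutive_model(k1 = k2 * ratio, k2 = k2, nic0 = 8.0e8)
    ts <- seq(1 / m$k1, 10, length.out = 40)
    max(abs(vapply(ts, function(t) product_simplified(m, t), numeric(1)) -
              vapply(ts, function(t) product_at(m, t), numeric(1)))) / m$nic0
  }, numeric(1))
  expect_lt(gaps[[3]], 0.02)  # ratio 100
  expect_true(all(diff(gaps) < 0))
  # frozen direct evaluation of the simplified form
  m <- es1_model()
  expect_equal(product_simplified(m, 2), 8.0e8 * (1 - exp(-0.26)))
})

test_that("k2 inversion is the exact inverse of the simplified product", {
  expect_equal(invert_k2_from_product(8.0e8, 0, t = 2), 0)
  expect_equal(invert_k2_from_product(8.0e8, 4.4e8, t = 2), -log(0.45) / 2)
  set.seed(31)
  for (i in 1:20) {
    m <- consecutive_model(k1 = runif(1, 0.5, 5), k2 = runif(1, 0.01, 1),
                           nic0 = runif(1, 1e6, 1e9))
    t <- runif(1, 0.5, 8)
    expect_equal(invert_k2_from_product(m$nic0, product_simplified(m, t), t),
                 m$k2, tolerance = 1e-10)
  }
  expect_error(invert_k2_from_product(8.0e8, 9e8, t = 2), "exceeds")
})

test_that("time of maximum intermediate matches grid search and symmetry", {
  m <- es1_model()
  tmax <- time_of_max_intermediate(m)
  expect_equal(tmax, log(1.11 / 0.13) / (1.11 - 0.13), tolerance = 1e-12)
  # confirmed against a fine grid over the numerical trajectory
  grid <- seq(0, 8, by = 0.001)
  traj <- consecutive_trajectory(m, grid)
  expect_equal(grid[which.max(traj$intermediate)], tmax, tolerance = 1e-3)
  # symmetry under swapping the rate constants
  m_swap <- consecutive_model(0.13, 1.11, nic0 = 8.0e8)
  expect_equal(time_of_max_intermediate(m_swap), tmax)
  # equal-rate limit
  m_eq <- consecutive_model(2, 2, nic0 = 1)
  expect_equal(time_of_max_intermediate(m_eq), 0.5)
  m_half <- consecutive_model(2, 1, nic0 = 1)
  expect_equal(time_of_max_intermediate(m_half), log(2))
})

test_that("derived summary composes the ratio quantities correctly", {
  m <- es1_model()
  s <- derived_summary(m, product_max = 4.4e8)
  expect_equal(s$ratio_product_to_nic, 0.55)
  expect_equal(s$pct_transferred_intact, 45)
  expect_equal(s$intermediate_at_t, intermediate_at(m, 2))
  expect_equal(s$ratio_nic_to_sum, 8.0e8 / (intermediate_at(m, 2) + 4.4e8))
  expect_error(derived_summary(consecutive_model(1, 1, 1, t = 0), 0),
               "undefined")
})
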