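test_that("decay rate follows the bounded logistic in age", {
  p <- physical_params(0.01, 0.21, tau = 0.1, t0 = 65, P_bar_H = 0.3,
                       kappa = 0.1, c0 = 10)
  expect_equal(decay_rate(65, p), (0.01 + 0.21) / 2)  # midpoint at t0
  expect_lt(abs(decay_rate(65 - 1000 / 0.1, p) - 0.01), 1e-9)
  expect_lt(abs(decay_rate(65 + 1000 / 0.1, p) - 0.21), 1e-9)
  # closed-form point: logistic(ln 3) = 3/4
  expect_equal(decay_rate(65 + log(3) / 0.1, p), 0.01 + 0.75 * 0.2,
               tolerance = 1e-12)
  grid <- seq(0, 120, by = 0.5)
  a <- decay_rate(grid, p)
  expect_true(all(diff(a) > 0))
  expect_true(all(a > 0.01 & a < 0.21))
  expect_error(physical_params(0.2, 0.2, 0.1, 65, 0.3, 0.1, 10),
               "0 < alpha_min < alpha_max < 1")
})

test_that("health investment is concave, saturating and zero at zero", {
  p <- const_alpha_physical(0.05, kappa = 0.1, c0 = 10)
  expect_equal(physical_investment(0, p), 0)
  expect_equal(physical_investment(10, p), 0.1 * (1 - exp(-1)),
               tolerance = 1e-12)
  for (c in c(0.5, 2, 10, 50)) {
    expect_lt(physical_investment(2 * c, p), 2 * physical_investment(c, p))
  }
  expect_true(all(physical_investment(c(1, 10, 50), p) < 0.1))
  expect_lte(physical_investment(1e6, p), 0.1)  # kappa binds asymptotically
  expect_error(physical_investment(-1, p), "C must be >= 0")
})

test_that("physical update composes decay, investment and the unit bounds", {
  p <- const_alpha_physical(0.05)
  t_early <- 25  # far below t0 = 1e6, so alpha == alpha_min exactly
  expect_equal(step_physical(0.8, 0, t_early, p), 0.76)
  expect_equal(step_physical(1, 1e9, t_early, p), 1)   # cap binds
  p2 <- const_alpha_physical(0.1, kappa = 0.1, c0 = 10)
  expect_equal(step_physical(0.5, 10, t_early, p2),
               0.45 + 0.1 * (1 - exp(-1)), tolerance = 1e-12)
  expect_error(step_physical(1.2, 0, t_early, p), "\\[0, 1\\]")
})

test_that("generic domain update honours decay bounds and the cap", {
  lin <- function(C) 0.1 * C
  expect_equal(step_domain(0.6, 0, 0, lin), 0.6)   # no decay, no investment
  expect_equal(step_domain(0.6, 0, 1, lin), 0)     # full decay
  expect_equal(step_domain(0.9, 3, 0.1, lin), 1)   # cap binds: 0.81 + 0.3
  expect_error(step_domain(0.5, 0, 1.2, lin), "delta must lie in \\[0, 1\\]")
})

test_that("health span is zero at the threshold and linear above it (a = 1)", {
  sp <- default_spans()
  expect_equal(health_span(0.3, sp, 0.3), 0)
  expect_equal(health_span(0.1, sp, 0.3), 0)
  expect_equal(health_span(1, sp, 0.3), 60)
  expect_equal(health_span(0.3 + 0.5 * 0.7, sp, 0.3), 30)  # midpoint, a = 1
  # continuity at the threshold
  expect_lt(health_span(0.3 + 1e-9, sp, 0.3), 1e-6)
  P <- seq(0.31, 1, length.out = 50)
  expect_true(all(diff(health_span(P, sp, 0.3)) > 0))
})

test_that("lifespan brackets the health span and responds less steeply", {
  sp <- default_spans()
  expect_equal(lifespan(0, sp), 70)
  expect_equal(lifespan(1, sp), 85)
  # numeric slope oracle on (P_bar_H, 1]: h' > g' >= 0 everywhere
  P <- seq(0.3 + 1e-6, 1, length.out = 100)
  dh <- diff(health_span(P, sp, 0.3)) / diff(P)
  dg <- diff(lifespan(P, sp)) / diff(P)
  expect_true(all(dh > dg))
  expect_true(all(dg >= 0))
  expect_true(all(health_span(P, sp, 0.3) <= lifespan(P, sp)))
  # parameterisations violating the shape are rejected at scenario assembly
  bad <- span_params(H_max = 60, a = 2, T_min = 70, T_max = 85, b = 1)
  expect_error(
    scenario(c(F = 0.5, P = 0.5), const_alpha_physical(0.05), bad,
             economy_params(50, 0.5), financial_index_params(500, 0.5),
             initial_P = 0.8, initial_OF = 100),
    "h'\\(P\\) > g'\\(P\\)")
  expect_error(span_params(H_max = 90, a = 1, T_min = 70, T_max = 85, b = 1),
               "H_max must be <= T_max")
})

test_that("labour income exists only inside the health span", {
  ec <- economy_params(y_max = 50, eta = 1)
  expect_equal(labour_income(0.9, ec, H_prev = 0), 0)
  expect_equal(labour_income(1, ec, H_prev = 5), 50)
  expect_equal(labour_income(0.5, ec, H_prev = 5), 25)  # eta = 1, linear
  ec2 <- economy_params(y_max = 50, eta = 0.5)
  P <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(labour_income(P, ec2, H_prev = 1)) > 0))
})

test_that("resource flow, budget and wealth accounting agree with the identities", {
  ec <- economy_params(y_max = 10, eta = 1)
  expect_equal(resource_flow(0.5, 100, 0.05, ec, H_prev = 1), 5 + 5)
  expect_equal(resource_flow(0.5, 0, 0.05, ec, H_prev = 0), 0)
  expect_equal(resource_flow(0.5, 100, 0, ec, H_prev = 1), 5)

  expect_true(budget_feasible(allocation(60, 50), 100, 10))   # boundary
  expect_false(budget_feasible(allocation(111, 0), 100, 10))
  expect_true(budget_feasible(allocation(0, 0), 0, 0))
  expect_error(allocation(-1, 0), ">= 0")

  expect_equal(step_wealth(100, 0.05, 5, 2, TRUE), 108)
  expect_equal(step_wealth(100, 0.05, 5, 2, FALSE), 103)
  expect_equal(step_wealth(100, 0, 5, 0, FALSE), 100)
  expect_error(step_wealth(100, 0, 0, 200, TRUE), "below 0")

  expect_equal(step_resources_general(10, c(0.5), 5, function(x) 3), 8)
  expect_equal(step_resources_general(10, c(0.5), 0, function(x) 0), 10)
  expect_equal(step_resources_general(10, c(0.5), 13, function(x) 3), 0)
  expect_error(step_resources_general(10, c(0.5), 14, function(x) 3),
               "infeasible")
})

test_that("labour income resumes if physical wellbeing recovers above the threshold", {
  # start just below the threshold with enough wealth to buy the way back up
  scn <- mini_scenario(alpha = 0.02, P0 = 0.28, OF0 = 500, horizon = 6)
  traj <- simulate_lifecycle(scn, policy_fixed_amount(40), quiet = TRUE)
  expect_equal(traj$Y[1], 0)            # below threshold at entry: no income
  expect_gt(traj$P[1], 0.3)             # investment lifts P back above it
  expect_true(all(traj$Y[-1] > 0))      # income resumes period by period
})
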