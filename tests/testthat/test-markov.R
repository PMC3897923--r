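test_that("propagation follows the occupancy recursion", {
  m <- two_state_model(q_monthly = 0.1, n_cycles = 3)
  tr <- propagate(m)
  expect_equal(tr$occupancy[, "alive"], c(1, 0.9, 0.81, 0.729))
  expect_equal(rowSums(tr$occupancy), rep(1, 4))
  # identity transitions leave occupancy constant
  id <- cohort_model(c("a", "dead"), function(t, age) diag(2),
                     state_costs = c(0, 0), state_utilities = c(1, 0),
                     start = c(1, 0), start_age = 60, n_cycles = 5)
  expect_true(all(propagate(id)$occupancy[, "a"] == 1))
  # starting in the absorbing state stays there
  dead <- cohort_model(c("a", "dead"), function(t, age) diag(2),
                       state_costs = c(0, 0), state_utilities = c(1, 0),
                       start = c(0, 1), start_age = 60, n_cycles = 5)
  expect_true(all(propagate(dead)$occupancy[, "dead"] == 1))
})

test_that("invalid transition matrices are rejected with cycle and row", {
  bad <- cohort_model(c("a", "dead"),
                      function(t, age) matrix(c(0.5, 0.4, 0, 1), 2, 2,
                                              byrow = TRUE),
                      state_costs = c(0, 0), state_utilities = c(1, 0),
                      start = c(1, 0), start_age = 60, n_cycles = 5)
  expect_error(propagate(bad), "cycle 0.*row.*a")
  leaky <- cohort_model(c("a", "dead"),
                        function(t, age) matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                                                byrow = TRUE),
                        state_costs = c(0, 0), state_utilities = c(1, 0),
                        start = c(1, 0), start_age = 60, n_cycles = 5)
  expect_error(propagate(leaky), "absorbing")
})

test_that("mass is conserved and death occupancy is monotone in random models", {
  set.seed(101)
  for (i in 1:200) {
    tr <- propagate(random_model(), keep_flows = FALSE)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-12))
  }
})

test_that("accumulated discounted QALYs match the geometric closed form", {
  q <- 0.05; u <- 0.6; r <- 0.03
  s <- 1 - q; v <- monthly_discount_factor(r)
  m <- two_state_model(q, u_annual = u, n_cycles = 800)
  res <- run_model(m, discount_annual = r)
  expect_equal(res$qalys, (u / 12) / (1 - s * v), tolerance = 1e-9)
  # undiscounted case and life-years
  res0 <- run_model(m, discount_annual = 0)
  expect_equal(res0$qalys, (u / 12) / (1 - s), tolerance = 1e-9)
  expect_equal(res0$life_years, res0$qalys / u, tolerance = 1e-9)
  expect_lte(res$qalys, res0$qalys)
})

test_that("one-time transition rewards are expectation-weighted and discounted at the flow cycle", {
  tr_rewards <- data.frame(from = "alive", to = "dead", cost = 100,
                           qaly = -0.1)
  m <- two_state_model(0.5, u_annual = 0, n_cycles = 40,
                       trans_rewards = tr_rewards)
  res <- run_model(m, discount_annual = 0)
  # half the cohort makes the transition in cycle 0, a quarter in cycle 1...
  expect_equal(res$qalys, -0.1, tolerance = 1e-9)
  expect_equal(res$cost, 100, tolerance = 1e-9)
  # the cycle-0 flow of mass 0.5 contributes -0.05 on its own
  tr <- propagate(m)
  expect_equal(tr$event_qalys[2], 0.5 * -0.1)
  # with discounting, the flow arriving at cycle t is scaled by v^t
  v <- monthly_discount_factor(0.12)
  resd <- run_model(m, discount_annual = 0.12)
  expect_equal(resd$cost, sum(100 * 0.5^(1:40) * v^(1:40)), tolerance = 1e-9)
  # initial one-time rewards are booked undiscounted at entry
  m2 <- two_state_model(0.5, u_annual = 0, n_cycles = 10,
                        init_costs = c(5000, 0))
  expect_equal(run_model(m2, 0.5)$cost, 5000)
})

test_that("rewards scale linearly and discounting is monotone", {
  m1 <- two_state_model(0.1, u_annual = 0.5, c_annual = 1200, n_cycles = 200)
  m2 <- two_state_model(0.1, u_annual = 0.5, c_annual = 2400, n_cycles = 200)
  r1 <- run_model(m1, 0.03); r2 <- run_model(m2, 0.03)
  expect_equal(r2$cost, 2 * r1$cost, tolerance = 1e-12)
  tr <- propagate(m1)
  totals <- vapply(c(0, 0.01, 0.03, 0.1),
                   function(r) accumulate(tr, m1, r)$cost, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("extending the horizon beyond absorption changes nothing", {
  a <- run_model(two_state_model(0.2, u_annual = 0.8, n_cycles = 200), 0.03)
  b <- run_model(two_state_model(0.2, u_annual = 0.8, n_cycles = 400), 0.03)
  expect_equal(a$qalys, b$qalys, tolerance = 1e-12)
  expect_equal(a$cost, b$cost, tolerance = 1e-12)
  # a one-cycle horizon accrues only the first cycle
  one <- run_model(two_state_model(0.2, u_annual = 0.8, n_cycles = 1), 0)
  expect_equal(one$qalys, 0.8 / 12)
})

test_that("the half-cycle correction averages start and end occupancy", {
  m <- two_state_model(0.1, u_annual = 1.2, n_cycles = 300)
  tr <- propagate(m)
  full <- accumulate(tr, m, 0)
  half <- accumulate(tr, m, 0, half_cycle = TRUE)
  s <- 0.9
  expect_equal(half$qalys, (1.2 / 12) * (1 + s) / 2 / (1 - s),
               tolerance = 1e-9)
  expect_lt(half$qalys, full$qalys)
})

test_that("traces export to a cycle-by-state CSV", {
  tr <- propagate(two_state_model(0.1, n_cycles = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("cycle", "age", "alive", "dead"))
  expect_equal(df$alive, c(1, 0.9, 0.81, 0.729))
})
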