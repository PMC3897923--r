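test_that("revision hazard follows implant-age tiers with a one-year embargo", {
  prim <- c(0.005, 0.01, 0.02)
  expect_equal(revision_monthly_prob(6, prim), 0)
  expect_equal(revision_monthly_prob(11, prim), 0)
  expect_equal(revision_monthly_prob(60, prim), 1 - 0.995^(1 / 12))
  expect_equal(revision_monthly_prob(60, prim), 0.00041762, tolerance = 3e-5)
  expect_equal(revision_monthly_prob(119, prim), 1 - 0.995^(1 / 12))
  expect_equal(revision_monthly_prob(120, prim), 1 - 0.99^(1 / 12))
  expect_equal(revision_monthly_prob(300, prim), 1 - 0.98^(1 / 12))
  expect_equal(revision_monthly_prob(300, prim), 0.0016821, tolerance = 5e-5)
})

test_that("competing monthly risks combine multiplicatively", {
  expect_equal(combine_risks(0.1, 0.2), 0.28)
  expect_equal(combine_risks(0.3, 0), 0.3)
  expect_equal(combine_risks(1, 0.5), 1)
  expect_equal(combine_risks(0.1, 0.2), combine_risks(0.2, 0.1))
  expect_gte(combine_risks(0.1, 0.2), 0.2)
  expect_error(combine_risks(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("state rewards reflect the cost scenario and bridge", {
  p <- base_params("A")
  rwA <- strategy_rewards(p, "delay_bridge")
  expect_equal(rwA$cost_annual[rwA$state == "wait"], 2500)
  expect_equal(rwA$utility_annual[rwA$state == "wait"], 0.7)
  expect_equal(rwA$cost_annual[rwA$state == "well_tka"], 0)
  rwA0 <- strategy_rewards(p, "delay_no_bridge")
  expect_equal(rwA0$cost_annual[rwA0$state == "wait"], 0)

  pB <- base_params("B")
  rwB <- strategy_rewards(pB, "delay_no_bridge")
  expect_equal(rwB$cost_annual[rwB$state == "wait"], 10369)
  expect_equal(rwB$utility_annual[rwB$state == "wait"], 0.6)
  expect_equal(rwB$cost_annual[rwB$state == "well_tka"], 0.2 * 10369)
  expect_equal(rwB$cost_annual[rwB$state == "well_tka"], 2073.80)
  one <- attr(rwB, "one_time")
  expect_equal(one$cost, c(26865, 35542))
  expect_equal(one$qaly, c(0.01 * -0.20, -0.1))
  # complication toggle removes the expected one-time disutility
  pB$include_complications <- FALSE
  expect_equal(attr(strategy_rewards(pB), "one_time")$qaly[1], 0)
})

test_that("waiting accrues the OA utility month by month", {
  # no deaths, no revisions, no discounting: 24 wait cycles at 0.6/yr
  p <- no_event_params(discount_annual = 0)
  lt <- immortal_lt()
  H <- 120
  del <- run_model(build_strategy("delay_no_bridge", p, lt, n_cycles = H), 0)
  imm <- run_model(build_strategy("immediate_tka", p, lt, n_cycles = H), 0)
  expect_equal(del$qalys, 24 * 0.6 / 12 + (H - 24) * 0.9 / 12,
               tolerance = 1e-12)
  expect_equal(imm$qalys, H * 0.9 / 12, tolerance = 1e-12)
  expect_equal(imm$qalys - del$qalys, 24 * (0.9 - 0.6) / 12,
               tolerance = 1e-12)
  # surgery costs are identical but the delayed one is paid later;
  # without discounting the totals agree
  expect_equal(del$cost, imm$cost, tolerance = 1e-12)
})

test_that("zero wait makes the delayed strategies degenerate to immediate TKA", {
  p <- parameter_set(wait_months = 0, max_age_years = 90)
  lt <- base_lt()
  imm <- run_strategy("immediate_tka", p, lt)
  for (s in c("delay_bridge", "delay_no_bridge")) {
    d <- run_strategy(s, p, lt)
    expect_equal(d$cost, imm$cost, tolerance = 1e-12)
    expect_equal(d$qalys, imm$qalys, tolerance = 1e-12)
  }
})

test_that("base-case orderings match the expected clinical structure", {
  runs <- base_runs("A")
  q <- vapply(runs, `[[`, numeric(1), "qalys")
  expect_true(q["immediate_tka"] > q["delay_bridge"])
  expect_true(q["delay_bridge"] > q["delay_no_bridge"])
  # delayed, discounted surgery is cheaper in the direct-cost scenario
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  expect_lt(costs["delay_no_bridge"], costs["immediate_tka"])
  # cohort mass is conserved throughout the strategy models
  occ <- runs$delay_bridge$trace$occupancy
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
  expect_true(all(diff(occ[, "dead"]) >= -1e-12))
  # everyone is eventually absorbed before the age cap
  expect_equal(unname(occ[nrow(occ), "dead"]), 1, tolerance = 1e-9)
})

test_that("the 30-day excess mortality acts only in the surgery month", {
  lt <- immortal_lt()
  p <- no_event_params(discount_annual = 0, p_mort30_primary = 0.1)
  m <- build_strategy("immediate_tka", p, lt, n_cycles = 24)
  tr <- propagate(m, keep_flows = FALSE)
  expect_equal(unname(tr$occupancy[2, "dead"]), 0.1)
  expect_equal(unname(tr$occupancy[25, "dead"]), 0.1)  # no further deaths
})

test_that("revisions respect the embargo year and the two-revision cap", {
  lt <- immortal_lt()
  p <- no_event_params(discount_annual = 0,
                       p_rev_primary_by_tier = c(0.5, 0.5, 0.5),
                       p_rev_revision_by_tier = c(0.5, 0.5, 0.5))
  m <- build_strategy("immediate_tka", p, lt, n_cycles = 600)
  tr <- propagate(m, keep_flows = FALSE)
  # no revision inflow during the implant's first year
  expect_equal(sum(tr$inflow[1:13, "post_rev1"]), 0)
  expect_gt(tr$inflow[14, "post_rev1"], 0)
  # with certain survival everyone ends in the second-revision well state
  expect_equal(unname(tr$occupancy[nrow(tr$occupancy), "well_rev2"]), 1,
               tolerance = 1e-6)
  # each patient is charged exactly one primary and two revisions
  res <- accumulate(tr, m, 0)
  expect_equal(res$cost, p$c_tka + 2 * p$c_rev, tolerance = 1e-4)
})

test_that("time-limited bridge relief interpolates the waiting utility", {
  lt <- immortal_lt()
  p0 <- no_event_params(discount_annual = 0, u_oa_bridge = 0.7,
                        c_bridge_annual = 0)
  run_relief <- function(m_rel) {
    p <- p0; p$bridge_relief_months <- m_rel
    run_model(build_strategy("delay_bridge", validate_parameters(p), lt,
                             n_cycles = 48), 0)$qalys
  }
  full <- run_relief(NA_real_)   # relief for the whole wait
  none <- run_relief(0)
  expect_equal(full - none, 24 * 0.1 / 12, tolerance = 1e-12)
  # fractional months weight the boundary cycle linearly
  expect_equal(run_relief(6.5) - none, 6.5 * 0.1 / 12, tolerance = 1e-12)
  # clamped at the wait itself
  expect_equal(run_relief(24), full, tolerance = 1e-12)
})
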