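#' Treatment strategy identifiers
#'
#' The three strategies compared by the model: primary TKA at model entry
#' (`"immediate_tka"`), TKA after a waiting period spent at the untreated
#' OA utility (`"delay_no_bridge"`), and TKA after a waiting period with a
#' non-operative treatment bridge (`"delay_bridge"`).
#'
#' @return Character vector of the three strategy ids.
#' @export
tka_strategies <- function() {
  c("immediate_tka", "delay_bridge", "delay_no_bridge")
}

#' Combine two competing monthly risks
#'
#' Independent competing risks within one cycle combine multiplicatively:
#' `1 - (1 - p1) * (1 - p2)`.
#'
#' @param p1,p2 probabilities in \eqn{[0, 1]} (vectorised).
#' @return Combined probability that at least one event occurs.
#' @export
combine_risks <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE) ||
      anyNA(p1) || anyNA(p2))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  1 - (1 - p1) * (1 - p2)
}

#' Monthly revision probability by implant age
#'
#' Selects the annual revision probability for the implant-age tier
#' (`[0, 10)`, `[10, 20)`, `[20, Inf)` years, half-open) and converts it to
#' a monthly probability.  No revision can occur in the implant's first
#' year: ages below 12 months return 0.
#'
#' @param implant_age_months months since the relevant arthroplasty
#'   (vectorised, >= 0).
#' @param tiers length-3 annual revision probabilities for the three tiers.
#' @return Monthly revision probability.
#' @examples
#' revision_monthly_prob(60, c(0.005, 0.01, 0.02))
#' @export
revision_monthly_prob <- function(implant_age_months, tiers) {
  stopifnot(length(tiers) == 3, all(implant_age_months >= 0))
  yrs <- implant_age_months / 12
  p <- ifelse(implant_age_months < 12, 0,
              ifelse(yrs < 10, tiers[1], ifelse(yrs < 20, tiers[2], tiers[3])))
  annual_to_monthly_prob(p)
}

# state space layout: the first-revision well state is a monthly tunnel so
# that the revision-of-revision hazard can follow the implant-age tiers for
# cohorts revised at different calendar times.  After two revisions no
# further revision is modelled, so the second-revision well state needs no
# clock.  The primary implant's age is deterministic (one surgery date for
# the whole cohort) and is handled through the cycle index instead.
REV1_CLOCK_MAX <- 239L

tka_state_names <- function() {
  c("wait", "post_tka", "well_tka", "post_rev1",
    paste0("well_rev1_m", 1:REV1_CLOCK_MAX), "well_rev1_late",
    "post_rev2", "well_rev2", "dead")
}

#' Per-state reward rates and one-time rewards for a strategy
#'
#' Returns the annual cost and utility rate attached to each state group
#' of a strategy's model under the parameter set's cost scenario, plus the
#' one-time rewards charged on transitions.  Scenario `"A"` counts direct
#' medical costs only (procedures and, for the bridge strategy, the bridge
#' itself); scenario `"B"` adds the indirect cost of end-stage knee OA
#' while waiting and its residual
#' `(1 - indirect_recovery_fraction) * c_indirect_oa_annual` from the
#' surgery month onward.
#'
#' @param params a `tka_parameters` object.
#' @param strategy one of [tka_strategies()].
#' @return A data frame (`state`, `cost_annual`, `utility_annual`) with a
#'   `"one_time"` attribute data frame (`event`, `cost`, `qaly`).
#' @export
strategy_rewards <- function(params, strategy = "immediate_tka") {
  strategy <- match.arg(strategy, tka_strategies())
  params <- validate_parameters(params)
  bridge <- strategy == "delay_bridge"
  societal <- params$scenario == "B"
  residual <- if (societal)
    (1 - params$indirect_recovery_fraction) * params$c_indirect_oa_annual
  else 0
  wait_cost <- (if (bridge) params$c_bridge_annual else 0) +
    (if (societal) params$c_indirect_oa_annual else 0)
  u_wait <- if (bridge) bridge_utility(params) else params$u_oa
  tab <- data.frame(
    state = c("wait", "post_tka", "well_tka", "post_rev", "well_rev", "dead"),
    cost_annual = c(wait_cost, residual, residual, residual, residual, 0),
    utility_annual = c(u_wait, params$u_tka, params$u_tka,
                       params$u_rev, params$u_rev, 0)
  )
  comp <- if (params$include_complications)
    params$p_early_complication * params$dis_complication else 0
  attr(tab, "one_time") <- data.frame(
    event = c("primary_tka", "revision_tka"),
    cost = c(params$c_tka, params$c_rev),
    qaly = c(comp, params$dis_rev)
  )
  tab
}

#' Build the cohort model for one treatment strategy
#'
#' Assembles a [cohort_model()] from a parameter set and life table.
#' Delayed strategies occupy the waiting state for `wait_months` cycles
#' (rounded to whole months) subject to background mortality only, then
#' flow into a one-cycle post-operative state carrying the procedure cost
#' and the 30-day excess mortality; the well-TKA state faces background
#' mortality plus the implant-age-tiered revision hazard (none in the
#' implant's first year).  Up to two revisions are modelled; the
#' first-revision well state is a monthly implant-age tunnel so that
#' revision-of-revision hazards follow their own tier table.  Background
#' death is applied first in every cycle; revision flows occur among the
#' survivors.
#'
#' @param strategy one of [tka_strategies()].
#' @param params a `tka_parameters` object.
#' @param life_table a `tka_life_table` covering the cohort's ages.
#' @param n_cycles optional horizon override (cycles); by default the model
#'   runs to `max_age_years`, where the life table forces absorption.
#' @return A `tka_cohort_model`.
#' @export
build_strategy <- function(strategy, params, life_table = bundled_life_table(),
                           n_cycles = NULL) {
  strategy <- match.arg(strategy, tka_strategies())
  params <- validate_parameters(params)
  lt <- validate_life_table(life_table)
  w <- if (strategy == "immediate_tka") 0L else
    as.integer(round(params$wait_months))
  if (is.null(n_cycles))
    n_cycles <- as.integer((params$max_age_years -
                              params$cohort_age_years) * 12 + 12)
  n_cycles <- max(n_cycles, w + 2L)

  states <- tka_state_names()
  S <- length(states)
  i <- as.list(seq_len(S)); names(i) <- states
  i_wait <- i$wait; i_post <- i$post_tka; i_well <- i$well_tka
  i_prev1 <- i$post_rev1; i_clock <- i$post_rev1 + 1:REV1_CLOCK_MAX
  i_late <- i$well_rev1_late; i_prev2 <- i$post_rev2
  i_wrev2 <- i$well_rev2; i_dead <- i$dead

  # revision-of-revision monthly hazard at each clock month
  h_clock <- revision_monthly_prob(1:REV1_CLOCK_MAX,
                                   params$p_rev_revision_by_tier)
  h_late <- annual_to_monthly_prob(params$p_rev_revision_by_tier[3])
  m30p <- params$p_mort30_primary
  m30r <- params$p_mort30_revision
  prim_tiers <- params$p_rev_primary_by_tier

  cache <- new.env(parent = emptyenv())
  make_matrix <- function(q, go, p1) {
    m <- matrix(0, S, S)
    s <- 1 - q
    # waiting state: background mortality only; flows to surgery when due
    m[i_wait, if (go) i_post else i_wait] <- s
    m[i_wait, i_dead] <- q
    pd <- combine_risks(q, m30p)
    m[i_post, i_well] <- 1 - pd
    m[i_post, i_dead] <- pd
    m[i_well, i_prev1] <- s * p1
    m[i_well, i_well] <- s * (1 - p1)
    m[i_well, i_dead] <- q
    pdr <- combine_risks(q, m30r)
    m[i_prev1, i_clock[1]] <- 1 - pdr
    m[i_prev1, i_dead] <- pdr
    nxt <- c(i_clock[-1], i_late)
    m[cbind(i_clock, nxt)] <- s * (1 - h_clock)
    m[cbind(i_clock, i_prev2)] <- s * h_clock
    m[i_clock, i_dead] <- q
    m[i_late, i_late] <- s * (1 - h_late)
    m[i_late, i_prev2] <- s * h_late
    m[i_late, i_dead] <- q
    m[i_prev2, i_wrev2] <- 1 - pdr
    m[i_prev2, i_dead] <- pdr
    m[i_wrev2, i_wrev2] <- s
    m[i_wrev2, i_dead] <- q
    m[i_dead, i_dead] <- 1
    m
  }
  trans_fun <- function(cycle, age) {
    q <- monthly_mortality(lt, age)
    go <- w > 0L && cycle == w - 1L
    p1 <- revision_monthly_prob(max(cycle - w, 0), prim_tiers)
    key <- sprintf("%.15g|%d|%.15g", q, go, p1)
    m <- cache[[key]]
    if (is.null(m)) {
      m <- make_matrix(q, go, p1)
      cache[[key]] <- m
    }
    m
  }

  rw <- strategy_rewards(params, strategy)
  by_state <- function(col) {
    v <- numeric(S)
    v[i_wait] <- rw[[col]][rw$state == "wait"]
    v[c(i_post, i_well)] <- rw[[col]][rw$state == "post_tka"]
    v[c(i_prev1, i_prev2)] <- rw[[col]][rw$state == "post_rev"]
    v[c(i_clock, i_late, i_wrev2)] <- rw[[col]][rw$state == "well_rev"]
    v
  }
  state_costs <- by_state("cost_annual")
  state_utilities <- by_state("utility_annual")

  # time-limited symptomatic relief: the bridge utility holds for the first
  # bridge_relief_months of the wait (fractional months weight the boundary
  # cycle), after which the waiting cohort reverts to the untreated OA
  # utility.  Bridge costs continue for the whole wait.
  relief <- params$bridge_relief_months
  if (strategy == "delay_bridge" && !is.na(relief) && relief < w && w > 0) {
    u_b <- bridge_utility(params)
    u_by_cycle <- matrix(state_utilities, n_cycles, S, byrow = TRUE)
    wait_u <- rep(params$u_oa, n_cycles)
    full <- floor(relief)
    if (full > 0) wait_u[seq_len(min(full, w))] <- u_b
    frac <- relief - full
    if (frac > 0 && full < w)
      wait_u[full + 1] <- params$u_oa + frac * (u_b - params$u_oa)
    u_by_cycle[, i_wait] <- wait_u
    state_utilities <- u_by_cycle
  }

  one_time <- attr(rw, "one_time")
  tka_cost <- one_time$cost[one_time$event == "primary_tka"]
  tka_qaly <- one_time$qaly[one_time$event == "primary_tka"]
  rev_cost <- one_time$cost[one_time$event == "revision_tka"]
  rev_qaly <- one_time$qaly[one_time$event == "revision_tka"]
  trans_rewards <- data.frame(
    from = c(i_wait, i_well, i_clock, i_late),
    to = c(i_post, i_prev1, rep(i_prev2, REV1_CLOCK_MAX + 1)),
    cost = c(tka_cost, rep(rev_cost, REV1_CLOCK_MAX + 2)),
    qaly = c(tka_qaly, rep(rev_qaly, REV1_CLOCK_MAX + 2))
  )

  start <- numeric(S)
  init_costs <- init_qalys <- NULL
  if (w > 0L) {
    start[i_wait] <- 1
  } else {
    start[i_post] <- 1
    init_costs <- numeric(S); init_costs[i_post] <- tka_cost
    init_qalys <- numeric(S); init_qalys[i_post] <- tka_qaly
  }

  cohort_model(states = states, trans_fun = trans_fun,
               state_costs = state_costs,
               state_utilities = state_utilities,
               start = start, start_age = params$cohort_age_years,
               n_cycles = n_cycles, trans_rewards = trans_rewards,
               init_costs = init_costs, init_qalys = init_qalys,
               death_state = "dead")
}

#' Run one strategy of the decision model
#'
#' @inheritParams build_strategy
#' @param half_cycle apply the half-cycle correction (see [accumulate()]).
#' @return A `tka_run_result`.
#' @export
run_strategy <- function(strategy, params,
                         life_table = bundled_life_table(),
                         n_cycles = NULL, half_cycle = FALSE) {
  model <- build_strategy(strategy, params, life_table, n_cycles)
  run_model(model, params$discount_annual, half_cycle = half_cycle,
            keep_flows = FALSE)
}

#' Run all three treatment strategies
#'
#' @inheritParams run_strategy
#' @param strategies strategy ids to run (default: all three).
#' @return A named list of `tka_run_result` objects.
#' @seealso [results_table()] to flatten the list for [build_cea_table()].
#' @export
run_strategies <- function(params, life_table = bundled_life_table(),
                           strategies = tka_strategies(),
                           half_cycle = FALSE) {
  stats::setNames(lapply(strategies, run_strategy, params = params,
                         life_table = life_table, half_cycle = half_cycle),
                  strategies)
}

#' Flatten per-strategy run results into a cost/QALY table
#'
#' @param results named list of `tka_run_result` (see [run_strategies()]).
#' @return Data frame with columns `strategy`, `cost`, `qalys`.
#' @export
results_table <- function(results) {
  data.frame(strategy = names(results),
             cost = vapply(results, function(r) r$cost, numeric(1)),
             qalys = vapply(results, function(r) r$qalys, numeric(1)),
             row.names = NULL)
}
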