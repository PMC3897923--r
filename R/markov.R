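#' Build a discrete-time cohort model
#'
#' A `tka_cohort_model` is a generic monthly-cycle Markov cohort model:
#' a state list with one absorbing death state, a (possibly time-varying)
#' transition rule, per-state reward rates and one-time transition rewards.
#' [propagate()] pushes the cohort's occupancy distribution through the
#' cycles; [accumulate()] turns the resulting trace into discounted cost
#' and QALY totals.
#'
#' @param states character vector of state names.
#' @param trans_fun function of `(cycle, age)` (cycle index from 0, cohort
#'   age in years at the start of that cycle) returning the row-stochastic
#'   transition matrix applied during that cycle.
#' @param state_costs,state_utilities annual reward rates per state: either
#'   a numeric vector of length `length(states)` or a matrix with
#'   `n_cycles` rows (one per cycle) for time-varying rates.  Rates are
#'   annual; each cycle accrues one twelfth.
#' @param start initial occupancy distribution (sums to 1).
#' @param start_age cohort age in years at cycle 0.
#' @param n_cycles maximum number of monthly cycles to run.
#' @param trans_rewards one-time rewards attached to transitions: a data
#'   frame with columns `from`, `to` (state names or indices), `cost`,
#'   `qaly`.  The reward is weighted by the probability mass making the
#'   transition and is booked — and discounted — at the cycle in which
#'   that mass arrives in the destination state.
#' @param init_costs,init_qalys optional per-state one-time rewards applied
#'   to the starting distribution at cycle 0 (e.g. a procedure performed
#'   at model entry).
#' @param death_state name of the absorbing death state.
#' @return A validated list of class `tka_cohort_model`.
#' @export
cohort_model <- function(states, trans_fun, state_costs, state_utilities,
                         start, start_age, n_cycles,
                         trans_rewards = NULL,
                         init_costs = NULL, init_qalys = NULL,
                         death_state = "dead") {
  S <- length(states)
  stopifnot(is.character(states), S >= 1, !anyDuplicated(states),
            is.function(trans_fun))
  if (!death_state %in% states)
    stop("death state '", death_state, "' not among states", call. = FALSE)
  chk_rewards <- function(x, nm) {
    if (is.matrix(x)) {
      if (ncol(x) != S || nrow(x) != n_cycles)
        stop(nm, " matrix must be n_cycles x n_states", call. = FALSE)
    } else if (length(x) != S) {
      stop(nm, " must have one value per state", call. = FALSE)
    }
    x
  }
  state_costs <- chk_rewards(state_costs, "state_costs")
  state_utilities <- chk_rewards(state_utilities, "state_utilities")
  if (length(start) != S || any(start < 0) ||
      abs(sum(start) - 1) > 1e-9)
    stop("start distribution must be non-negative and sum to 1",
         call. = FALSE)
  if (n_cycles < 1) stop("horizon must be at least 1 cycle", call. = FALSE)
  if (!is.null(trans_rewards)) {
    stopifnot(is.data.frame(trans_rewards),
              all(c("from", "to") %in% names(trans_rewards)))
    idx <- function(x) if (is.character(x)) match(x, states) else as.integer(x)
    trans_rewards$from <- idx(trans_rewards$from)
    trans_rewards$to <- idx(trans_rewards$to)
    if (anyNA(trans_rewards$from) || anyNA(trans_rewards$to))
      stop("trans_rewards names unknown states", call. = FALSE)
    if (is.null(trans_rewards$cost)) trans_rewards$cost <- 0
    if (is.null(trans_rewards$qaly)) trans_rewards$qaly <- 0
  }
  zero_or <- function(x) if (is.null(x)) numeric(S) else {
    stopifnot(length(x) == S); x
  }
  structure(list(
    states = states, trans_fun = trans_fun,
    state_costs = state_costs, state_utilities = state_utilities,
    start = as.numeric(start), start_age = start_age,
    n_cycles = as.integer(n_cycles),
    trans_rewards = trans_rewards,
    init_costs = zero_or(init_costs), init_qalys = zero_or(init_qalys),
    death_state = death_state, death_index = match(death_state, states)
  ), class = "tka_cohort_model")
}

#' @export
print.tka_cohort_model <- function(x, ...) {
  cat("<tka_cohort_model> ", length(x$states), " states, horizon ",
      x$n_cycles, " cycles, start age ", x$start_age, "\n", sep = "")
  invisible(x)
}

check_transition_matrix <- function(m, model, cycle, tol = 1e-12) {
  S <- length(model$states)
  if (!is.matrix(m) || nrow(m) != S || ncol(m) != S)
    stop("transition matrix at cycle ", cycle, " is not ", S, "x", S,
         call. = FALSE)
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > tol | apply(m < -tol, 1, any))
  if (length(bad))
    stop("transition matrix at cycle ", cycle,
         " is not row-stochastic in row(s) ",
         paste(model$states[bad], collapse = ", "), call. = FALSE)
  d <- model$death_index
  if (abs(m[d, d] - 1) > tol)
    stop("death state is not absorbing at cycle ", cycle, call. = FALSE)
  invisible(TRUE)
}

#' Propagate a cohort through its model
#'
#' Runs the occupancy recursion `occ(t+1) = occ(t) %*% M(t)` from the start
#' distribution, recording occupancy, state inflows and the per-cycle
#' one-time reward streams implied by the model's transition rewards.
#' Propagation stops early once the living mass falls below `1e-12`
#' (full absorption); the trace is truncated at that point.
#'
#' @param model a [cohort_model()].
#' @param keep_flows record the full cycle-by-from-by-to flow array
#'   (defaults to `TRUE` for models with at most 30 states).
#' @return A list of class `tka_cohort_trace` with elements `occupancy`
#'   (`(T+1) x S` matrix, row `t+1` = start of cycle `t`), `inflow`
#'   (per-cycle arriving mass per state), `event_costs` / `event_qalys`
#'   (one-time rewards booked at each cycle, index `t+1` = cycle `t`),
#'   `ages`, `n_cycles` (the truncated horizon `T`) and optionally `flows`.
#' @export
propagate <- function(model, keep_flows = length(model$states) <= 30) {
  stopifnot(inherits(model, "tka_cohort_model"))
  S <- length(model$states)
  H <- model$n_cycles
  d <- model$death_index
  occ <- matrix(0, H + 1, S, dimnames = list(NULL, model$states))
  occ[1, ] <- model$start
  inflow <- matrix(0, H + 1, S, dimnames = list(NULL, model$states))
  event_costs <- numeric(H + 1)
  event_qalys <- numeric(H + 1)
  event_costs[1] <- sum(model$start * model$init_costs)
  event_qalys[1] <- sum(model$start * model$init_qalys)
  flows <- if (keep_flows) array(0, c(H, S, S)) else NULL
  tr <- model$trans_rewards
  m_prev <- NULL
  t_end <- H
  for (t in 0:(H - 1)) {
    age <- model$start_age + t / 12
    m <- model$trans_fun(t, age)
    if (is.null(m_prev) || !identical(m, m_prev))
      check_transition_matrix(m, model, t)
    m_prev <- m
    cur <- occ[t + 1, ]
    nxt <- as.numeric(cur %*% m)
    occ[t + 2, ] <- nxt
    inflow[t + 2, ] <- nxt - cur * diag(m)
    if (!is.null(tr) && nrow(tr)) {
      w <- cur[tr$from] * m[cbind(tr$from, tr$to)]
      event_costs[t + 2] <- sum(w * tr$cost)
      event_qalys[t + 2] <- sum(w * tr$qaly)
    }
    if (keep_flows) flows[t + 1, , ] <- cur * m
    if (1 - nxt[d] < 1e-12) { t_end <- t + 1; break }
  }
  keep <- seq_len(t_end + 1)
  structure(list(
    occupancy = occ[keep, , drop = FALSE],
    inflow = inflow[keep, , drop = FALSE],
    event_costs = event_costs[keep], event_qalys = event_qalys[keep],
    flows = if (keep_flows) flows[seq_len(t_end), , , drop = FALSE],
    ages = model$start_age + (seq_len(t_end + 1) - 1) / 12,
    n_cycles = t_end, states = model$states,
    death_index = d
  ), class = "tka_cohort_trace")
}

#' @export
print.tka_cohort_trace <- function(x, ...) {
  cat("<tka_cohort_trace> ", x$n_cycles, " cycles, ",
      length(x$states), " states, final death occupancy ",
      signif(x$occupancy[nrow(x$occupancy), x$death_index], 6), "\n",
      sep = "")
  invisible(x)
}

#' Accumulate discounted rewards over a cohort trace
#'
#' Cycle rewards accrue at one twelfth of the annual rate, based on
#' start-of-cycle occupancy (no half-cycle correction by default), and are
#' discounted at the per-cycle factor `(1 + discount_annual)^(-1/12)`.
#' One-time transition rewards are discounted at the cycle in which the
#' flow arrives.  With `half_cycle = TRUE` cycle rewards use the average
#' of start- and end-of-cycle occupancy instead.
#'
#' @param trace a trace from [propagate()].
#' @param model the model that produced it.
#' @param discount_annual annual discount rate.
#' @param half_cycle apply the half-cycle correction to cycle rewards.
#' @return A list of class `tka_run_result`: discounted `cost` and `qalys`,
#'   undiscounted `cost_undisc` / `qalys_undisc`, undiscounted `life_years`
#'   and the `trace`.
#' @export
accumulate <- function(trace, model, discount_annual, half_cycle = FALSE) {
  stopifnot(inherits(trace, "tka_cohort_trace"),
            inherits(model, "tka_cohort_model"))
  if (!identical(trace$states, model$states))
    stop("trace and model state spaces differ", call. = FALSE)
  TT <- trace$n_cycles
  occ <- trace$occupancy
  wocc <- if (half_cycle)
    (occ[seq_len(TT), , drop = FALSE] + occ[seq_len(TT) + 1, , drop = FALSE]) / 2
  else occ[seq_len(TT), , drop = FALSE]
  rate_at <- function(r) {
    if (is.matrix(r)) r[seq_len(TT), , drop = FALSE]
    else matrix(r, TT, length(r), byrow = TRUE)
  }
  cyc_cost <- rowSums(wocc * rate_at(model$state_costs)) / 12
  cyc_qaly <- rowSums(wocc * rate_at(model$state_utilities)) / 12
  v <- monthly_discount_factor(discount_annual)
  vt <- v^(0:TT)
  cost <- sum(vt[seq_len(TT)] * cyc_cost) + sum(vt * trace$event_costs)
  qalys <- sum(vt[seq_len(TT)] * cyc_qaly) + sum(vt * trace$event_qalys)
  alive <- 1 - wocc[, trace$death_index]
  structure(list(
    cost = cost, qalys = qalys,
    cost_undisc = sum(cyc_cost) + sum(trace$event_costs),
    qalys_undisc = sum(cyc_qaly) + sum(trace$event_qalys),
    life_years = sum(alive) / 12,
    discount_annual = discount_annual,
    trace = trace
  ), class = "tka_run_result")
}

#' Run a cohort model end to end
#'
#' Convenience composition of [propagate()] and [accumulate()].
#'
#' @inheritParams propagate
#' @inheritParams accumulate
#' @return A `tka_run_result`.
#' @export
run_model <- function(model, discount_annual, half_cycle = FALSE,
                      keep_flows = length(model$states) <= 30) {
  accumulate(propagate(model, keep_flows = keep_flows), model,
             discount_annual, half_cycle = half_cycle)
}

#' @export
print.tka_run_result <- function(x, ...) {
  cat(sprintf(paste0("<tka_run_result> discounted cost $%s, %.4f QALYs ",
                     "(undiscounted $%s, %.4f QALYs, %.2f life-years)\n"),
              format(round(x$cost), big.mark = ","), x$qalys,
              format(round(x$cost_undisc), big.mark = ","),
              x$qalys_undisc, x$life_years))
  invisible(x)
}

#' Export a cohort trace as a cycle-by-state CSV
#'
#' Writes one row per cycle with the cohort age and the occupancy of every
#' state.
#'
#' @param trace a `tka_cohort_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tka_cohort_trace"))
  df <- data.frame(cycle = seq_len(nrow(trace$occupancy)) - 1,
                   age = trace$ages)
  df <- cbind(df, as.data.frame(trace$occupancy))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
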