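# shared fixtures and a per-session cache so expensive full-model runs are
# computed once across test files

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

base_lt <- function() cached("lt", bundled_life_table())

base_params <- function(scenario = "A") {
  p <- parameter_set()
  p$scenario <- scenario
  validate_parameters(p)
}

base_runs <- function(scenario = "A") {
  cached(paste0("runs_", scenario),
         run_strategies(base_params(scenario), base_lt()))
}

# a lighter configuration (shorter lifespan) for sweep-style tests
short_params <- function(scenario = "A") {
  p <- parameter_set(max_age_years = 75, scenario = scenario)
  validate_parameters(p)
}

# deaths impossible until the age cap; isolates reward accounting
immortal_lt <- function(max_age = 110) {
  life_table(age = 0:max_age, qx = c(rep(0, max_age), 1))
}

# no revisions, no perioperative deaths, no complications
no_event_params <- function(...) {
  parameter_set(p_rev_primary_by_tier = c(0, 0, 0),
                p_rev_revision_by_tier = c(0, 0, 0),
                p_early_complication = 0, p_mort30_primary = 0,
                p_mort30_revision = 0, include_complications = FALSE, ...)
}

# simple two-state alive/dead engine model with constant monthly hazard
two_state_model <- function(q_monthly, u_annual = 0.6, c_annual = 0,
                            n_cycles = 60, init_costs = NULL,
                            trans_rewards = NULL) {
  m <- matrix(c(1 - q_monthly, q_monthly, 0, 1), 2, 2, byrow = TRUE)
  cohort_model(states = c("alive", "dead"),
               trans_fun = function(t, age) m,
               state_costs = c(c_annual, 0),
               state_utilities = c(u_annual, 0),
               start = c(1, 0), start_age = 60, n_cycles = n_cycles,
               trans_rewards = trans_rewards, init_costs = init_costs)
}

# random absorbing-chain model for property tests
random_model <- function(n_states = sample(3:6, 1), n_cycles = 60) {
  m <- matrix(stats::rexp(n_states^2), n_states)
  m[n_states, ] <- c(rep(0, n_states - 1), 1)
  m <- m / rowSums(m)
  start <- stats::rexp(n_states - 1)
  start <- c(start / sum(start), 0)
  cohort_model(states = c(paste0("s", seq_len(n_states - 1)), "dead"),
               trans_fun = function(t, age) m,
               state_costs = stats::runif(n_states, 0, 1000) *
                 c(rep(1, n_states - 1), 0),
               state_utilities = stats::runif(n_states) *
                 c(rep(1, n_states - 1), 0),
               start = start, start_age = 50, n_cycles = n_cycles)
}
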