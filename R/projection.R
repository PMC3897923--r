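#' Read a procedure-volume table
#'
#' CSV with header `year,volume`: projected annual primary TKA counts.
#' Volume projections are a user input (e.g. published demand
#' projections); the package bundles only a clearly-labelled synthetic
#' illustration, `volumes_synthetic.csv` under `extdata`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `year`, `volume`.
#' @export
read_volume_table <- function(path) {
  if (!file.exists(path))
    stop("volume table not found: ", path, call. = FALSE)
  v <- utils::read.csv(path)
  if (!all(c("year", "volume") %in% names(v)))
    stop("volume table CSV must have header columns 'year' and 'volume'",
         call. = FALSE)
  validate_volume_table(v)
}

validate_volume_table <- function(v) {
  stopifnot(is.data.frame(v), all(c("year", "volume") %in% names(v)))
  if (nrow(v) < 1) stop("volume table is empty", call. = FALSE)
  if (anyDuplicated(v$year)) stop("duplicate years in volume table",
                                  call. = FALSE)
  if (any(v$volume < 0)) stop("negative procedure volume", call. = FALSE)
  v[order(v$year), c("year", "volume")]
}

#' Per-patient incremental cost and QALYs of delaying TKA
#'
#' Runs the delayed strategy at the given wait time and the immediate
#' strategy under the same cost scenario, and reports the per-patient
#' incrementals: `inc_cost` is the extra discounted cost of delaying
#' (`cost_delayed - cost_immediate`) and `inc_qalys` the discounted QALYs
#' gained by operating without delay (`qalys_immediate - qalys_delayed`).
#'
#' @param params base `tka_parameters`.
#' @param life_table a `tka_life_table`.
#' @param wait_months wait before TKA, in \eqn{[0, 60]} months.
#' @param strategy which delayed strategy, `"delay_bridge"` or
#'   `"delay_no_bridge"`.
#' @param scenario cost scenario override (`"A"` or `"B"`); default takes
#'   the scenario from `params`.
#' @return A list with `inc_cost` ($) and `inc_qalys` (QALY).
#' @export
per_patient_incremental <- function(params, life_table, wait_months,
                                    strategy = c("delay_bridge",
                                                 "delay_no_bridge"),
                                    scenario = NULL) {
  strategy <- match.arg(strategy)
  if (wait_months < 0 || wait_months > 60)
    stop("wait_months must lie in [0, 60]", call. = FALSE)
  p <- set_parameter(params, "wait_months", wait_months)
  if (!is.null(scenario)) p$scenario <- scenario
  p <- validate_parameters(p)
  imm <- run_strategy("immediate_tka", p, life_table)
  del <- run_strategy(strategy, p, life_table)
  list(inc_cost = del$cost - imm$cost, inc_qalys = imm$qalys - del$qalys)
}

#' Population-level cost and QALY projection
#'
#' Scales the per-patient incrementals of a wait time by projected annual
#' procedure volumes.  Each calendar year's cohort is valued at its own
#' start: totals are not discounted across calendar years.
#'
#' @inheritParams per_patient_incremental
#' @param volumes data frame with columns `year` and `volume` (see
#'   [read_volume_table()]).
#' @return A data frame with columns `year`, `volume`, `inc_cost`,
#'   `inc_qalys` (totals per calendar year).
#' @export
population_projection <- function(volumes, params, life_table, wait_months,
                                  strategy = c("delay_bridge",
                                               "delay_no_bridge"),
                                  scenario = NULL) {
  volumes <- validate_volume_table(volumes)
  per <- per_patient_incremental(params, life_table, wait_months,
                                 strategy = match.arg(strategy),
                                 scenario = scenario)
  data.frame(year = volumes$year, volume = volumes$volume,
             inc_cost = volumes$volume * per$inc_cost,
             inc_qalys = volumes$volume * per$inc_qalys)
}
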