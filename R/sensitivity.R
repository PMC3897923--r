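#' Locate a switch point by bisection
#'
#' Finds the value of a scalar input at which a logical predicate flips,
#' to within an absolute tolerance.  The predicate must differ at the two
#' bracket endpoints; otherwise a no-crossing error is raised rather than
#' a value guessed.
#'
#' @param predicate function of one numeric argument returning `TRUE` or
#'   `FALSE`.
#' @param lower,upper bracket endpoints.
#' @param tol absolute tolerance on the returned value.
#' @return Midpoint of the final bracket (within `tol` of the flip).
#' @examples
#' bisect_threshold(function(x) x > 5, 0, 10, tol = 1e-6)
#' @export
bisect_threshold <- function(predicate, lower, upper, tol = 0.01) {
  stopifnot(lower < upper, tol > 0)
  pl <- isTRUE(predicate(lower))
  pu <- isTRUE(predicate(upper))
  if (pl == pu)
    stop("predicate does not change over [", lower, ", ", upper,
         "]: no crossing to locate", call. = FALSE)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (isTRUE(predicate(mid)) == pl) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' Threshold analysis on a named model parameter
#'
#' Bisects a parameter (addressed as in [set_parameter()], so derived
#' names like `c_indirect_oa_monthly` work) for the value at which a
#' strategy-comparison predicate flips.
#'
#' @param params base `tka_parameters`.
#' @param life_table a `tka_life_table`.
#' @param param parameter name to vary.
#' @param predicate function of a named list of `tka_run_result` (one per
#'   requested strategy) returning a logical.
#' @param bracket length-2 numeric search interval.
#' @param tol absolute tolerance.
#' @param strategies strategies the predicate needs (fewer runs = faster).
#' @return The switch-point value of `param`.
#' @export
threshold_parameter <- function(params, life_table, param, predicate,
                                bracket, tol = 0.01,
                                strategies = tka_strategies()) {
  bisect_threshold(function(x) {
    p <- set_parameter(params, param, x)
    predicate(run_strategies(p, life_table, strategies = strategies))
  }, bracket[1], bracket[2], tol = tol)
}

#' Paper-style switch-point analyses
#'
#' Four canned threshold analyses on the base-case comparison:
#' \describe{
#'   \item{`threshold_indirect_monthly()`}{the monthly indirect OA cost
#'     above which immediate TKA is cheaper than the delayed strategy when
#'     indirect costs are counted (societal scenario).  The comparator is
#'     the cheaper delayed strategy, delay without bridge; against the
#'     bridge strategy immediate TKA is already cheaper at zero indirect
#'     cost, so no switch point exists.}
#'   \item{`threshold_bridge_monthly()`}{the monthly bridge cost below
#'     which the delay-with-bridge strategy is cheaper than immediate TKA
#'     (direct-cost scenario).}
#'   \item{`threshold_indirect_recovery()`}{the fraction of indirect OA
#'     costs that TKA must eliminate for immediate TKA to be cheaper than
#'     delaying (societal scenario).}
#'   \item{`threshold_bridge_relief()`}{the months of symptomatic relief
#'     that make the bridge cost-effective relative to waiting untreated
#'     (net-benefit comparison of the two delayed strategies at `wtp`).}
#' }
#'
#' @param params base `tka_parameters`.
#' @param life_table a `tka_life_table`.
#' @param bracket search interval (units of the varied quantity).
#' @param tol absolute tolerance.
#' @param wtp willingness to pay per QALY (relief threshold only).
#' @return The switch-point value ($/month, fraction, or months).
#' @name thresholds
NULL

#' @rdname thresholds
#' @export
threshold_indirect_monthly <- function(params, life_table,
                                       bracket = c(0, 857), tol = 0.01) {
  params$scenario <- "B"
  threshold_parameter(params, life_table, "c_indirect_oa_monthly",
                      function(r) r$immediate_tka$cost < r$delay_no_bridge$cost,
                      bracket, tol,
                      strategies = c("immediate_tka", "delay_no_bridge"))
}

#' @rdname thresholds
#' @export
threshold_bridge_monthly <- function(params, life_table,
                                     bracket = c(0, 500), tol = 0.01) {
  params$scenario <- "A"
  threshold_parameter(params, life_table, "c_bridge_monthly",
                      function(r) r$delay_bridge$cost < r$immediate_tka$cost,
                      bracket, tol,
                      strategies = c("immediate_tka", "delay_bridge"))
}

#' @rdname thresholds
#' @export
threshold_indirect_recovery <- function(params, life_table,
                                        bracket = c(0, 1), tol = 0.001) {
  params$scenario <- "B"
  threshold_parameter(params, life_table, "indirect_recovery_fraction",
                      function(r) r$immediate_tka$cost < r$delay_no_bridge$cost,
                      bracket, tol,
                      strategies = c("immediate_tka", "delay_no_bridge"))
}

#' @rdname thresholds
#' @export
threshold_bridge_relief <- function(params, life_table,
                                    bracket = c(0.75, NA), tol = 0.01,
                                    wtp = 50000) {
  if (is.na(bracket[2])) bracket[2] <- params$wait_months
  threshold_parameter(params, life_table, "bridge_relief_months",
                      function(r) {
                        net_benefit(r$delay_bridge$cost,
                                    r$delay_bridge$qalys, wtp)$nmb >=
                          net_benefit(r$delay_no_bridge$cost,
                                      r$delay_no_bridge$qalys, wtp)$nmb
                      },
                      bracket, tol,
                      strategies = c("delay_bridge", "delay_no_bridge"))
}

#' One- to three-way deterministic sensitivity sweep
#'
#' Re-runs the full model at every point of a rectangular grid over up to
#' three named parameters and records each strategy's discounted cost,
#' QALYs and net monetary benefit plus the preferred strategy at `wtp`.
#' The grid covers each range inclusively at `n_points` per axis.
#'
#' @param params base `tka_parameters`.
#' @param life_table a `tka_life_table`.
#' @param vary named list (1--3 entries) of `c(low, high)` ranges;
#'   parameter names as in [set_parameter()].
#' @param n_points grid points per axis (>= 1; a zero-width range
#'   requires `n_points = 1`).
#' @param wtp willingness to pay per QALY.
#' @return A data frame: one row per grid point, the varied parameter
#'   values, `<strategy>_cost`, `<strategy>_qalys`, `<strategy>_nmb`
#'   columns and `preferred`.
#' @export
sweep_parameters <- function(params, life_table, vary, n_points = 5,
                             wtp = 50000) {
  stopifnot(is.list(vary), length(vary) >= 1)
  if (length(vary) > 3)
    stop("at most three parameters can be swept jointly", call. = FALSE)
  axes <- lapply(names(vary), function(nm) {
    r <- vary[[nm]]
    stopifnot(length(r) == 2)
    get_parameter(params, nm)  # errors if unknown
    if (r[1] == r[2] && n_points > 1)
      stop("zero-width range for '", nm, "' with n_points > 1",
           call. = FALSE)
    if (n_points == 1) mean(r) else seq(r[1], r[2], length.out = n_points)
  })
  names(axes) <- names(vary)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    for (nm in names(vary)) p <- set_parameter(p, nm, grid[i, nm])
    runs <- run_strategies(p, life_table)
    cea <- build_cea_table(results_table(runs), wtp = wtp)
    row <- list()
    for (s in names(runs)) {
      row[[paste0(s, "_cost")]] <- runs[[s]]$cost
      row[[paste0(s, "_qalys")]] <- runs[[s]]$qalys
      row[[paste0(s, "_nmb")]] <-
        net_benefit(runs[[s]]$cost, runs[[s]]$qalys, wtp)$nmb
    }
    row$preferred <- attr(cea, "preferred")
    as.data.frame(row)
  })
  cbind(grid, do.call(rbind, res))
}

#' Wait-time sweep with net benefits as the outcome
#'
#' Evaluates both delayed strategies over a list of wait times (months,
#' snapped to whole cycles) and reports, per wait time and strategy, the
#' discounted cost and QALYs, the net health benefit at `wtp`, and the
#' incrementals against immediate TKA: `d_cost` is the extra cost of
#' delaying (`cost - cost_immediate`) and `d_qalys` the QALYs forgone
#' (`qalys_immediate - qalys`).
#'
#' @param params base `tka_parameters`.
#' @param life_table a `tka_life_table`.
#' @param months wait times in months, within \eqn{[0, 60]}.
#' @param wtp willingness to pay per QALY.
#' @return A long data frame with columns `wait_months` (as requested),
#'   `strategy`, `cost`, `qalys`, `nhb`, `d_cost`, `d_qalys`; the
#'   immediate strategy appears once per wait time as its own rows with
#'   zero incrementals.
#' @export
wait_time_sweep <- function(params, life_table,
                            months = c(0.75, seq(6, 60, by = 6)),
                            wtp = 50000) {
  if (any(months < 0)) stop("negative wait time", call. = FALSE)
  if (any(months > 60)) stop("wait times above 60 months are not part of ",
                             "the analysis grid", call. = FALSE)
  imm <- run_strategy("immediate_tka", params, life_table)
  rows <- lapply(months, function(m) {
    p <- set_parameter(params, "wait_months", m)
    out <- lapply(c("delay_bridge", "delay_no_bridge"), function(s) {
      r <- run_strategy(s, p, life_table)
      data.frame(wait_months = m, strategy = s, cost = r$cost,
                 qalys = r$qalys,
                 nhb = net_benefit(r$cost, r$qalys, wtp)$nhb,
                 d_cost = r$cost - imm$cost,
                 d_qalys = imm$qalys - r$qalys)
    })
    rbind(data.frame(wait_months = m, strategy = "immediate_tka",
                     cost = imm$cost, qalys = imm$qalys,
                     nhb = net_benefit(imm$cost, imm$qalys, wtp)$nhb,
                     d_cost = 0, d_qalys = 0),
          do.call(rbind, out))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
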