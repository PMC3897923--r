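#' Construct and validate a model parameter set
#'
#' A `tka_parameters` object holds every quantity the decision model needs:
#' annual health-state utilities, one-time disutilities, annual transition
#' probabilities, procedure and disease costs, the surgical wait, run
#' settings (cohort age, discount rate, cost scenario) and the optional
#' behavioural toggles.  All utilities are annual quality weights in
#' \eqn{[0, 1]}; disutilities are one-time QALY deductions in \eqn{[-1, 0]};
#' costs are US dollars.
#'
#' @param ... named parameter values overriding the base-case defaults
#'   returned by [default_parameters()].
#'
#' @section Fields:
#' \describe{
#'   \item{u_oa, u_oa_bridge, u_tka, u_rev}{annual utilities of end-stage
#'     knee OA, OA with a non-operative treatment bridge, primary TKA and
#'     revision TKA.  `u_oa_bridge` may be `NA`, in which case the bridge
#'     utility is derived as
#'     `u_oa + bridge_utility_improvement * (u_tka - u_oa)`.}
#'   \item{dis_rev, dis_complication}{one-time QALY deductions for recovery
#'     from revision TKA and from an early TKA complication.}
#'   \item{p_early_complication}{annual probability of an early complication
#'     after primary TKA.}
#'   \item{p_rev_primary_by_tier, p_rev_revision_by_tier}{annual revision
#'     probabilities for implant-age tiers 0--9, 10--19 and 20+ years
#'     (length-3 numeric, non-decreasing).}
#'   \item{p_mort30_primary, p_mort30_revision}{30-day excess mortality of
#'     the primary and revision procedures, applied in the single
#'     post-operative month.}
#'   \item{wait_months}{months spent in the waiting state before surgery
#'     in the delayed strategies (snapped to whole cycles).}
#'   \item{c_indirect_oa_annual, c_bridge_annual, c_tka, c_rev}{annual
#'     indirect cost of end-stage knee OA, annual direct cost of the
#'     non-operative bridge, and one-time costs of the primary and revision
#'     TKA episodes (each episode cost covers the first 90 days).}
#'   \item{indirect_recovery_fraction}{fraction of the indirect OA cost
#'     eliminated after successful TKA (societal scenario only).}
#'   \item{bridge_utility_improvement}{fractional closure of the
#'     OA-to-TKA utility gap attributed to the bridge, used when
#'     `u_oa_bridge` is `NA` or when sweeping the bridge effect.}
#'   \item{bridge_relief_months}{duration (months, may be fractional) of
#'     the bridge's symptomatic relief within the wait; `NA` means the
#'     relief lasts for the entire wait.}
#'   \item{discount_annual}{annual discount rate applied to both costs and
#'     QALYs.}
#'   \item{cohort_age_years}{age of the cohort at model start.}
#'   \item{scenario}{`"A"` (direct medical costs only) or `"B"` (direct
#'     plus indirect, the societal perspective).}
#'   \item{max_age_years}{horizon cap; the annual death probability is
#'     forced to 1 at this age.}
#'   \item{include_complications}{logical; when `TRUE` the expected
#'     one-time complication disutility
#'     `p_early_complication * dis_complication` is charged at primary
#'     TKA.}
#' }
#'
#' @return A validated list of class `tka_parameters`.
#' @examples
#' p <- parameter_set(wait_months = 12, scenario = "B")
#' p$wait_months
#' @export
parameter_set <- function(...) {
  p <- default_parameters()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all arguments to parameter_set() must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(dots)] <- dots
  }
  validate_parameters(p)
}

#' Base-case parameter values
#'
#' Returns the base-case parameter set: utilities 0.6 (OA), 0.7 (OA with
#' bridge), 0.9 (primary TKA), 0.85 (revision TKA); disutilities -0.1
#' (revision recovery) and -0.20 (early complication); annual revision
#' probabilities 0.005/0.01/0.02 (primary) and 0.01/0.02/0.04 (revision)
#' across implant-age tiers; 30-day mortality 0.007/0.01; a 24-month wait;
#' costs $10,369 (indirect OA, annual), $2,500 (bridge, annual), $26,865
#' (primary TKA) and $35,542 (revision TKA); 3% annual discounting; a
#' 60-year-old cohort.
#'
#' @return A `tka_parameters` list (unvalidated; see [parameter_set()]).
#' @export
default_parameters <- function() {
  structure(list(
    u_oa = 0.6,
    u_oa_bridge = 0.7,
    u_tka = 0.9,
    u_rev = 0.85,
    dis_rev = -0.1,
    dis_complication = -0.20,
    p_early_complication = 0.01,
    p_rev_primary_by_tier = c(0.005, 0.01, 0.02),
    p_rev_revision_by_tier = c(0.01, 0.02, 0.04),
    p_mort30_primary = 0.007,
    p_mort30_revision = 0.01,
    wait_months = 24,
    c_indirect_oa_annual = 10369,
    c_bridge_annual = 2500,
    c_tka = 26865,
    c_rev = 35542,
    indirect_recovery_fraction = 0.80,
    bridge_utility_improvement = 0.33,
    bridge_relief_months = NA_real_,
    discount_annual = 0.03,
    cohort_age_years = 60,
    scenario = "A",
    max_age_years = 110,
    include_complications = TRUE
  ), class = "tka_parameters")
}

required_parameter_keys <- function() {
  c("u_oa", "u_tka", "u_rev", "dis_rev", "dis_complication",
    "p_early_complication", "p_rev_primary_by_tier",
    "p_rev_revision_by_tier", "p_mort30_primary", "p_mort30_revision",
    "wait_months", "c_indirect_oa_annual", "c_bridge_annual",
    "c_tka", "c_rev")
}

#' @rdname parameter_set
#' @param params a candidate parameter list.
#' @export
validate_parameters <- function(params) {
  stopifnot(is.list(params))
  chk_range <- function(nm, lo, hi, len = 1) {
    x <- params[[nm]]
    if (is.null(x) || length(x) != len || !is.numeric(x) || anyNA(x))
      stop("parameter '", nm, "' must be numeric of length ", len,
           call. = FALSE)
    if (any(x < lo) || any(x > hi))
      stop("parameter '", nm, "' = ", paste(signif(x, 6), collapse = "/"),
           " outside [", lo, ", ", hi, "]", call. = FALSE)
    invisible(x)
  }
  for (u in c("u_oa", "u_tka", "u_rev")) chk_range(u, 0, 1)
  if (!is.null(params$u_oa_bridge) && !is.na(params$u_oa_bridge))
    chk_range("u_oa_bridge", 0, 1)
  for (d in c("dis_rev", "dis_complication")) chk_range(d, -1, 0)
  chk_range("p_early_complication", 0, 1)
  chk_range("p_rev_primary_by_tier", 0, 1, len = 3)
  chk_range("p_rev_revision_by_tier", 0, 1, len = 3)
  for (tiers in c("p_rev_primary_by_tier", "p_rev_revision_by_tier"))
    if (is.unsorted(params[[tiers]]))
      stop("parameter '", tiers, "' must be non-decreasing across ",
           "implant-age tiers", call. = FALSE)
  chk_range("p_mort30_primary", 0, 1)
  chk_range("p_mort30_revision", 0, 1)
  chk_range("wait_months", 0, Inf)
  for (cc in c("c_indirect_oa_annual", "c_bridge_annual", "c_tka", "c_rev"))
    chk_range(cc, 0, Inf)
  chk_range("indirect_recovery_fraction", 0, 1)
  chk_range("bridge_utility_improvement", 0, 1)
  if (!is.na(params$bridge_relief_months))
    chk_range("bridge_relief_months", 0, Inf)
  chk_range("discount_annual", 0, Inf)
  chk_range("cohort_age_years", 0, Inf)
  chk_range("max_age_years", params$cohort_age_years, Inf)
  if (!params$scenario %in% c("A", "B"))
    stop("parameter 'scenario' must be \"A\" (direct costs only) or ",
         "\"B\" (direct + indirect)", call. = FALSE)
  if (!is.logical(params$include_complications) ||
      length(params$include_complications) != 1)
    stop("parameter 'include_complications' must be TRUE or FALSE",
         call. = FALSE)
  class(params) <- "tka_parameters"
  params
}

#' @export
print.tka_parameters <- function(x, ...) {
  cat("<tka_parameters>\n")
  cat(sprintf("  cohort age %g y, wait %g mo, scenario %s, discount %g/y\n",
              x$cohort_age_years, x$wait_months, x$scenario,
              x$discount_annual))
  cat(sprintf("  utilities: OA %.2f, bridge %s, TKA %.2f, revision %.2f\n",
              x$u_oa,
              if (is.na(x$u_oa_bridge)) "derived" else
                sprintf("%.2f", x$u_oa_bridge),
              x$u_tka, x$u_rev))
  cat(sprintf("  costs: TKA $%s, revision $%s, bridge $%s/y, indirect $%s/y\n",
              format(x$c_tka, big.mark = ","),
              format(x$c_rev, big.mark = ","),
              format(x$c_bridge_annual, big.mark = ","),
              format(x$c_indirect_oa_annual, big.mark = ",")))
  invisible(x)
}

#' Load a parameter configuration file
#'
#' Reads a YAML configuration whose keys are exactly the
#' [parameter_set()] field names.  The core disease/treatment quantities
#' (utilities, disutilities, transition probabilities, wait and costs) are
#' required; run settings (discount rate, cohort age, scenario, toggles)
#' default to the base case when absent.  An optional `sensitivity` block
#' (a list of `parameter`/`low`/`high` maps) is returned as the
#' `"sensitivity"` attribute, a data frame with that shape.
#'
#' @param path path to a YAML configuration file.
#' @return A validated `tka_parameters` object.
#' @seealso [write_parameters()], [default_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg))
    stop("configuration file does not parse to a key/value map: ", path,
         call. = FALSE)
  sens <- NULL
  if (!is.null(cfg$sensitivity)) {
    sens <- do.call(rbind, lapply(cfg$sensitivity, function(r) {
      if (is.null(r$parameter) || is.null(r$low) || is.null(r$high))
        stop("each sensitivity entry needs 'parameter', 'low' and 'high'",
             call. = FALSE)
      data.frame(parameter = r$parameter, low = as.numeric(r$low),
                 high = as.numeric(r$high))
    }))
    cfg$sensitivity <- NULL
  }
  missing <- setdiff(required_parameter_keys(), names(cfg))
  if (length(missing))
    stop("configuration ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (k in c("p_rev_primary_by_tier", "p_rev_revision_by_tier"))
    cfg[[k]] <- as.numeric(unlist(cfg[[k]]))
  p <- do.call(parameter_set, cfg)
  message("read ", length(cfg), " parameter keys from ", path)
  if (!is.null(sens)) {
    validate_sensitivity_ranges(sens, p)
    attr(p, "sensitivity") <- sens
  }
  p
}

#' Write a parameter set (and optional sensitivity ranges) to YAML
#'
#' Round-trips with [load_parameters()].
#'
#' @param params a `tka_parameters` object.
#' @param path output file path.
#' @param ranges optional data frame of sensitivity ranges
#'   (`parameter`, `low`, `high`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path, ranges = attr(params, "sensitivity")) {
  params <- validate_parameters(params)
  out <- unclass(params)
  attr(out, "sensitivity") <- NULL
  if (!is.null(ranges))
    out$sensitivity <- lapply(seq_len(nrow(ranges)), function(i)
      list(parameter = ranges$parameter[i], low = ranges$low[i],
           high = ranges$high[i]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Sensitivity ranges for the base-case parameters
#'
#' The one-way ranges over which each parameter is varied in deterministic
#' sensitivity analysis.  Tiered revision probabilities use the suffixed
#' names understood by [set_parameter()] (e.g. `p_rev_primary_tier1`).
#'
#' @return A data frame with columns `parameter`, `low`, `high`.
#' @export
default_sensitivity_ranges <- function() {
  data.frame(
    parameter = c("u_oa", "u_oa_bridge", "u_tka", "u_rev",
                  "dis_rev", "dis_complication", "p_early_complication",
                  "p_rev_primary_tier1", "p_rev_primary_tier2",
                  "p_rev_primary_tier3", "p_rev_revision_tier1",
                  "p_rev_revision_tier2", "p_rev_revision_tier3",
                  "p_mort30_primary", "p_mort30_revision", "wait_months",
                  "c_indirect_oa_annual", "c_bridge_annual", "c_tka",
                  "c_rev"),
    low  = c(0.4, 0.6, 0.6, 0.6, -0.25, -0.40, 0,
             0, 0, 0, 0, 0, 0, 0, 0, 0.75,
             0, 0, 20000, 30000),
    high = c(0.8, 0.9, 0.9, 0.9, 0, 0, 0.05,
             0.02, 0.05, 0.05, 0.04, 0.08, 0.10, 0.014, 0.02, 60,
             20000, 3883, 30000, 40000)
  )
}

validate_sensitivity_ranges <- function(ranges, params = NULL) {
  stopifnot(is.data.frame(ranges),
            all(c("parameter", "low", "high") %in% names(ranges)))
  if (any(ranges$low > ranges$high))
    stop("sensitivity range with low > high for: ",
         paste(ranges$parameter[ranges$low > ranges$high], collapse = ", "),
         call. = FALSE)
  if (!is.null(params)) {
    for (i in seq_len(nrow(ranges))) {
      base <- try(get_parameter(params, ranges$parameter[i]), silent = TRUE)
      if (inherits(base, "try-error"))
        stop("sensitivity range names unknown parameter: ",
             ranges$parameter[i], call. = FALSE)
      if (!is.na(base) && (base < ranges$low[i] || base > ranges$high[i]))
        stop("base value of '", ranges$parameter[i],
             "' lies outside its sensitivity range", call. = FALSE)
    }
  }
  invisible(ranges)
}

# --- probability / discount plumbing ---------------------------------------

#' Convert an annual probability to a monthly (per-cycle) probability
#'
#' Uses the constant-hazard conversion \eqn{1 - (1 - p)^{1/12}}, so that
#' compounding the monthly probability over 12 cycles recovers the annual
#' probability exactly.
#'
#' @param p_annual annual probability (vectorised), in \eqn{[0, 1]}.
#' @return Monthly probability of the same event.
#' @examples
#' annual_to_monthly_prob(0.005)
#' @export
annual_to_monthly_prob <- function(p_annual) {
  if (any(p_annual < 0 | p_annual > 1, na.rm = TRUE) || anyNA(p_annual))
    stop("annual probability outside [0, 1]", call. = FALSE)
  1 - (1 - p_annual)^(1 / 12)
}

#' Per-cycle discount factor from an annual rate
#'
#' Discounting compounds monthly: the per-cycle factor is
#' \eqn{(1 + r)^{-1/12}}, so 12 cycles equal one annual discount step.
#'
#' @param annual_rate annual discount rate (\eqn{\ge 0}).
#' @return The per-cycle (monthly) discount factor.
#' @examples
#' monthly_discount_factor(0.03)^12  # = 1 / 1.03
#' @export
monthly_discount_factor <- function(annual_rate) {
  if (length(annual_rate) != 1 || is.na(annual_rate) || annual_rate < 0)
    stop("annual discount rate must be a single number >= 0", call. = FALSE)
  (1 + annual_rate)^(-1 / 12)
}

# --- parameter addressing for sweeps/thresholds ----------------------------

#' Get or set a (possibly derived) scalar parameter by name
#'
#' Sweeps and threshold searches address parameters by name.  Besides the
#' plain [parameter_set()] fields these helpers understand the tier
#' components `p_rev_primary_tier1..3` / `p_rev_revision_tier1..3` and the
#' monthly cost aliases `c_indirect_oa_monthly` / `c_bridge_monthly`
#' (stored annually, scaled by 12).
#'
#' @param params a `tka_parameters` object.
#' @param name parameter name.
#' @param value replacement value (for `set_parameter`).
#' @return `get_parameter`: the scalar value; `set_parameter`: the updated,
#'   re-validated parameter set.
#' @export
set_parameter <- function(params, name, value) {
  validate_parameters(set_parameter_raw(params, name, value))
}

set_parameter_raw <- function(params, name, value) {
  tier <- regmatches(name, regexec("^(p_rev_(primary|revision))_tier([123])$",
                                   name))[[1]]
  if (length(tier)) {
    field <- paste0(tier[2], "_by_tier")
    params[[field]][as.integer(tier[4])] <- value
  } else if (name == "c_indirect_oa_monthly") {
    params$c_indirect_oa_annual <- 12 * value
  } else if (name == "c_bridge_monthly") {
    params$c_bridge_annual <- 12 * value
  } else if (name %in% names(params)) {
    params[[name]] <- value
  } else {
    stop("unknown parameter name: ", name, call. = FALSE)
  }
  params
}

#' @rdname set_parameter
#' @export
get_parameter <- function(params, name) {
  tier <- regmatches(name, regexec("^(p_rev_(primary|revision))_tier([123])$",
                                   name))[[1]]
  if (length(tier))
    return(params[[paste0(tier[2], "_by_tier")]][as.integer(tier[4])])
  if (name == "c_indirect_oa_monthly")
    return(params$c_indirect_oa_annual / 12)
  if (name == "c_bridge_monthly")
    return(params$c_bridge_annual / 12)
  if (!name %in% names(params))
    stop("unknown parameter name: ", name, call. = FALSE)
  params[[name]]
}

#' Effective utility of the waiting state under the treatment bridge
#'
#' The explicit bridge utility is used when configured; otherwise the
#' bridge is assumed to close a fraction `bridge_utility_improvement` of
#' the OA-to-TKA utility gap.
#'
#' @param params a `tka_parameters` object.
#' @return Annual utility of OA with the non-operative bridge.
#' @export
bridge_utility <- function(params) {
  if (!is.null(params$u_oa_bridge) && !is.na(params$u_oa_bridge))
    params$u_oa_bridge
  else
    params$u_oa + params$bridge_utility_improvement *
      (params$u_tka - params$u_oa)
}
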