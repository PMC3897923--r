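#' Generate a parametric (Gompertz) life table
#'
#' Background mortality follows a Gompertz hazard: the annual death
#' probability at age \eqn{x} is \eqn{q(x) = 1 - \exp(-a e^{b x})}, clamped
#' to \eqn{[0, 1]}, with \eqn{q} forced to 1 at `max_age`.  The defaults
#' (`a = 4.1521e-5`, `b = 0.09`) are calibrated so that life expectancy at
#' age 60 is about 22.6 years, in line with a US 2009 all-sex period table;
#' see [bundled_life_table()] for the fixture generated from them.
#'
#' @param a baseline annual hazard at age 0 (> 0).
#' @param b exponential age coefficient per year (>= 0); `b = 0` gives an
#'   age-independent hazard.
#' @param max_age last age in the table (years, >= 1); certain death.
#' @return A `tka_life_table` covering ages `0:max_age`.
#' @examples
#' lt <- gompertz_life_table()
#' lt$qx[lt$age == 60]
#' @export
gompertz_life_table <- function(a = 4.1521e-5, b = 0.09, max_age = 110) {
  if (length(a) != 1 || is.na(a) || a <= 0)
    stop("Gompertz 'a' must be a single value > 0", call. = FALSE)
  if (length(b) != 1 || is.na(b) || b < 0)
    stop("Gompertz 'b' must be a single value >= 0", call. = FALSE)
  if (length(max_age) != 1 || is.na(max_age) || max_age < 1)
    stop("'max_age' must be >= 1", call. = FALSE)
  ages <- 0:max_age
  q <- pmin(pmax(1 - exp(-a * exp(b * ages)), 0), 1)
  q[length(q)] <- 1
  life_table(age = ages, qx = q)
}

#' Draw parameter sets uniformly over sensitivity ranges
#'
#' Each listed parameter is drawn independently and uniformly in
#' `[low, high]`; unlisted parameters keep their base value.  Intended for
#' scenario exploration and property tests — the decision model itself is
#' deterministic.
#'
#' @param base a `tka_parameters` object.
#' @param ranges data frame with columns `parameter`, `low`, `high`
#'   (default: [default_sensitivity_ranges()]); names may use the derived
#'   forms understood by [set_parameter()].
#' @param n number of parameter sets to draw (>= 1).
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return A list of `n` validated `tka_parameters` objects.
#' @export
sample_parameter_sets <- function(base, ranges = default_sensitivity_ranges(),
                                  n = 1, seed = 1) {
  stopifnot(n >= 1)
  validate_sensitivity_ranges(ranges)
  for (nm in ranges$parameter) get_parameter(base, nm)  # errors if unknown
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- matrix(stats::runif(n * nrow(ranges)), nrow = n)
  lapply(seq_len(n), function(i) {
    p <- unclass(base)
    for (j in seq_len(nrow(ranges))) {
      v <- ranges$low[j] + draws[i, j] * (ranges$high[j] - ranges$low[j])
      p <- unclass(set_parameter_raw(p, ranges$parameter[j], v))
    }
    # independent tier draws may cross; restore the non-decreasing tier
    # invariant (cummax keeps every value inside its own range because the
    # range upper bounds themselves are non-decreasing)
    for (f in c("p_rev_primary_by_tier", "p_rev_revision_by_tier"))
      p[[f]] <- cummax(p[[f]])
    validate_parameters(p)
  })
}

#' A miniature configuration with closed-form lifetime totals
#'
#' Returns a parameter set and life table for which the cohort engine's
#' output has a simple closed form: constant annual mortality
#' `q = 0.12` at every age (certain death at the age cap), zero
#' discounting, no revisions, no perioperative mortality and no
#' complications.  For the immediate-TKA strategy the undiscounted QALY
#' total is then a finite geometric series in the monthly survival
#' \eqn{s = 0.88^{1/12}}:
#' \eqn{(u_{TKA}/12)\sum_{t} s^t}.
#'
#' @param q constant annual death probability.
#' @param max_age age of certain death.
#' @return A list with elements `params` and `life_table`.
#' @export
toy_fixture <- function(q = 0.12, max_age = 110) {
  lt <- life_table(age = 0:max_age, qx = c(rep(q, max_age), 1))
  params <- parameter_set(
    p_rev_primary_by_tier = c(0, 0, 0),
    p_rev_revision_by_tier = c(0, 0, 0),
    p_early_complication = 0,
    p_mort30_primary = 0,
    p_mort30_revision = 0,
    include_complications = FALSE,
    discount_annual = 0,
    max_age_years = max_age
  )
  list(params = params, life_table = lt)
}
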