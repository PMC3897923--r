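#' Cost-effectiveness ratio
#'
#' The average cost per QALY of a single strategy, `cost / qalys`.
#'
#' @param cost discounted total cost ($).
#' @param qalys discounted total QALYs (> 0 unless cost is 0).
#' @return Dollars per QALY.
#' @export
ce_ratio <- function(cost, qalys) {
  if (any(qalys <= 0 & cost != 0))
    stop("cost-effectiveness ratio undefined for non-positive QALYs",
         call. = FALSE)
  ifelse(cost == 0, 0, cost / qalys)
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' Computes `(cost_a - cost_b) / (qalys_a - qalys_b)` when the two
#' strategies trade off cost against effectiveness, and reports dominance
#' when one of them is at least as cheap and at least as effective (with
#' one strict).  Equal QALYs with unequal costs are reported as dominance
#' by the cheaper strategy, never as a division by zero.
#'
#' @param a,b lists (or one-row data frames) with elements `strategy`
#'   (optional), `cost` and `qalys`.
#' @return A list with `type` (`"icer"`, `"dominance"` or `"equivalent"`),
#'   and either `value` ($/QALY) or `dominant` (`"a"` or `"b"`).
#' @export
icer <- function(a, b) {
  dc <- a$cost - b$cost
  dq <- a$qalys - b$qalys
  if (dc == 0 && dq == 0) return(list(type = "equivalent"))
  if (dc <= 0 && dq >= 0) return(list(type = "dominance", dominant = "a"))
  if (dc >= 0 && dq <= 0) return(list(type = "dominance", dominant = "b"))
  list(type = "icer", value = dc / dq)
}

#' Net monetary and net health benefit
#'
#' `NMB = qalys * wtp - cost`; `NHB = qalys - cost / wtp`.  The two are
#' related by `NMB = NHB * wtp` exactly.
#'
#' @param cost discounted total cost ($).
#' @param qalys discounted total QALYs.
#' @param wtp willingness to pay per QALY ($ > 0).
#' @return A list with elements `nmb` ($) and `nhb` (QALY).
#' @export
net_benefit <- function(cost, qalys, wtp = 50000) {
  if (any(wtp <= 0)) stop("willingness to pay must be > 0", call. = FALSE)
  list(nmb = qalys * wtp - cost, nhb = qalys - cost / wtp)
}

#' Rank strategies on the cost-effectiveness frontier
#'
#' Sorts strategies by ascending effectiveness, removes strongly dominated
#' strategies (another strategy is at least as cheap and at least as
#' effective), flags extendedly dominated ones (their incremental ratio
#' exceeds that of the next frontier segment), and computes incremental
#' costs, incremental QALYs and ICERs along the remaining frontier.  The
#' preferred strategy is the most effective frontier strategy whose ICER
#' does not exceed `wtp`; a tie at exactly `wtp` resolves to the more
#' effective strategy.
#'
#' @param results data frame with columns `strategy`, `cost`, `qalys`
#'   (one row per strategy; see [results_table()]), or a named list of
#'   `tka_run_result`.
#' @param wtp willingness to pay per QALY.
#' @return A data frame of class `tka_cea_table`, sorted by ascending
#'   QALYs, with columns `strategy`, `cost`, `qalys`, `d_cost`, `d_qalys`,
#'   `ce_ratio`, `icer`, `status`, `nmb`, `nhb`, and attributes
#'   `"preferred"` (strategy id) and `"wtp"`.
#' @export
build_cea_table <- function(results, wtp = 50000) {
  if (!is.data.frame(results)) results <- results_table(results)
  stopifnot(all(c("strategy", "cost", "qalys") %in% names(results)),
            nrow(results) >= 2)
  if (anyDuplicated(results$strategy))
    stop("duplicate strategy ids", call. = FALSE)
  df <- results[order(results$qalys, results$cost), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  status <- rep("", n)

  # strong dominance: pairwise, independent of ordering
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    if (any(df$cost[others] <= df$cost[i] & df$qalys[others] >= df$qalys[i] &
            (df$cost[others] < df$cost[i] | df$qalys[others] > df$qalys[i])))
      status[i] <- "strongly dominated"
  }
  # extended dominance: ICERs along the surviving frontier must increase
  repeat {
    idx <- which(status == "")
    if (length(idx) < 3) break
    ic <- diff(df$cost[idx]) / diff(df$qalys[idx])
    bad <- which(ic[-length(ic)] > ic[-1])
    if (!length(bad)) break
    status[idx[bad[1] + 1]] <- "extendedly dominated"
  }

  frontier <- which(status == "")
  d_cost <- d_qalys <- icer_v <- rep(NA_real_, n)
  if (length(frontier) > 1) {
    prev <- frontier[-length(frontier)]
    cur <- frontier[-1]
    d_cost[cur] <- df$cost[cur] - df$cost[prev]
    d_qalys[cur] <- df$qalys[cur] - df$qalys[prev]
    icer_v[cur] <- d_cost[cur] / d_qalys[cur]
  }
  status[frontier[1]] <- "reference"

  nb <- net_benefit(df$cost, df$qalys, wtp)
  out <- data.frame(
    strategy = df$strategy, cost = df$cost, qalys = df$qalys,
    d_cost = d_cost, d_qalys = d_qalys,
    ce_ratio = ce_ratio(df$cost, df$qalys),
    icer = icer_v, status = status,
    nmb = nb$nmb, nhb = nb$nhb
  )
  preferred <- frontier[1]
  for (k in frontier[-1]) if (icer_v[k] <= wtp) preferred <- k
  attr(out, "preferred") <- df$strategy[preferred]
  attr(out, "wtp") <- wtp
  class(out) <- c("tka_cea_table", "data.frame")
  out
}

#' @export
print.tka_cea_table <- function(x, ...) {
  cat("Cost-effectiveness analysis (WTP $",
      format(attr(x, "wtp"), big.mark = ","), "/QALY)\n", sep = "")
  shown <- data.frame(
    strategy = x$strategy,
    cost = sprintf("$%s", format(round(x$cost), big.mark = ",")),
    qalys = sprintf("%.2f", x$qalys),
    `C/E` = sprintf("$%s/QALY", format(round(x$ce_ratio), big.mark = ",")),
    ICER = ifelse(is.na(x$icer), "-",
                  sprintf("$%s/QALY", format(round(x$icer), big.mark = ","))),
    status = x$status, check.names = FALSE
  )
  print(shown, row.names = FALSE)
  cat("preferred strategy:", attr(x, "preferred"), "\n")
  invisible(x)
}

#' Write a CEA table to CSV
#'
#' Ratios are rounded to whole dollars per QALY in the exported file;
#' the in-memory table keeps full precision.
#'
#' @param cea a `tka_cea_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cea_table <- function(cea, path) {
  stopifnot(inherits(cea, "tka_cea_table"))
  out <- as.data.frame(cea)
  out$ce_ratio <- round(out$ce_ratio)
  out$icer <- round(out$icer)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
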