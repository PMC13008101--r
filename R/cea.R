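#' Incremental cost-effectiveness ratio
#'
#' `(cost_comparator - cost_reference) / (qaly_comparator - qaly_reference)`,
#' computed on full-precision outcomes. A comparator that is cheaper and more
#' effective has a negative ICER; interpret through [dominance_frontier()]
#' rather than the raw number. Equal QALYs make the ratio undefined and
#' return `NA` (a dominance case, not a number).
#'
#' @param reference,comparator `fib_strategy_outcome` objects or lists with
#'   `cost` and `qaly`.
#' @return THB per QALY gained, or `NA` if the QALY difference is zero.
#' @export
#' @examples
#' compute_icer(list(cost = 0, qaly = 0), list(cost = 1000, qaly = 0.01))
compute_icer <- function(reference, comparator) {
  dq <- comparator$qaly - reference$qaly
  dc <- comparator$cost - reference$cost
  if (dq == 0) return(NA_real_)
  dc / dq
}

#' Net monetary benefit versus a comparator
#'
#' `wtp * (QALY gained) - (incremental cost)`.
#'
#' @param outcome,comparator Objects with `cost` and `qaly`.
#' @param wtp Willingness-to-pay threshold, THB per QALY.
#' @return Money (THB); positive favours `outcome` at this threshold.
#' @export
net_monetary_benefit <- function(outcome, comparator, wtp) {
  wtp * (outcome$qaly - comparator$qaly) - (outcome$cost - comparator$cost)
}

#' Simple and extended dominance frontier
#'
#' Sorts strategies by effectiveness, removes the simply dominated (weakly
#' more costly and weakly less effective than some other strategy, strictly
#' so in at least one dimension; exact QALY ties are resolved as dominance by
#' lower cost), then iteratively computes ICERs against the next-cheaper
#' survivor and removes any strategy whose ICER exceeds that of a more
#' effective strategy (extended dominance), until the frontier ICER sequence
#' strictly increases.
#'
#' @param outcomes Data frame with columns `strategy`, `cost`, `qaly` (e.g.
#'   from [evaluate_strategies()]), or a list of outcome objects.
#' @return Data frame, one row per strategy, with `status`
#'   (`"nondominated"`, `"dominated"`, `"extended_dominated"`),
#'   `icer` (vs the next-cheaper frontier strategy; `NA` for the cheapest)
#'   and `dominated_by`.
#' @export
dominance_frontier <- function(outcomes) {
  df <- .as_ce_df(outcomes)
  if (nrow(df) < 1) stop("need at least one strategy", call. = FALSE)
  df$status <- "nondominated"
  df$icer <- NA_real_
  df$dominated_by <- NA_character_

  # simple dominance (handles QALY ties by lower cost)
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      ci <- df$cost[i]; qi <- df$qaly[i]
      cj <- df$cost[j]; qj <- df$qaly[j]
      if (cj <= ci && qj >= qi && (cj < ci || qj > qi)) {
        df$status[i] <- "dominated"
        df$dominated_by[i] <- df$strategy[j]
        break
      }
    }
  }

  # extended dominance on the survivors
  repeat {
    alive <- which(df$status == "nondominated")
    ord <- alive[order(df$qaly[alive], df$cost[alive])]
    if (length(ord) >= 1) {
      icers <- rep(NA_real_, length(ord))
      for (k in seq_along(ord)[-1]) {
        icers[k] <- (df$cost[ord[k]] - df$cost[ord[k - 1]]) /
          (df$qaly[ord[k]] - df$qaly[ord[k - 1]])
      }
      bad <- which(diff(icers[-1]) <= 0)  # icer[k] >= icer[k+1]
      if (length(bad)) {
        k <- bad[1] + 1  # position in ord whose ICER exceeds the next one
        df$status[ord[k]] <- "extended_dominated"
        df$dominated_by[ord[k]] <- df$strategy[ord[k + 1]]
        next
      }
      df$icer[ord] <- icers
    }
    break
  }
  df[order(df$qaly, df$cost), ]
}

.as_ce_df <- function(outcomes) {
  if (is.data.frame(outcomes)) {
    stopifnot(all(c("strategy", "cost", "qaly") %in% names(outcomes)))
    outcomes[, c("strategy", "cost", "qaly")]
  } else {
    do.call(rbind, lapply(outcomes, function(o)
      data.frame(strategy = o$strategy, cost = o$cost, qaly = o$qaly)))
  }
}

#' Full cost-effectiveness comparison of the configured strategies
#'
#' Evaluates every strategy, computes ICERs versus no screening and along the
#' dominance frontier, and issues a willingness-to-pay verdict per strategy:
#' a strategy is cost-effective when it is on the frontier with a frontier
#' ICER at or below the threshold, or below a frontier segment at that
#' threshold (its ICER versus no screening under the threshold).
#'
#' @param params A `fib_params`.
#' @param comparator Strategy id used for the pairwise ICER column, default
#'   `"no_screen"`.
#' @return Data frame of class `fib_ce_result`: per strategy, life
#'   expectancy, cost (THB and USD), QALYs, ICER versus the comparator,
#'   frontier ICER and status, and the WTP verdict.
#' @export
#' @examples
#' \donttest{
#' cost_effectiveness(default_parameters("mets"))
#' }
cost_effectiveness <- function(params, comparator = "no_screen") {
  ev <- evaluate_strategies(params)
  outs <- attr(ev, "outcomes")
  front <- dominance_frontier(ev)
  ref <- outs[[comparator]]
  ev$icer_vs_comparator <- vapply(attr(ev, "outcomes"), function(o)
    if (o$strategy == comparator) NA_real_ else compute_icer(ref, o), 0)
  m <- match(ev$strategy, front$strategy)
  ev$frontier_icer <- front$icer[m]
  ev$status <- front$status[m]
  ev$dominated_by <- front$dominated_by[m]
  wtp <- params$econ$wtp
  ev$cost_effective <- ev$status == "nondominated" &
    (is.na(ev$frontier_icer) | ev$frontier_icer <= wtp)
  attr(ev, "wtp") <- wtp
  class(ev) <- c("fib_ce_result", "data.frame")
  ev
}

#' ICERs across screening ages
#'
#' Re-evaluates every strategy at each screening age (the age-banded
#' prevalences are swapped in automatically) and reports the ICER versus no
#' screening.
#'
#' @param params A `fib_params`; its `start_age` is replaced per scenario.
#' @param ages Integer vector of screening ages, default 30 to 80 by 10.
#' @return Data frame: `age`, `strategy`, `cost`, `qaly`, `icer_vs_no_screen`,
#'   `cost_effective` at the configured WTP.
#' @export
scenario_sweep <- function(params, ages = seq(30, 80, 10)) {
  rows <- lapply(ages, function(a) {
    p <- params
    p$start_age <- a
    ce <- cost_effectiveness(p)
    data.frame(age = a, strategy = ce$strategy, cost = ce$cost,
               qaly = ce$qaly, icer_vs_no_screen = ce$icer_vs_comparator,
               cost_effective = ce$icer_vs_comparator <= params$econ$wtp)
  })
  do.call(rbind, rows)
}

#' Maximum TE unit cost at which a strategy stays cost-effective
#'
#' Bisects on the transient-elastography unit cost until the strategy's ICER
#' versus no screening equals the willingness-to-pay threshold to within a
#' relative tolerance of 1e-6. If the strategy is already cost-effective at
#' the current cost the verdict is returned with the current cost; if even a
#' free test would not be cost-effective, the boundary verdict says so.
#'
#' @param strategy Strategy id.
#' @param params A `fib_params`.
#' @param wtp Threshold, defaults to the configured one.
#' @param tol Relative tolerance on `|ICER - wtp| / wtp`.
#' @return List with `verdict` (`"threshold_found"`,
#'   `"already_cost_effective"` or `"not_cost_effective_even_free"`),
#'   `critical_cost` (THB), and the ICERs at the bracket ends.
#' @export
threshold_te_cost <- function(strategy, params, wtp = params$econ$wtp,
                              tol = 1e-6) {
  icer_at <- function(cost_te) {
    p <- params
    p$costs$screening["te"] <- cost_te
    ev <- evaluate_strategies(p, c("no_screen", strategy))
    outs <- attr(ev, "outcomes")
    compute_icer(outs$no_screen, outs[[strategy]])
  }
  c0 <- unname(params$costs$screening["te"])
  icer_cur <- icer_at(c0)
  icer_free <- icer_at(0)
  if (!is.na(icer_cur) && icer_cur <= wtp)
    return(list(verdict = "already_cost_effective", critical_cost = c0,
                icer_at_current = icer_cur, icer_at_zero = icer_free))
  if (is.na(icer_free) || icer_free > wtp)
    return(list(verdict = "not_cost_effective_even_free", critical_cost = NA_real_,
                icer_at_current = icer_cur, icer_at_zero = icer_free))
  lo <- 0; hi <- c0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    ic <- icer_at(mid)
    if (abs(ic - wtp) / wtp < tol) break
    if (ic > wtp) hi <- mid else lo <- mid
  }
  list(verdict = "threshold_found", critical_cost = mid,
       icer_at_current = icer_cur, icer_at_zero = icer_free,
       icer_at_critical = ic)
}

#' @export
print.fib_ce_result <- function(x, ...) {
  cat("Cost-utility analysis (WTP ", attr(x, "wtp"), " THB/QALY)\n", sep = "")
  y <- as.data.frame(x)
  y$cost <- round(y$cost, 1); y$cost_usd <- round(y$cost_usd, 1)
  y$qaly <- round(y$qaly, 3)
  y$life_expectancy <- round(y$life_expectancy, 2)
  y$icer_vs_comparator <- round(y$icer_vs_comparator, 2)
  y$frontier_icer <- round(y$frontier_icer, 2)
  print(y[, setdiff(names(y), "label")], row.names = FALSE)
  invisible(x)
}
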