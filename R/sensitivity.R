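#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the ICER of a strategy versus a comparator with each
#' uncertain parameter set to its lower and upper bound in turn, all else at
#' base case. Bounds are the 95% confidence interval (mean +/- 1.96 se,
#' truncated to the parameter's domain) for probabilities, utilities and the
#' treatment effect; +/- 25% for cost parameters; and the stated plausible
#' range for uptake rates, adherence, the cost-to-charge ratio, the discount
#' rate and the mortality hazard ratios. Rows are ordered by tornado range.
#' A bound that removes the whole QALY gain yields an infinite ICER
#' (reported as `Inf`, i.e. dominated at that bound).
#'
#' @param params A `fib_params`.
#' @param strategy Strategy id under study.
#' @param comparator Comparator id, default `"no_screen"`.
#' @return Data frame of class `fib_owsa`: `id`, `low`, `high`, `icer_low`,
#'   `icer_high`, `range`, sorted descending by `range`; the base-case ICER
#'   is attribute `"icer_base"`.
#' @export
one_way_sweep <- function(params, strategy, comparator = "no_screen") {
  reg <- parameter_registry(params)
  paths <- .param_paths()

  icer_for <- function(p) {
    ev <- evaluate_strategies(p, c(comparator, strategy))
    outs <- attr(ev, "outcomes")
    dq <- outs[[strategy]]$qaly - outs[[comparator]]$qaly
    dc <- outs[[strategy]]$cost - outs[[comparator]]$cost
    if (dq == 0) return(if (dc > 0) Inf else if (dc < 0) -Inf else NA_real_)
    dc / dq
  }
  icer_base <- icer_for(params)

  domain <- function(dist) switch(dist,
    beta = c(1e-9, 1 - 1e-9),
    gamma = c(0, Inf),
    lognormal_rr = c(0, 1 - 1e-9),
    c(-Inf, Inf))

  rows <- list()
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    if (r$owsa == "none") next
    bounds <- switch(r$owsa,
      ci = {
        if (r$se == 0) c(r$mean, r$mean)
        else {
          dom <- domain(r$dist)
          c(max(dom[1], r$mean - 1.96 * r$se),
            min(dom[2], r$mean + 1.96 * r$se))
        }
      },
      pct25 = c(r$mean * 0.75, r$mean * 1.25),
      range = c(r$low, r$high))
    ic <- vapply(bounds, function(v) {
      p <- params
      for (pa in paths[[r$id]]) p <- .set_path(p, pa, v)
      icer_for(p)
    }, 0)
    rows[[r$id]] <- data.frame(id = r$id, low = bounds[1], high = bounds[2],
                               icer_low = ic[1], icer_high = ic[2],
                               range = abs(ic[2] - ic[1]))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- icer_base
  attr(out, "strategy") <- strategy
  class(out) <- c("fib_owsa", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` full parameter sets (beta for probabilities and utilities,
#' gamma for costs, log-normal relative risk for the treatment effect,
#' uniform for range-only uptake rates; all parameters independent) and
#' evaluates every strategy on each common draw. A draw whose sampled
#' disease exits are infeasible (sum above 1 for some state) is resampled
#' deterministically; if more than 5% of draws need resampling the
#' parameterisation is considered suspect and an error is raised. The same
#' seed reproduces the identical draw list.
#'
#' @param params A `fib_params`.
#' @param strategies Strategy ids, default all configured.
#' @param n Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed.
#' @return Data frame of class `fib_psa`: `draw`, `seed`, `strategy`,
#'   `cost`, `qaly`; the resample count is attribute `"n_resampled"`.
#' @export
run_psa <- function(params, strategies = names(params$strategies),
                    n = 1000, seed = params$psa$seed %||% 1) {
  if (n == 0) {
    out <- data.frame(draw = integer(0), seed = integer(0),
                      strategy = character(0), cost = numeric(0),
                      qaly = numeric(0))
    class(out) <- c("fib_psa", "data.frame")
    attr(out, "n_resampled") <- 0L
    return(out)
  }
  set.seed(seed)
  draw_seeds <- sample.int(2147483646L, n)
  feasible <- function(p) {
    ex <- .state_exits(p$transitions)
    all(vapply(ex, sum, 0) <= 1)
  }
  n_resampled <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s_i <- draw_seeds[i]
    p <- sample_parameter_set(params, s_i)
    tries <- 0L
    while (!feasible(p)) {
      tries <- tries + 1L
      if (tries > 100L) stop("could not draw a feasible parameter set",
                             call. = FALSE)
      s_i <- (s_i + 7919L * tries) %% 2147483647L
      p <- sample_parameter_set(params, s_i)
    }
    if (tries > 0L) n_resampled <- n_resampled + 1L
    ev <- evaluate_strategies(p, strategies)
    rows[[i]] <- data.frame(draw = i, seed = s_i, strategy = ev$strategy,
                            cost = ev$cost, qaly = ev$qaly)
  }
  if (n_resampled / n > 0.05)
    stop("more than 5% of PSA draws were infeasible; ",
         "check the parameterisation", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_resampled") <- n_resampled
  class(out) <- c("fib_psa", "data.frame")
  out
}

#' Summaries of a probabilistic sensitivity analysis
#'
#' Computes, from the PSA draws: the cost-effectiveness plane (incremental
#' cost and QALYs versus the comparator per draw); the probability that each
#' strategy is cost-effective versus the comparator (positive net monetary
#' benefit) across the willingness-to-pay grid; and the cost-effectiveness
#' acceptability curve among the screening strategies only (the comparator
#' is excluded from the CEAC choice set; optimal = highest net monetary
#' benefit in each draw, ties broken by strategy order). CEAC probabilities
#' sum to 1 at every threshold.
#'
#' @param draws A [run_psa()] result.
#' @param comparator Comparator strategy id, default `"no_screen"`.
#' @param wtp_grid Thresholds in THB/QALY, default 0 to 300,000 by 10,000.
#' @return List with `ce_plane`, `prob_ce`, `ceac` data frames.
#' @export
psa_summaries <- function(draws, comparator = "no_screen",
                          wtp_grid = seq(0, 300000, by = 10000)) {
  if (nrow(draws) == 0) stop("no PSA draws", call. = FALSE)
  strategies <- unique(draws$strategy)
  others <- setdiff(strategies, comparator)
  n <- max(draws$draw)

  C <- matrix(NA_real_, n, length(strategies),
              dimnames = list(NULL, strategies))
  Q <- C
  idx <- cbind(draws$draw, match(draws$strategy, strategies))
  C[idx] <- draws$cost
  Q[idx] <- draws$qaly

  dC <- C[, others, drop = FALSE] - C[, comparator]
  dQ <- Q[, others, drop = FALSE] - Q[, comparator]

  ce_plane <- data.frame(
    draw = rep(seq_len(n), length(others)),
    strategy = rep(others, each = n),
    delta_cost = as.vector(dC), delta_qaly = as.vector(dQ))

  prob_ce <- do.call(rbind, lapply(wtp_grid, function(w) {
    nmb <- w * dQ - dC
    data.frame(wtp = w, strategy = others,
               prob = colMeans(nmb > 0), row.names = NULL)
  }))

  ceac <- do.call(rbind, lapply(wtp_grid, function(w) {
    nmb <- w * dQ - dC
    best <- others[max.col(nmb, ties.method = "first")]
    data.frame(wtp = w, strategy = others,
               prob = vapply(others, function(s) mean(best == s), 0),
               row.names = NULL)
  }))
  list(ce_plane = ce_plane, prob_ce = prob_ce, ceac = ceac)
}
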