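#' Build the annual transition matrix at a given age
#'
#' Death competes first: the per-state annual death probability is the
#' life-table probability times the metabolic multiplier times the disease
#' hazard ratio (1.29 for non-cirrhotic MASLD F0-F3, 3.13 for compensated
#' cirrhosis, decompensated cirrhosis and HCC; no disease hazard for
#' NO_MASLD; transplant states use the post-transplant mortality parameter),
#' capped at 1. Disease transitions apply to the survivor fraction, so every
#' row is feasible by construction provided the raw exits sum to at most 1 —
#' otherwise an error names the offending row rather than renormalising
#' silently. Death mass is split across the three cause-attributed death
#' states. Transplant entry (DC to LT, HCC to LT) is permitted only while
#' age is at most the transplant age limit (default 70). In a
#' treated-adherent cohort, the three progression probabilities F2-F3,
#' F3-F4/CC and F4/CC-DC are multiplied by one minus the relative risk
#' reduction before use.
#'
#' @param params A `fib_params`.
#' @param age Age (integer years) at the start of the cycle.
#' @param treated_adherent Apply the lifestyle-intervention effect?
#' @return 13 x 13 row-stochastic matrix over [health_states()].
#' @export
#' @examples
#' p <- default_parameters("mets")
#' M <- build_transition_matrix(p, 50)
#' rowSums(M)
build_transition_matrix <- function(params, age, treated_adherent = FALSE) {
  states <- .states()
  n <- .n_states()
  tp <- params$transitions
  if (treated_adherent) {
    mult <- 1 - params$treatment$rrr
    tp[c("f2_f3", "f3_f4", "f4_dc")] <- tp[c("f2_f3", "f3_f4", "f4_dc")] * mult
  }
  if (age > params$mortality$lt_age_max) {
    tp["dc_lt"] <- 0
    tp["hcc_lt"] <- 0
  }
  exits <- .state_exits(tp)

  mort <- params$mortality
  q <- .life_table_qx(params, age) * mort$metabolic_multiplier
  p_death <- c(
    NO_MASLD = q,
    F0 = q * mort$hr_noncirrhotic, F1 = q * mort$hr_noncirrhotic,
    F2 = q * mort$hr_noncirrhotic, F3 = q * mort$hr_noncirrhotic,
    F4_CC = q * mort$hr_cirrhotic, DC = q * mort$hr_cirrhotic,
    HCC = q * mort$hr_cirrhotic,
    LT = mort$post_lt_mortality, POST_LT = mort$post_lt_mortality
  )
  p_death <- pmin(p_death, 1)

  split_for <- function(state) {
    g <- switch(state,
                NO_MASLD = "no_masld",
                F0 = , F1 = , F2 = , F3 = "noncirrhotic",
                F4_CC = , DC = , HCC = "cirrhotic",
                LT = , POST_LT = "lt")
    mort$cause_split[[g]]
  }

  M <- matrix(0, n, n, dimnames = list(states, states))
  for (s in .alive_states()) {
    pd <- p_death[[s]]
    ex <- if (s == "LT") c(POST_LT = 1) else exits[[s]] %||% numeric(0)
    tot <- sum(ex)
    if (tot > 1 + 1e-12)
      stop("infeasible parameters: exits from row ", s, " sum to ",
           signif(tot, 5), " > 1", call. = FALSE)
    surv <- 1 - pd
    if (length(ex)) M[s, names(ex)] <- surv * ex
    M[s, s] <- M[s, s] + surv * (1 - tot)
    cs <- split_for(s)
    M[s, .death_states()] <- pd * cs[c("cvd", "liver", "other")]
  }
  for (d in .death_states()) M[d, d] <- 1
  M
}

#' Precompute the transition matrices for every model age
#'
#' @param params A `fib_params`.
#' @return List with elements `untreated` and `treated`, each a list of
#'   matrices indexed by cycle (ages `start_age` to `max_age - 1`), plus the
#'   `ages` vector.
#' @export
build_matrix_set <- function(params) {
  ages <- params$start_age:(params$max_age - 1)
  list(ages = ages,
       untreated = lapply(ages, function(a)
         build_transition_matrix(params, a, FALSE)),
       treated = lapply(ages, function(a)
         build_transition_matrix(params, a, TRUE)))
}

#' Run the cohort model from an initial state distribution
#'
#' Iterates the occupancy vector annually from the start age to the maximum
#' model age. The returned trajectory has one row per cycle (the first row is
#' the initial distribution at the start age); each row sums to 1.
#'
#' @param initial Occupancy vector over [health_states()] summing to 1.
#' @param params A `fib_params`.
#' @param treated_adherent Use the treatment-modified matrices?
#' @param matrices Optional [build_matrix_set()] result to avoid rebuilding.
#' @return Matrix of dimension `(max_age - start_age + 1) x 13`, class
#'   `fib_trajectory`.
#' @export
run_cohort <- function(initial, params, treated_adherent = FALSE,
                       matrices = NULL) {
  if (abs(sum(initial) - 1) > 1e-9)
    stop("initial occupancy must sum to 1", call. = FALSE)
  n_cycles <- params$max_age - params$start_age
  mats <- if (!is.null(matrices)) {
    if (treated_adherent) matrices$treated else matrices$untreated
  } else {
    ages <- params$start_age:(params$max_age - 1)
    lapply(ages, function(a)
      build_transition_matrix(params, a, treated_adherent))
  }
  traj <- matrix(0, n_cycles + 1, .n_states(),
                 dimnames = list(NULL, .states()))
  occ <- as.numeric(initial)
  traj[1, ] <- occ
  for (t in seq_len(n_cycles)) {
    occ <- as.numeric(occ %*% mats[[t]])
    traj[t + 1, ] <- occ
  }
  structure(traj, class = c("fib_trajectory", "matrix"))
}

#' Discounted lifetime outcomes of a trajectory
#'
#' Accumulates QALYs (occupancy times state utility), costs (state annual
#' medical cost, with the cost-to-charge ratio applied to hospital-derived
#' costs, plus non-medical visit costs, plus the lifestyle-programme cost in
#' pre-decompensation states for strata that incur it) and life expectancy
#' (undiscounted alive person-years). Each cycle contributes a full year of
#' payoff at its starting occupancy; the first cycle is undiscounted (t = 0),
#' no half-cycle correction is applied, and the terminal row (occupancy at
#' the maximum model age) contributes no further outcomes. Death states carry
#' zero utility and cost.
#'
#' @param traj A trajectory from [run_cohort()].
#' @param params A `fib_params`.
#' @param lifestyle Does this stratum accrue the lifestyle-programme cost?
#' @return List of class `fib_outcome`: `cost`, `qaly` (discounted),
#'   `cost_undisc`, `qaly_undisc`, `life_expectancy`.
#' @export
accumulate_outcomes <- function(traj, params, lifestyle = FALSE) {
  # payoff cycles t = 0..A-1; the terminal row is the horizon
  n_cyc <- nrow(traj) - 1L
  if (n_cyc < 1) stop("trajectory needs at least two rows", call. = FALSE)
  traj <- traj[seq_len(n_cyc), , drop = FALSE]
  d <- params$econ$discount
  disc <- (1 + d)^(-(seq_len(n_cyc) - 1))

  u_vec <- .expand_group_vector(params$utilities)
  cost_state <- params$costs$state *
    ifelse(params$costs$state_hospital_derived, params$econ$ctc_ratio, 1)
  c_vec <- .expand_group_vector(cost_state) +
    .expand_group_vector(params$costs$visits) * params$costs$nonmedical_per_visit

  q_cyc <- as.numeric(traj %*% u_vec)
  c_cyc <- as.numeric(traj %*% c_vec)
  if (lifestyle) {
    ls_vec <- as.numeric(.states() %in% .lifestyle_states()) *
      params$treatment$lifestyle_cost
    dur <- params$treatment$lifestyle_duration
    on <- (seq_len(n_cyc) - 1) < dur
    c_cyc <- c_cyc + as.numeric(traj %*% ls_vec) * on
  }
  alive <- as.numeric(traj %*% as.numeric(.states() %in% .alive_states()))

  structure(list(
    cost = sum(c_cyc * disc),
    qaly = sum(q_cyc * disc),
    cost_undisc = sum(c_cyc),
    qaly_undisc = sum(q_cyc),
    life_expectancy = sum(alive)
  ), class = "fib_outcome")
}

#' Evaluate one screening strategy end to end
#'
#' Builds the decision-tree strata, runs each through the Markov model with
#' its matrix variant (treated-adherent strata use the treatment-modified
#' progression), mass-weights the stratum outcomes and adds the expected
#' per-person screening cost (incurred at time zero, undiscounted). The
#' no-screening strategy is the pure natural-history run.
#'
#' @param strategy Strategy id or definition.
#' @param params A `fib_params`.
#' @param matrices Optional precomputed [build_matrix_set()].
#' @return List of class `fib_strategy_outcome` with `strategy`, `cost`,
#'   `qaly`, `life_expectancy`, undiscounted counterparts, `screening_cost`
#'   and the `cascade`.
#' @export
evaluate_strategy <- function(strategy, params, matrices = NULL) {
  strat <- .resolve_strategy(strategy, params)
  if (is.null(matrices)) matrices <- build_matrix_set(params)
  strata <- build_initial_strata(strat, params)
  cascade <- classify_cohort(strat, params)

  tot <- c(cost = 0, qaly = 0, cost_undisc = 0, qaly_undisc = 0,
           life_expectancy = 0)
  for (st in strata) {
    if (st$mass <= 0) next
    traj <- run_cohort(st$init, params,
                       treated_adherent = st$treated && st$adherent,
                       matrices = matrices)
    o <- accumulate_outcomes(traj, params, lifestyle = st$lifestyle)
    tot <- tot + st$mass * unlist(o)
  }
  tot["cost"] <- tot["cost"] + cascade$screening_cost
  tot["cost_undisc"] <- tot["cost_undisc"] + cascade$screening_cost

  structure(list(strategy = strat$id, label = strat$label %||% strat$id,
                 population = params$population, age = params$start_age,
                 cost = unname(tot["cost"]), qaly = unname(tot["qaly"]),
                 cost_undisc = unname(tot["cost_undisc"]),
                 qaly_undisc = unname(tot["qaly_undisc"]),
                 life_expectancy = unname(tot["life_expectancy"]),
                 screening_cost = cascade$screening_cost,
                 cascade = cascade),
            class = "fib_strategy_outcome")
}

#' Evaluate several strategies on a common parameter set
#'
#' The transition matrices are built once and shared, so probabilistic
#' replications stay fast.
#'
#' @param params A `fib_params`.
#' @param strategies Character vector of strategy ids; default all
#'   configured strategies.
#' @return Data frame with one row per strategy (`strategy`, `label`,
#'   `life_expectancy`, `cost`, `cost_usd`, `qaly`); the full outcome
#'   objects are attached as attribute `"outcomes"`.
#' @export
#' @examples
#' \donttest{
#' p <- default_parameters("mets")
#' evaluate_strategies(p)
#' }
evaluate_strategies <- function(params, strategies = names(params$strategies)) {
  matrices <- build_matrix_set(params)
  outs <- lapply(strategies, evaluate_strategy, params = params,
                 matrices = matrices)
  names(outs) <- strategies
  df <- data.frame(
    strategy = strategies,
    label = vapply(outs, `[[`, "", "label"),
    life_expectancy = vapply(outs, `[[`, 0, "life_expectancy"),
    cost = vapply(outs, `[[`, 0, "cost"),
    cost_usd = thb_to_usd(vapply(outs, `[[`, 0, "cost"),
                          params$econ$thb_per_usd),
    qaly = vapply(outs, `[[`, 0, "qaly"),
    row.names = NULL
  )
  attr(df, "outcomes") <- outs
  df
}

#' @export
print.fib_strategy_outcome <- function(x, ...) {
  cat(sprintf("<fib_strategy_outcome> %s (%s, age %d)\n", x$label,
              x$population, x$age))
  cat(sprintf("  life expectancy %.2f y | cost %.1f THB | QALYs %.3f\n",
              x$life_expectancy, x$cost, x$qaly))
  invisible(x)
}
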