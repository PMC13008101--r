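#' Generate a synthetic Gompertz life table
#'
#' Annual all-cause death probability at age `a` is
#' `1 - exp(-alpha * exp(beta * a))`: a Gompertz hazard integrated over a
#' one-year cycle. With `alpha = 5.5e-5, beta = 0.09` (the package default)
#' life expectancy at birth is about 77 years, a plausible stand-in where a
#' national life table is not supplied. `beta = 0` gives age-constant
#' mortality, handy for closed-form checks.
#'
#' @param alpha Baseline hazard (>= 0).
#' @param beta Gompertz slope (>= 0).
#' @param ages Integer vector of ages.
#' @return Data frame with columns `age`, `qx`.
#' @export
#' @examples
#' lt <- synth_life_table(5.5e-5, 0.09, 0:100)
#' head(lt)
synth_life_table <- function(alpha = 5.5e-5, beta = 0.09, ages = 0:100) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  qx <- 1 - exp(-alpha * exp(beta * ages))
  cap <- 1 - 1e-9
  if (any(qx > cap)) {
    warning("life-table probabilities clipped at 1 - 1e-9")
    qx <- pmin(qx, cap)
  }
  data.frame(age = as.integer(ages), qx = qx)
}

#' Life expectancy implied by a life table
#'
#' Closed-form cohort expectancy under the model's full-year convention:
#' each year lived counts 1 at its starting survival probability,
#' `e(a) = sum_t prod_{j<t} (1 - q(a+j))`, truncated at the table's last age.
#'
#' @param life_table Data frame with `age`, `qx`.
#' @param start_age Age at which to evaluate.
#' @return Expected remaining years (including the current year).
#' @export
life_table_expectancy <- function(life_table, start_age,
                                  max_age = max(life_table$age)) {
  ages <- start_age:(max_age - 1)
  q <- life_table$qx[match(ages, life_table$age)]
  if (any(is.na(q))) stop("life table does not cover the requested ages",
                          call. = FALSE)
  surv <- cumprod(1 - q)
  sum(c(1, surv[-length(surv)]))
}

#' Write a life table in the standard two-column format
#'
#' @param life_table Data frame with `age`, `qx`.
#' @param path Output path (tab-delimited, header `age qx`).
#' @return Invisibly, `path`.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.table(life_table[, c("age", "qx")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' A reduced scenario with closed-form outcomes
#'
#' A degenerate parameter set used as an analytic anchor: age-constant
#' mortality (annual death probability `1 - s`), no disease transitions, all
#' utilities equal to `utility`, zero costs. Starting anywhere alive, the
#' discounted QALY total over `T` cycles is the geometric sum
#' `sum_{t<T} (s/(1+d))^t`; with `s = 0.9`, `d = 0.03` and a long horizon it
#' approaches `1/(1 - 0.9/1.03) = 7.92305...`.
#'
#' @param survival Annual survival probability `s`.
#' @param utility Utility of every alive state.
#' @param discount Annual discount rate `d`.
#' @param horizon Number of cycles simulated.
#' @return List of class `fib_toy_scenario`: `params` (a `fib_params`),
#'   `expected` (closed-form discounted and undiscounted QALYs and life
#'   expectancy over the horizon) and the formulas as text.
#' @export
#' @examples
#' toy <- toy_scenario()
#' toy$expected$qaly
toy_scenario <- function(survival = 0.9, utility = 1, discount = 0.03,
                         horizon = 400) {
  q_const <- 1 - survival
  lt <- data.frame(age = 0:horizon, qx = q_const)
  params <- default_parameters("mets", start_age = 0, max_age = horizon,
                               life_table = lt)
  params$transitions[] <- 0
  params$treatment$rrr <- 0
  params$utilities[] <- utility
  params$costs$state[] <- 0
  params$costs$visits[] <- 0
  params$costs$screening[] <- 0
  params$treatment$lifestyle_cost <- 0
  params$mortality$hr_noncirrhotic <- 1
  params$mortality$hr_cirrhotic <- 1
  params$mortality$metabolic_multiplier <- 1
  params$mortality$post_lt_mortality <- q_const
  params$econ$discount <- discount

  t_idx <- 0:(horizon - 1)
  ratio <- survival / (1 + discount)
  expected <- list(
    qaly = utility * sum(ratio^t_idx),
    qaly_infinite = utility / (1 - ratio),
    qaly_undisc = utility * sum(survival^t_idx),
    life_expectancy = sum(survival^t_idx)
  )
  structure(list(params = params, expected = expected,
                 formulas = c(
                   qaly = "u * sum_{t=0}^{T-1} (s/(1+d))^t",
                   qaly_infinite = "u / (1 - s/(1+d))",
                   life_expectancy = "sum_{t=0}^{T-1} s^t"),
                 survival = survival, utility = utility,
                 discount = discount, horizon = horizon),
            class = "fib_toy_scenario")
}

#' Individual-level microsimulation oracle
#'
#' Independent verification of the cohort engine: simulates `n` individuals
#' by categorical sampling from the same age-indexed transition rows and
#' accumulates the same per-cycle payoffs, without any of the cohort
#' engine's matrix algebra. Agreement of the two engines within Monte Carlo
#' error validates the deterministic cohort propagation.
#'
#' @param params A `fib_params`.
#' @param initial Initial state distribution over [health_states()].
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#' @param treated_adherent Use treatment-modified transition rows?
#' @param lifestyle Accrue the lifestyle-programme cost?
#' @return List: `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`,
#'   `mean_life_years`, `n`.
#' @export
microsim_oracle <- function(params, initial, n = 10000, seed = 1,
                            treated_adherent = FALSE, lifestyle = FALSE) {
  stopifnot(n >= 1)
  set.seed(seed)
  n_states <- .n_states()
  n_cycles <- params$max_age - params$start_age
  ages <- params$start_age:(params$max_age - 1)
  rows <- lapply(ages, function(a)
    build_transition_matrix(params, a, treated_adherent))

  u_vec <- .expand_group_vector(params$utilities)
  cost_state <- params$costs$state *
    ifelse(params$costs$state_hospital_derived, params$econ$ctc_ratio, 1)
  c_vec <- .expand_group_vector(cost_state) +
    .expand_group_vector(params$costs$visits) * params$costs$nonmedical_per_visit
  ls_vec <- as.numeric(.states() %in% .lifestyle_states()) *
    params$treatment$lifestyle_cost
  alive_vec <- as.numeric(.states() %in% .alive_states())
  d <- params$econ$discount
  dur <- params$treatment$lifestyle_duration

  state <- sample.int(n_states, n, replace = TRUE, prob = initial)
  qaly <- numeric(n); cost <- numeric(n); years <- numeric(n)
  for (t in 0:(n_cycles - 1)) {
    disc <- (1 + d)^(-t)
    qaly <- qaly + u_vec[state] * disc
    cc <- c_vec[state]
    if (lifestyle && t < dur) cc <- cc + ls_vec[state]
    cost <- cost + cc * disc
    years <- years + alive_vec[state]
    M <- rows[[t + 1]]
    prev <- state
    for (s in unique(prev)) {
      idx <- which(prev == s)
      state[idx] <- sample.int(n_states, length(idx), replace = TRUE,
                               prob = M[s, ])
    }
  }
  list(mean_cost = mean(cost), mean_qaly = mean(qaly),
       se_cost = stats::sd(cost) / sqrt(n),
       se_qaly = stats::sd(qaly) / sqrt(n),
       mean_life_years = mean(years), n = n)
}
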