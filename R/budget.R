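#' Default budget-impact inputs
#'
#' National prevalence and annual incidence of the eligible conditions among
#' adults aged 50-79 (prevalence: MetS 18.0%, obesity 33.4%, both 15.2%;
#' incidence: MetS 8.0%, obesity 0.9%, both 4.5% -- the joint incidence is
#' approximated by averaging the two condition-specific rates). The national
#' population count in the eligible age window is a synthetic default of
#' 20 million and should be configured for real use.
#'
#' @return List of BIA inputs.
#' @export
default_bia_inputs <- function() {
  list(
    population_count = 20e6, # synthetic default: Thai adults aged 50-79
    prevalence = c(mets = 0.180, obesity = 0.334, both = 0.152),
    incidence = c(mets = 0.080, obesity = 0.009,
                  both = (0.080 + 0.009) / 2),
    horizon = 5
  )
}

#' Project the eligible screening population over the horizon
#'
#' Open-cohort projection: year 1 contains the prevalent population
#' (population count times prevalence); each later year adds the incident
#' cases arising in the remaining at-risk pool (population not yet
#' eligible). Each person is screened once, in the year they become
#' eligible; no population growth or mortality attrition is applied.
#'
#' @param inputs BIA inputs, see [default_bia_inputs()].
#' @param population `"mets"`, `"obesity"` or `"both"`.
#' @return Data frame: `year`, `eligible_new` (persons newly eligible and
#'   screened that year), `at_risk` (pool remaining after the year).
#' @export
#' @examples
#' project_eligible_population(default_bia_inputs(), "mets")
project_eligible_population <- function(inputs, population = "mets") {
  pop <- inputs$population_count
  prev <- inputs$prevalence[[population]]
  inc <- inputs$incidence[[population]]
  horizon <- inputs$horizon %||% 5
  eligible <- numeric(horizon)
  at_risk <- numeric(horizon)
  eligible[1] <- pop * prev
  at_risk[1] <- pop - eligible[1]
  for (y in seq_len(horizon)[-1]) {
    eligible[y] <- at_risk[y - 1] * inc
    at_risk[y] <- at_risk[y - 1] - eligible[y]
  }
  data.frame(year = seq_len(horizon), eligible_new = eligible,
             at_risk = at_risk)
}

#' Five-year budget impact of a screening strategy
#'
#' Payer-perspective, undiscounted projection counting only the direct
#' medical costs of the screening tests themselves (no post-screening
#' management, treatment or non-medical costs). Per newly eligible person
#' the expected outlay is `u1*c1 + u1*P(step-1 positive)*u2*c_TE` for a
#' stepwise strategy or `u_TE*c_TE` for TE alone; the step-1 positivity rate
#' uses the significant-fibrosis prevalence of the model profile at the
#' configured screening age.
#'
#' @param params A `fib_params` (supplies test accuracy, unit costs and the
#'   prevalence profile).
#' @param strategy Strategy id.
#' @param inputs BIA inputs, default `params$bia`.
#' @param population BIA population: `"mets"`, `"obesity"` or `"both"`;
#'   default the model population.
#' @param uptake_stage1,uptake_te Optional uptake overrides for scenario
#'   analysis; default the strategy's configured rates.
#' @return Data frame of class `fib_bia`: per year, newly eligible persons,
#'   tests by type, cost in THB and USD; a `total` row sums the five years.
#'   Attributes carry the annual average.
#' @export
#' @examples
#' p <- default_parameters("mets")
#' compute_budget(p, "fib4_te")
compute_budget <- function(params, strategy, inputs = params$bia,
                           population = params$population,
                           uptake_stage1 = NULL, uptake_te = NULL) {
  strat <- .resolve_strategy(strategy, params)
  if (!is.null(uptake_stage1)) strat$uptake_stage1 <- uptake_stage1
  if (!is.null(uptake_te)) strat$uptake_te <- uptake_te

  proj <- project_eligible_population(inputs, population)
  cs <- params$costs$screening

  if (!isTRUE(strat$screen)) {
    per_step1 <- 0; per_te <- 0; per_cost <- 0
  } else if (!is.null(strat$stage1)) {
    pi <- .sigfib_prev_at(params, params$start_age)
    t1 <- params$tests[[strat$stage1]]
    p_pos1 <- pi * t1$sens + (1 - pi) * (1 - t1$spec)
    per_step1 <- strat$uptake_stage1
    per_te <- strat$uptake_stage1 * p_pos1 * strat$uptake_te
    per_cost <- per_step1 * unname(cs[strat$stage1]) + per_te * unname(cs["te"])
  } else {
    per_step1 <- 0
    per_te <- strat$uptake_te
    per_cost <- per_te * unname(cs["te"])
  }

  df <- data.frame(
    year = proj$year,
    eligible_new = proj$eligible_new,
    step1_tests = proj$eligible_new * per_step1,
    te_tests = proj$eligible_new * per_te,
    cost_thb = proj$eligible_new * per_cost
  )
  df$cost_usd <- thb_to_usd(df$cost_thb, params$econ$thb_per_usd)
  total <- data.frame(year = NA_integer_,
                      eligible_new = sum(df$eligible_new),
                      step1_tests = sum(df$step1_tests),
                      te_tests = sum(df$te_tests),
                      cost_thb = sum(df$cost_thb),
                      cost_usd = sum(df$cost_usd))
  out <- rbind(df, total)
  attr(out, "annual_average_thb") <- mean(df$cost_thb)
  attr(out, "strategy") <- strat$id
  attr(out, "population") <- population
  class(out) <- c("fib_bia", "data.frame")
  out
}

#' @export
print.fib_bia <- function(x, ...) {
  cat(sprintf("Budget impact: %s, population %s (undiscounted)\n",
              attr(x, "strategy"), attr(x, "population")))
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], function(v) signif(v, 6))
  print(y, row.names = FALSE)
  cat(sprintf("annual average: %.1f million THB\n",
              attr(x, "annual_average_thb") / 1e6))
  invisible(x)
}
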