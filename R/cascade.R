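#' Partition a cohort through the screening decision tree
#'
#' Applies a strategy's test sequence to the population, using each test's
#' sensitivity and specificity against significant fibrosis (true stage
#' F2-F4) and the strategy's uptake rates, and returns the mass fraction in
#' every decision-tree leaf. For a stepwise strategy the leaves are:
#' not screened; step-1 negative; step-1 positive but not attending TE;
#' TE negative; TE positive with true F2-F4 (`treated_true`); and TE positive
#' without true F2-F4 (`treated_false`, who incur intervention costs without
#' benefit). Step-1 tests and TE are treated as conditionally independent
#' given true fibrosis status.
#'
#' @param strategy Strategy id (see [default_strategies()]) or a strategy
#'   definition list.
#' @param params A `fib_params` object.
#' @param age Age in years used to look up the significant-fibrosis
#'   prevalence band; defaults to the configured start age.
#' @return Object of class `fib_cascade`: `fractions` (named, sums to 1),
#'   `tests_per_person` (expected tests by type), `screening_cost` (expected
#'   THB per person), and the prevalence and positivity rates used.
#' @export
#' @examples
#' p <- default_parameters("mets")
#' classify_cohort("fib4_te", p)$fractions
classify_cohort <- function(strategy, params, age = params$start_age) {
  strat <- .resolve_strategy(strategy, params)
  pi <- .sigfib_prev_at(params, age)

  if (!isTRUE(strat$screen)) {
    fr <- c(unscreened = 1, step1_negative = 0, referred_not_attending = 0,
            te_negative = 0, treated_true = 0, treated_false = 0)
    return(structure(list(strategy = strat$id, fractions = fr,
                          tests_per_person = c(stage1 = 0, te = 0),
                          screening_cost = 0, sigfib_prev = pi,
                          p_step1_positive = NA_real_),
                     class = "fib_cascade"))
  }

  te <- params$tests$te
  c_te <- unname(params$costs$screening["te"])

  if (!is.null(strat$stage1)) {
    t1 <- params$tests[[strat$stage1]]
    if (is.null(t1)) stop("unknown stage-1 test: ", strat$stage1, call. = FALSE)
    u1 <- strat$uptake_stage1
    u2 <- strat$uptake_te
    p_pos1 <- pi * t1$sens + (1 - pi) * (1 - t1$spec)
    fr <- c(
      unscreened = 1 - u1,
      step1_negative = u1 * (pi * (1 - t1$sens) + (1 - pi) * t1$spec),
      referred_not_attending = u1 * p_pos1 * (1 - u2),
      te_negative = u1 * u2 * (pi * t1$sens * (1 - te$sens) +
                                 (1 - pi) * (1 - t1$spec) * te$spec),
      treated_true = u1 * pi * t1$sens * u2 * te$sens,
      treated_false = u1 * (1 - pi) * (1 - t1$spec) * u2 * (1 - te$spec)
    )
    tests <- c(stage1 = u1, te = u1 * p_pos1 * u2)
    cost <- u1 * unname(params$costs$screening[strat$stage1]) +
      tests[["te"]] * c_te
  } else {
    u <- strat$uptake_te
    p_pos1 <- NA_real_
    fr <- c(
      unscreened = 1 - u,
      step1_negative = 0,
      referred_not_attending = 0,
      te_negative = u * (pi * (1 - te$sens) + (1 - pi) * te$spec),
      treated_true = u * pi * te$sens,
      treated_false = u * (1 - pi) * (1 - te$spec)
    )
    tests <- c(stage1 = 0, te = u)
    cost <- u * c_te
  }
  stopifnot(abs(sum(fr) - 1) < 1e-12)
  structure(list(strategy = strat$id, fractions = fr,
                 tests_per_person = tests,
                 screening_cost = unname(cost), sigfib_prev = pi,
                 p_step1_positive = p_pos1),
            class = "fib_cascade")
}

.resolve_strategy <- function(strategy, params) {
  if (is.character(strategy)) {
    strat <- params$strategies[[strategy]]
    if (is.null(strat)) stop("unknown strategy: ", strategy, call. = FALSE)
    strat
  } else strategy
}

#' Expected screening cost per eligible person
#'
#' Sum over tests of expected tests performed times unit cost; for a
#' stepwise strategy `u1*c1 + u1*P(step-1 positive)*u2*c_TE`.
#'
#' @param strategy Strategy id or definition.
#' @param params A `fib_params`.
#' @param cascade Optionally, a precomputed [classify_cohort()] result for
#'   the same strategy.
#' @param age Age for the prevalence band.
#' @return Money (THB) per person.
#' @export
expected_screening_cost <- function(strategy, params,
                                    cascade = NULL, age = params$start_age) {
  if (is.null(cascade)) cascade <- classify_cohort(strategy, params, age)
  cascade$screening_cost
}

#' Cost per true positive case detected
#'
#' Ratio of the expected per-person screening outlay to the mass of true
#' positives started on treatment (`treated_true`). Because the exact
#' component convention behind published figures varies, three conventions
#' are available and all can be reported: screening tests only; tests plus
#' the non-medical (food and transportation) cost of each test visit; and
#' additionally the first-year lifestyle-programme cost of everyone started
#' on the intervention (true and false positives).
#'
#' @param strategy Strategy id or definition.
#' @param params A `fib_params`.
#' @param components Character vector among `"tests_only"`, `"tests_visits"`,
#'   `"tests_visits_lifestyle"`.
#' @param age Age for the prevalence band.
#' @return Named numeric vector, THB per true positive, one per convention.
#' @export
cost_per_true_positive <- function(strategy, params,
                                   components = c("tests_only",
                                                  "tests_visits",
                                                  "tests_visits_lifestyle"),
                                   age = params$start_age) {
  components <- match.arg(components, several.ok = TRUE)
  cs <- classify_cohort(strategy, params, age)
  tp <- cs$fractions[["treated_true"]]
  if (tp <= 0)
    stop("cost per true positive undefined: treated-true mass is 0",
         call. = FALSE)
  visits <- sum(cs$tests_per_person) * params$costs$nonmedical_per_visit
  lifestyle1 <- (cs$fractions[["treated_true"]] +
                   cs$fractions[["treated_false"]]) *
    params$treatment$lifestyle_cost
  num <- c(tests_only = cs$screening_cost,
           tests_visits = cs$screening_cost + visits,
           tests_visits_lifestyle = cs$screening_cost + visits + lifestyle1)
  num[components] / tp
}

#' Build the initial cohort strata for the Markov engine
#'
#' Each decision-tree leaf becomes a stratum with a mass and an initial
#' distribution over the 13 health states obtained by Bayes' rule from the
#' leaf's test outcomes. Unconditionally, mass `1 - P(MASLD)` starts in
#' NO_MASLD, `P(MASLD) - P(F2+)` in F0/F1 (configurable split), and `P(F2+)`
#' in F2/F3/F4_CC (configurable split). TE-positive strata are treated: the
#' true positives split into adherent (progression slowed by the relative
#' risk reduction) and non-adherent sub-strata by the adherence rate, and
#' both true and false positives accrue the lifestyle-programme cost.
#'
#' @inheritParams classify_cohort
#' @return List of strata, each with `label`, `mass`, `init` (13-state
#'   probability vector), `treated`, `adherent`, `lifestyle`.
#' @export
build_initial_strata <- function(strategy, params, age = params$start_age) {
  strat <- .resolve_strategy(strategy, params)
  pi <- .sigfib_prev_at(params, age)
  p_masld <- .masld_prev_at(params, age)
  # Table-1 prevalence bands can put P(F2+) above P(MASLD) at high ages;
  # clamp the effective MASLD prevalence so the F0/F1 pool is never negative
  p_masld <- max(p_masld, pi)

  s01 <- params$splits$f0_f1
  s24 <- params$splits$f2_f3_f4
  prior <- setNames(numeric(.n_states()), .states())
  prior["NO_MASLD"] <- 1 - p_masld
  prior[c("F0", "F1")] <- (p_masld - pi) * s01
  prior[c("F2", "F3", "F4_CC")] <- pi * s24

  sig <- .states() %in% .sigfib_states()

  # per-leaf likelihood of the observed test path given true condition
  # (significant fibrosis yes/no); uptake factors are condition-independent
  leaf_def <- function(label, u_factor, l_sig, l_nonsig,
                       treated = FALSE, lifestyle = FALSE) {
    w <- prior * ifelse(sig, l_sig, l_nonsig) * u_factor
    mass <- sum(w)
    init <- if (mass > 0) w / mass else prior
    list(label = label, mass = unname(mass), init = init,
         treated = treated, adherent = FALSE, lifestyle = lifestyle)
  }

  if (!isTRUE(strat$screen))
    return(list(leaf_def("unscreened", 1, 1, 1)))

  te <- params$tests$te
  strata <- if (!is.null(strat$stage1)) {
    t1 <- params$tests[[strat$stage1]]
    u1 <- strat$uptake_stage1; u2 <- strat$uptake_te
    list(
      leaf_def("unscreened", 1 - u1, 1, 1),
      leaf_def("step1_negative", u1, 1 - t1$sens, t1$spec),
      leaf_def("referred_not_attending", u1 * (1 - u2), t1$sens, 1 - t1$spec),
      leaf_def("te_negative", u1 * u2,
               t1$sens * (1 - te$sens), (1 - t1$spec) * te$spec),
      leaf_def("treated_true", u1 * u2, t1$sens * te$sens, 0,
               treated = TRUE, lifestyle = TRUE),
      leaf_def("treated_false", u1 * u2, 0, (1 - t1$spec) * (1 - te$spec),
               treated = TRUE, lifestyle = TRUE)
    )
  } else {
    u <- strat$uptake_te
    list(
      leaf_def("unscreened", 1 - u, 1, 1),
      leaf_def("te_negative", u, 1 - te$sens, te$spec),
      leaf_def("treated_true", u, te$sens, 0,
               treated = TRUE, lifestyle = TRUE),
      leaf_def("treated_false", u, 0, 1 - te$spec,
               treated = TRUE, lifestyle = TRUE)
    )
  }

  # adherence sub-split of the true positives: only adherent individuals
  # receive the progression benefit; everyone treated pays for the programme
  adh <- params$treatment$adherence
  out <- list()
  for (st in strata) {
    if (st$label == "treated_true" && adh < 1) {
      a <- st; a$mass <- st$mass * adh; a$adherent <- TRUE
      a$label <- "treated_true_adherent"
      n <- st; n$mass <- st$mass * (1 - adh)
      n$label <- "treated_true_nonadherent"
      out <- c(out, list(a, n))
    } else {
      if (st$label == "treated_true") st$adherent <- TRUE
      out <- c(out, list(st))
    }
  }
  stopifnot(abs(sum(vapply(out, `[[`, 0, "mass")) - 1) < 1e-12)
  out
}

#' @export
print.fib_cascade <- function(x, ...) {
  cat("<fib_cascade>", x$strategy,
      sprintf(" (sig-fib prevalence %.3f)\n", x$sigfib_prev))
  print(round(x$fractions, 6))
  cat(sprintf("  expected tests/person: stage1 %.3f, TE %.3f; cost %.2f THB\n",
              x$tests_per_person[["stage1"]], x$tests_per_person[["te"]],
              x$screening_cost))
  invisible(x)
}

#' Export cascade strata as a data frame
#'
#' One row per stratum with mass, flags and the initial state distribution.
#'
#' @param strategy Strategy id or definition.
#' @param params A `fib_params`.
#' @param age Age for the prevalence band.
#' @return Data frame suitable for CSV export.
#' @export
strata_table <- function(strategy, params, age = params$start_age) {
  strata <- build_initial_strata(strategy, params, age)
  df <- do.call(rbind, lapply(strata, function(s) {
    cbind(data.frame(stratum = s$label, mass = s$mass, treated = s$treated,
                     adherent = s$adherent, lifestyle = s$lifestyle),
          as.data.frame(as.list(s$init)))
  }))
  rownames(df) <- NULL
  df
}
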