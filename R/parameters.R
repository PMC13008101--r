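#' Build the base-case parameter set
#'
#' Assembles the full numeric state of the model for one target population:
#' screening-test accuracy, strategy definitions and uptake rates, age-banded
#' MASLD and significant-fibrosis prevalence, MASLD incidence, annual fibrosis
#' transition probabilities, lifestyle-intervention effect (relative risk
#' reduction of progression), state utilities and annual costs, non-medical
#' visit costs, mortality inputs (life table, hazard ratios 1.29 non-cirrhotic
#' and 3.13 cirrhotic, cause-of-death splits, post-transplant mortality), and
#' economic settings (3% discounting, willingness-to-pay 160,000 THB/QALY,
#' 34.64 THB/USD). Every value carries an uncertainty specification used by
#' the one-way and probabilistic sensitivity analyses.
#'
#' @param population `"mets"` (metabolic syndrome) or `"obesity"`.
#' @param start_age Screening age in years (base case 50).
#' @param max_age Maximum model age; the cohort is followed to this age.
#' @param life_table Data frame with columns `age` and `qx` (annual all-cause
#'   death probability). Defaults to the package's synthetic Gompertz life
#'   table (life expectancy ~77 y at birth), see [synth_life_table()].
#' @return A validated object of class `fib_params`.
#' @export
#' @examples
#' p <- default_parameters("mets")
#' p$tests$fib4$sens
default_parameters <- function(population = c("mets", "obesity"),
                               start_age = 50, max_age = 100,
                               life_table = NULL) {
  population <- match.arg(population)
  if (is.null(life_table))
    life_table <- synth_life_table(5.5e-5, 0.09, 0:max(100, max_age))

  mets <- population == "mets"

  params <- list(
    population = population,
    start_age = start_age,
    max_age = max_age,
    strategies = default_strategies(),
    tests = list(
      fib4 = list(sens = 0.660, spec = 0.650),
      safe = list(sens = 0.873, spec = 0.351),
      te   = list(sens = 0.801, spec = 0.730)
    ),
    epi = list(
      # MASLD prevalence by age band (18-39.9, 40-59.9, >= 60)
      masld_prev = c(a18 = 0.353, a40 = 0.348, a60 = 0.244),
      # prevalence of MASLD with significant fibrosis (F2+), by decade band
      sigfib_prev = if (mets)
        c(a30 = 0.174, a40 = 0.108, a50 = 0.116, a60 = 0.114,
          a70 = 0.105, a80 = 0.407)
      else
        c(a30 = 0.250, a40 = 0.227, a50 = 0.241, a60 = 0.361,
          a70 = 0.324, a80 = 0.522),
      # MASLD incidence among the population, events per person-year
      incidence_rate = if (mets) 0.0549 else 0.0509
    ),
    transitions = c(
      no_masld_f0 = if (mets) 0.055 else 0.051,
      f0_no_masld = 0.024, f0_f1 = 0.063,
      f1_f0 = 0.025, f1_f2 = 0.067,
      f2_f1 = 0.045, f2_f3 = 0.056,
      f3_f2 = 0.058, f3_f4 = 0.044,
      f4_f3 = 0.046, f4_dc = 0.043, f4_hcc = 0.008,
      dc_hcc = 0.029, dc_lt = 0.003, hcc_lt = 0.012
    ),
    treatment = list(
      rrr = 0.204,            # relative risk reduction of fibrosis progression
      adherence = 1.0,        # fraction of treated who adhere (base case)
      lifestyle_cost = 1426.8, # THB per year
      lifestyle_duration = Inf # years the programme cost accrues (lifelong)
    ),
    utilities = if (mets)
      c(no_masld = 0.890, f0_f3 = 0.840, f4 = 0.748, dc = 0.603,
        hcc = 0.380, lt = 0.570, post_lt = 0.683)
    else
      c(no_masld = 0.908, f0_f3 = 0.908, f4 = 0.748, dc = 0.603,
        hcc = 0.380, lt = 0.570, post_lt = 0.683),
    costs = list(
      screening = c(fib4 = 271.0, safe = 355.4, te = 2000.0),
      state = if (mets)
        c(no_masld = 2668.5, f0_f3 = 8294.1, f4 = 38394.5, dc = 151164.1,
          hcc = 184822.2, lt = 683432.3, post_lt = 110287.1)
      else
        c(no_masld = 0, f0_f3 = 14583.7, f4 = 37568.2, dc = 151164.1,
          hcc = 184822.2, lt = 683432.3, post_lt = 110287.1),
      # hospital-database-derived state costs, scaled by the cost-to-charge
      # ratio; literature-based costs (DC and beyond) are not
      state_hospital_derived = c(no_masld = TRUE, f0_f3 = TRUE, f4 = TRUE,
                                 dc = FALSE, hcc = FALSE, lt = FALSE,
                                 post_lt = FALSE),
      nonmedical_per_visit = 245.9, # tertiary-hospital food + transportation
      visits = c(no_masld = if (mets) 2 else 0, f0_f3 = 2, f4 = 2,
                 dc = 4, hcc = 4, lt = 4, post_lt = 4)
    ),
    mortality = list(
      life_table = life_table,
      metabolic_multiplier = 1.0,
      hr_noncirrhotic = 1.29,
      hr_cirrhotic = 3.13,
      post_lt_mortality = 0.05,
      lt_age_max = 70, # transplant entry permitted while age <= 70
      cause_split = list(
        no_masld     = c(cvd = 0.5, liver = 0.0, other = 0.5),
        noncirrhotic = c(cvd = 0.5, liver = 0.0, other = 0.5),
        cirrhotic    = c(cvd = 0.4, liver = 0.4, other = 0.2),
        lt           = c(cvd = 0.0, liver = 1.0, other = 0.0)
      )
    ),
    econ = list(
      discount = 0.03,
      wtp = 160000,
      thb_per_usd = 34.64,
      ctc_ratio = 1.0
    ),
    splits = list(
      # allocation of the non-significant MASLD pool across F0:F1 and of the
      # significant-fibrosis pool across F2:F3:F4_CC (assumptions, config knobs)
      f0_f1 = c(f0 = 0.5, f1 = 0.5),
      f2_f3_f4 = c(f2 = 0.60, f3 = 0.25, f4 = 0.15)
    ),
    bia = default_bia_inputs(),
    psa = list(n = 1000, seed = 1),
    seed = 1
  )
  params$uncertainty <- default_uncertainty(population)
  params <- structure(params, class = "fib_params")
  validate_parameters(params)
  params
}

#' Default screening strategy definitions
#'
#' Four strategies: no screening; FIB-4 triage (cutoff >= 1.3) followed by TE;
#' SAFE triage (cutoff >= 0) followed by TE; TE alone (positivity LSM >= 7.0
#' kPa). Stepwise strategies use 90% step-1 uptake and 90% confirmatory-TE
#' uptake; TE alone uses 80%.
#'
#' @return Named list of strategy definitions.
#' @export
default_strategies <- function() {
  list(
    no_screen = list(id = "no_screen", label = "No screening",
                     screen = FALSE,
                     uptake_stage1 = 0, uptake_te = 0),
    fib4_te = list(id = "fib4_te", label = "FIB-4 + TE",
                   screen = TRUE, stage1 = "fib4",
                   uptake_stage1 = 0.90, uptake_te = 0.90,
                   cutoffs = "FIB-4 >= 1.3; LSM >= 7.0 kPa"),
    safe_te = list(id = "safe_te", label = "SAFE + TE",
                   screen = TRUE, stage1 = "safe",
                   uptake_stage1 = 0.90, uptake_te = 0.90,
                   cutoffs = "SAFE >= 0; LSM >= 7.0 kPa"),
    te_alone = list(id = "te_alone", label = "TE alone",
                    screen = TRUE,
                    uptake_stage1 = 0, uptake_te = 0.80,
                    cutoffs = "LSM >= 7.0 kPa")
  )
}

# Uncertainty specifications keyed by parameter id. Each entry: distribution
# family, se (or range), and how the one-way sweep bounds it ("ci" = mean
# +/- 1.96 se truncated to the domain, "pct25" = +/- 25%, "range" = explicit
# low/high, "none" = excluded from the sweep).
default_uncertainty <- function(population = "mets") {
  mets <- population == "mets"
  u <- list(
    test_fib4_sens = list(dist = "beta", se = 0.012, owsa = "ci"),
    test_fib4_spec = list(dist = "beta", se = 0.014, owsa = "ci"),
    test_safe_sens = list(dist = "beta", se = 0.008, owsa = "ci"),
    test_safe_spec = list(dist = "beta", se = 0.014, owsa = "ci"),
    test_te_sens   = list(dist = "beta", se = 0.021, owsa = "ci"),
    test_te_spec   = list(dist = "beta", se = 0.026, owsa = "ci"),
    rate_stage1      = list(dist = "uniform_range", se = 0, low = 0.50,
                            high = 1.00, owsa = "range"),
    rate_te_followup = list(dist = "uniform_range", se = 0, low = 0.65,
                            high = 1.00, owsa = "range"),
    rate_te_alone    = list(dist = "uniform_range", se = 0, low = 0.30,
                            high = 1.00, owsa = "range"),
    prev_masld_18 = list(dist = "beta", se = 0.013, owsa = "ci"),
    prev_masld_40 = list(dist = "beta", se = 0.002, owsa = "ci"),
    prev_masld_60 = list(dist = "beta", se = 0.004, owsa = "ci"),
    prev_sigfib_30 = list(dist = "beta", se = if (mets) 0.079 else 0.056, owsa = "ci"),
    prev_sigfib_40 = list(dist = "beta", se = if (mets) 0.038 else 0.043, owsa = "ci"),
    prev_sigfib_50 = list(dist = "beta", se = if (mets) 0.020 else 0.029, owsa = "ci"),
    prev_sigfib_60 = list(dist = "beta", se = if (mets) 0.020 else 0.028, owsa = "ci"),
    prev_sigfib_70 = list(dist = "beta", se = if (mets) 0.029 else 0.044, owsa = "ci"),
    prev_sigfib_80 = list(dist = "beta", se = if (mets) 0.095 else 0.104, owsa = "ci"),
    inc_masld = list(dist = "beta", se = if (mets) 0.0169 else 0.0033, owsa = "ci"),
    tp_no_masld_f0 = list(dist = "beta", se = if (mets) 0.017 else 0.003, owsa = "ci"),
    tp_f0_no_masld = list(dist = "beta", se = 0.013, owsa = "ci"),
    tp_f0_f1 = list(dist = "beta", se = 0.025, owsa = "ci"),
    tp_f1_f0 = list(dist = "beta", se = 0.017, owsa = "ci"),
    tp_f1_f2 = list(dist = "beta", se = 0.025, owsa = "ci"),
    tp_f2_f1 = list(dist = "beta", se = 0.022, owsa = "ci"),
    tp_f2_f3 = list(dist = "beta", se = 0.024, owsa = "ci"),
    tp_f3_f2 = list(dist = "beta", se = 0.024, owsa = "ci"),
    tp_f3_f4 = list(dist = "beta", se = 0.021, owsa = "ci"),
    tp_f4_f3 = list(dist = "beta", se = 0.022, owsa = "ci"),
    tp_f4_dc = list(dist = "beta", se = 0.041, owsa = "ci"),
    tp_f4_hcc = list(dist = "beta", se = 0.017, owsa = "ci"),
    tp_dc_hcc = list(dist = "beta", se = 0.045, owsa = "ci"),
    tp_dc_lt = list(dist = "beta", se = 0.012, owsa = "ci"),
    tp_hcc_lt = list(dist = "beta", se = 0.027, owsa = "ci"),
    rrr = list(dist = "lognormal_rr", se = 0.124, owsa = "ci"),
    u_no_masld = list(dist = "beta", se = if (mets) 0.003 else 0.004, owsa = "ci"),
    u_f0_f3 = list(dist = "beta", se = if (mets) 0.071 else 0.131, owsa = "ci"),
    u_f4 = list(dist = "beta", se = 0.042, owsa = "ci"),
    u_dc = list(dist = "beta", se = 0.022, owsa = "ci"),
    u_hcc = list(dist = "beta", se = 0.015, owsa = "ci"),
    u_lt = list(dist = "beta", se = 0.015, owsa = "ci"),
    u_post_lt = list(dist = "beta", se = 0.015, owsa = "ci"),
    # FIB-4/SAFE screening-cost SEs propagated from their laboratory
    # components in quadrature (AST, ALT, platelet; + globulin for SAFE)
    c_screen_fib4 = list(dist = "gamma", se = 39.35, owsa = "pct25"),
    c_screen_safe = list(dist = "gamma", se = 44.62, owsa = "pct25"),
    c_screen_te = list(dist = "gamma", se = 500.0, owsa = "pct25"),
    c_lifestyle = list(dist = "gamma", se = 356.7, owsa = "pct25"),
    c_state_no_masld = if (mets)
      list(dist = "gamma", se = 667.1, owsa = "pct25")
    else list(dist = "fixed", se = 0, owsa = "none"),
    c_state_f0_f3 = list(dist = "gamma", se = if (mets) 2073.5 else 3645.9, owsa = "pct25"),
    c_state_f4 = list(dist = "gamma", se = if (mets) 9598.6 else 9392.0, owsa = "pct25"),
    c_state_dc = list(dist = "gamma", se = 37791.0, owsa = "pct25"),
    c_state_hcc = list(dist = "gamma", se = 46205.5, owsa = "pct25"),
    c_state_lt = list(dist = "gamma", se = 170858.1, owsa = "pct25"),
    c_state_post_lt = list(dist = "gamma", se = 27571.8, owsa = "pct25"),
    c_visit = list(dist = "gamma", se = 16.06, owsa = "pct25"),
    # deterministic in the PSA, swept one-way over stated ranges
    adherence = list(dist = "fixed", se = 0, low = 0.60, high = 1.00, owsa = "range"),
    ctc_ratio = list(dist = "fixed", se = 0, low = 0.6, high = 1.2, owsa = "range"),
    discount = list(dist = "fixed", se = 0, low = 0, high = 0.06, owsa = "range"),
    hr_noncirrhotic = list(dist = "fixed", se = 0, low = 1.04, high = 1.59, owsa = "range"),
    hr_cirrhotic = list(dist = "fixed", se = 0, low = 1.08, high = 9.12, owsa = "range")
  )
  u
}

# parameter id -> list of paths into the fib_params structure (several paths
# when one sampled quantity feeds multiple fields, e.g. the shared step-1
# uptake of the two stepwise strategies)
.param_paths <- function() {
  list(
    test_fib4_sens = list(c("tests", "fib4", "sens")),
    test_fib4_spec = list(c("tests", "fib4", "spec")),
    test_safe_sens = list(c("tests", "safe", "sens")),
    test_safe_spec = list(c("tests", "safe", "spec")),
    test_te_sens = list(c("tests", "te", "sens")),
    test_te_spec = list(c("tests", "te", "spec")),
    rate_stage1 = list(c("strategies", "fib4_te", "uptake_stage1"),
                       c("strategies", "safe_te", "uptake_stage1")),
    rate_te_followup = list(c("strategies", "fib4_te", "uptake_te"),
                            c("strategies", "safe_te", "uptake_te")),
    rate_te_alone = list(c("strategies", "te_alone", "uptake_te")),
    prev_masld_18 = list(c("epi", "masld_prev", "a18")),
    prev_masld_40 = list(c("epi", "masld_prev", "a40")),
    prev_masld_60 = list(c("epi", "masld_prev", "a60")),
    prev_sigfib_30 = list(c("epi", "sigfib_prev", "a30")),
    prev_sigfib_40 = list(c("epi", "sigfib_prev", "a40")),
    prev_sigfib_50 = list(c("epi", "sigfib_prev", "a50")),
    prev_sigfib_60 = list(c("epi", "sigfib_prev", "a60")),
    prev_sigfib_70 = list(c("epi", "sigfib_prev", "a70")),
    prev_sigfib_80 = list(c("epi", "sigfib_prev", "a80")),
    inc_masld = list(c("epi", "incidence_rate")),
    tp_no_masld_f0 = list(c("transitions", "no_masld_f0")),
    tp_f0_no_masld = list(c("transitions", "f0_no_masld")),
    tp_f0_f1 = list(c("transitions", "f0_f1")),
    tp_f1_f0 = list(c("transitions", "f1_f0")),
    tp_f1_f2 = list(c("transitions", "f1_f2")),
    tp_f2_f1 = list(c("transitions", "f2_f1")),
    tp_f2_f3 = list(c("transitions", "f2_f3")),
    tp_f3_f2 = list(c("transitions", "f3_f2")),
    tp_f3_f4 = list(c("transitions", "f3_f4")),
    tp_f4_f3 = list(c("transitions", "f4_f3")),
    tp_f4_dc = list(c("transitions", "f4_dc")),
    tp_f4_hcc = list(c("transitions", "f4_hcc")),
    tp_dc_hcc = list(c("transitions", "dc_hcc")),
    tp_dc_lt = list(c("transitions", "dc_lt")),
    tp_hcc_lt = list(c("transitions", "hcc_lt")),
    rrr = list(c("treatment", "rrr")),
    adherence = list(c("treatment", "adherence")),
    c_lifestyle = list(c("treatment", "lifestyle_cost")),
    u_no_masld = list(c("utilities", "no_masld")),
    u_f0_f3 = list(c("utilities", "f0_f3")),
    u_f4 = list(c("utilities", "f4")),
    u_dc = list(c("utilities", "dc")),
    u_hcc = list(c("utilities", "hcc")),
    u_lt = list(c("utilities", "lt")),
    u_post_lt = list(c("utilities", "post_lt")),
    c_screen_fib4 = list(c("costs", "screening", "fib4")),
    c_screen_safe = list(c("costs", "screening", "safe")),
    c_screen_te = list(c("costs", "screening", "te")),
    c_state_no_masld = list(c("costs", "state", "no_masld")),
    c_state_f0_f3 = list(c("costs", "state", "f0_f3")),
    c_state_f4 = list(c("costs", "state", "f4")),
    c_state_dc = list(c("costs", "state", "dc")),
    c_state_hcc = list(c("costs", "state", "hcc")),
    c_state_lt = list(c("costs", "state", "lt")),
    c_state_post_lt = list(c("costs", "state", "post_lt")),
    c_visit = list(c("costs", "nonmedical_per_visit")),
    ctc_ratio = list(c("econ", "ctc_ratio")),
    discount = list(c("econ", "discount")),
    hr_noncirrhotic = list(c("mortality", "hr_noncirrhotic")),
    hr_cirrhotic = list(c("mortality", "hr_cirrhotic"))
  )
}

.get_path <- function(x, path) Reduce(function(a, k) a[[k]], path, x)

.set_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
    return(x)
  }
  x[[path[1L]]] <- .set_path(x[[path[1L]]], path[-1L], value)
  x
}

#' Enumerate the model's uncertain parameters
#'
#' Joins each uncertainty specification to its location(s) in the parameter
#' set and the current base-case mean; the result drives both [run_psa()] and
#' [one_way_sweep()].
#'
#' @param params A `fib_params` object.
#' @return Data frame with columns `id`, `dist`, `mean`, `se`, `low`, `high`,
#'   `owsa`.
#' @export
parameter_registry <- function(params) {
  paths <- .param_paths()
  ids <- intersect(names(paths), names(params$uncertainty))
  rows <- lapply(ids, function(id) {
    u <- params$uncertainty[[id]]
    data.frame(id = id, dist = u$dist,
               mean = .get_path(params, paths[[id]][[1]]),
               se = u$se %||% 0,
               low = u$low %||% NA_real_, high = u$high %||% NA_real_,
               owsa = u$owsa %||% "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# dist_spec for one registry row given current mean
.spec_for <- function(row) {
  if (row$dist == "uniform_range")
    dist_spec("uniform_range", mean = row$mean, se = 0,
              low = row$low, high = row$high)
  else if (row$dist == "fixed")
    dist_spec("fixed", mean = row$mean, se = 0)
  else
    dist_spec(row$dist, mean = row$mean, se = row$se)
}

#' Draw one probabilistic parameter set
#'
#' Independently samples every uncertain parameter from its specified
#' distribution (beta for probabilities and utilities, gamma for costs,
#' log-normal relative risk for the treatment effect, uniform for
#' range-only uptake rates); deterministic parameters are untouched. The
#' same seed always reproduces the same draw.
#'
#' @param base A `fib_params` object (means and ses define the distributions).
#' @param seed Integer seed for the draw.
#' @return A new `fib_params` with sampled values; the draws are attached as
#'   attribute `"draws"`.
#' @export
sample_parameter_set <- function(base, seed) {
  reg <- parameter_registry(base)
  set.seed(seed)
  out <- base
  paths <- .param_paths()
  draws <- numeric(0)
  for (i in seq_len(nrow(reg))) {
    row <- reg[i, ]
    if (row$dist == "fixed" || (row$dist != "uniform_range" && row$se == 0))
      next
    v <- build_distribution(.spec_for(row))(1)
    for (p in paths[[row$id]]) out <- .set_path(out, p, v)
    draws[row$id] <- v
  }
  attr(out, "draws") <- draws
  out
}

# ---- validation -----------------------------------------------------------

.check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1))
    stop("domain error: ", what, " must lie in [0, 1], got ",
         paste(signif(x, 4), collapse = ", "), call. = FALSE)
}

# raw per-state disease exits (annual probabilities, before mortality
# competition); used by both the validator and the matrix builder
.state_exits <- function(tp) {
  list(
    NO_MASLD = c(F0 = unname(tp["no_masld_f0"])),
    F0 = c(NO_MASLD = unname(tp["f0_no_masld"]), F1 = unname(tp["f0_f1"])),
    F1 = c(F0 = unname(tp["f1_f0"]), F2 = unname(tp["f1_f2"])),
    F2 = c(F1 = unname(tp["f2_f1"]), F3 = unname(tp["f2_f3"])),
    F3 = c(F2 = unname(tp["f3_f2"]), F4_CC = unname(tp["f3_f4"])),
    F4_CC = c(F3 = unname(tp["f4_f3"]), DC = unname(tp["f4_dc"]),
              HCC = unname(tp["f4_hcc"])),
    DC = c(HCC = unname(tp["dc_hcc"]), LT = unname(tp["dc_lt"])),
    HCC = c(LT = unname(tp["hcc_lt"]))
  )
}

#' Validate a parameter set
#'
#' Checks every structural invariant: probabilities and utilities in
#' \[0, 1\], non-negative costs, per-state disease exits summing to at most
#' one, stage splits and cause-of-death splits summing to one, a life table
#' covering the whole model age range, and a non-empty strategy list.
#'
#' @param params A `fib_params` object.
#' @return Invisibly `TRUE`; stops with an informative message on violation.
#' @export
validate_parameters <- function(params) {
  if (length(params$strategies) == 0)
    stop("validation error: strategy list is empty", call. = FALSE)
  if (!params$population %in% c("mets", "obesity"))
    stop("validation error: population must be 'mets' or 'obesity'",
         call. = FALSE)
  for (t in names(params$tests)) {
    .check_prob(params$tests[[t]]$sens, paste0("tests$", t, "$sens"))
    .check_prob(params$tests[[t]]$spec, paste0("tests$", t, "$spec"))
  }
  for (s in params$strategies) {
    .check_prob(s$uptake_stage1 %||% 0, paste0("strategy ", s$id, " uptake_stage1"))
    .check_prob(s$uptake_te %||% 0, paste0("strategy ", s$id, " uptake_te"))
  }
  .check_prob(params$epi$masld_prev, "epi$masld_prev")
  .check_prob(params$epi$sigfib_prev, "epi$sigfib_prev")
  if (params$epi$incidence_rate < 0)
    stop("domain error: incidence_rate must be >= 0", call. = FALSE)
  .check_prob(params$transitions, "transitions")
  exits <- .state_exits(params$transitions)
  for (st in names(exits)) {
    if (sum(exits[[st]]) > 1)
      stop("infeasible parameters: disease exits from state ", st,
           " sum to ", signif(sum(exits[[st]]), 5), " > 1", call. = FALSE)
  }
  .check_prob(params$utilities, "utilities")
  if (any(params$costs$state < 0) || any(params$costs$screening < 0) ||
      params$costs$nonmedical_per_visit < 0 ||
      params$treatment$lifestyle_cost < 0)
    stop("domain error: costs must be >= 0", call. = FALSE)
  if (params$treatment$rrr < 0 || params$treatment$rrr >= 1)
    stop("domain error: treatment$rrr must lie in [0, 1)", call. = FALSE)
  .check_prob(params$treatment$adherence, "treatment$adherence")
  if (params$econ$discount < 0) stop("domain error: discount must be >= 0", call. = FALSE)
  if (params$econ$wtp < 0) stop("domain error: wtp must be >= 0", call. = FALSE)
  if (params$econ$ctc_ratio <= 0)
    stop("domain error: ctc_ratio must be > 0", call. = FALSE)
  m <- params$mortality
  if (m$hr_noncirrhotic <= 0 || m$hr_cirrhotic <= 0 ||
      m$metabolic_multiplier <= 0)
    stop("domain error: mortality multipliers must be > 0", call. = FALSE)
  .check_prob(m$post_lt_mortality, "post_lt_mortality")
  for (g in names(m$cause_split)) {
    cs <- m$cause_split[[g]]
    if (abs(sum(cs) - 1) > 1e-9 || any(cs < 0))
      stop("validation error: cause_split$", g, " must be >= 0 and sum to 1",
           call. = FALSE)
  }
  lt <- m$life_table
  if (!is.data.frame(lt) || !all(c("age", "qx") %in% names(lt)))
    stop("validation error: life_table needs columns age, qx", call. = FALSE)
  .check_prob(lt$qx, "life_table$qx")
  need <- params$start_age:params$max_age
  if (!all(need %in% lt$age))
    stop("validation error: life_table must cover ages ",
         params$start_age, "-", params$max_age, call. = FALSE)
  for (sp in names(params$splits)) {
    v <- params$splits[[sp]]
    if (abs(sum(v) - 1) > 1e-9 || any(v < 0))
      stop("validation error: splits$", sp, " must be >= 0 and sum to 1",
           call. = FALSE)
  }
  invisible(TRUE)
}

# ---- age-band lookups -----------------------------------------------------

.masld_prev_at <- function(params, age) {
  p <- params$epi$masld_prev
  if (age < 18) stop("no MASLD prevalence band defined for age ", age,
                     call. = FALSE)
  if (age < 40) unname(p["a18"]) else if (age < 60) unname(p["a40"])
  else unname(p["a60"])
}

.sigfib_prev_at <- function(params, age) {
  p <- params$epi$sigfib_prev
  if (age < 30)
    stop("no significant-fibrosis prevalence band defined for age ", age,
         call. = FALSE)
  band <- c("a30", "a40", "a50", "a60", "a70", "a80")[
    min(max(floor((age - 30) / 10) + 1, 1), 6)]
  unname(p[band])
}

.life_table_qx <- function(params, age) {
  lt <- params$mortality$life_table
  i <- match(age, lt$age)
  if (any(is.na(i)))
    stop("life table does not cover age ", paste(age[is.na(i)], collapse = ","),
         call. = FALSE)
  lt$qx[i]
}

# ---- configuration I/O ----------------------------------------------------

# YAML deserialisation returns nested lists; restore the numeric-vector /
# data-frame shapes the engine expects
.normalize_params <- function(params) {
  num <- function(v) {
    x <- unlist(v)
    if (is.character(x)) x <- as.numeric(x)
    storage.mode(x) <- "double"
    x
  }
  params$epi$masld_prev <- num(params$epi$masld_prev)
  params$epi$sigfib_prev <- num(params$epi$sigfib_prev)
  params$epi$incidence_rate <- as.numeric(params$epi$incidence_rate)
  params$transitions <- num(params$transitions)
  params$utilities <- num(params$utilities)
  params$costs$screening <- num(params$costs$screening)
  params$costs$state <- num(params$costs$state)
  params$costs$visits <- num(params$costs$visits)
  params$costs$state_hospital_derived <-
    as.logical(unlist(params$costs$state_hospital_derived))
  names(params$costs$state_hospital_derived) <- names(params$costs$state)
  params$costs$nonmedical_per_visit <-
    as.numeric(params$costs$nonmedical_per_visit)
  params$splits <- lapply(params$splits, num)
  params$mortality$cause_split <- lapply(params$mortality$cause_split, num)
  params$mortality$life_table <-
    as.data.frame(params$mortality$life_table)[, c("age", "qx")]
  params$treatment$lifestyle_duration <-
    as.numeric(params$treatment$lifestyle_duration)
  params
}

#' Load a parameter set from a YAML configuration file
#'
#' The configuration selects the population and start age and may override
#' any subset of the model parameters; everything not specified takes the
#' documented base-case default and is recorded in the provenance log
#' (attribute `"provenance"`). A `life_table` entry may be a path (relative
#' to the config file) to a two-column delimited text file with header
#' columns `age` and `qx`, or an inline list with those fields.
#'
#' @param config Path to a YAML file, or an already-parsed list.
#' @return A validated `fib_params` with attribute `"provenance"`.
#' @export
load_parameters <- function(config) {
  cfg_dir <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    cfg_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)

  prov <- character(0)
  note <- function(msg) prov <<- c(prov, msg)

  population <- config$population %||% {
    note("population: default 'mets'"); "mets"
  }
  start_age <- config$start_age %||% { note("start_age: default 50"); 50 }
  max_age <- config$max_age %||% { note("max_age: default 100"); 100 }

  life_table <- NULL
  lt_cfg <- config$life_table %||% config$mortality$life_table
  if (!is.null(lt_cfg)) {
    life_table <- if (is.character(lt_cfg)) {
      path <- lt_cfg
      if (!file.exists(path)) path <- file.path(cfg_dir, lt_cfg)
      read_life_table(path)
    } else {
      as.data.frame(lt_cfg)
    }
    config$mortality$life_table <- NULL
  } else note("life_table: synthetic Gompertz default")

  params <- default_parameters(population = population, start_age = start_age,
                               max_age = max_age, life_table = life_table)

  merge_section <- function(name, coerce = NULL) {
    if (is.null(config[[name]])) {
      note(paste0(name, ": all defaults"))
    } else {
      over <- config[[name]]
      cur <- params[[name]]
      if (is.list(cur) && !is.data.frame(cur)) {
        for (k in names(over)) {
          if (is.list(cur[[k]]) || is.null(cur[[k]])) cur[[k]] <-
              modifyList(cur[[k]] %||% list(), as.list(over[[k]]))
          else if (length(cur[[k]]) > 1 && !is.null(names(cur[[k]]))) {
            v <- unlist(over[[k]]); cur[[k]][names(v)] <- v
          } else cur[[k]] <- over[[k]]
        }
      } else if (!is.null(names(cur))) {
        v <- unlist(over); cur[names(v)] <- v
      } else cur <- over
      params[[name]] <<- cur
    }
  }
  for (sec in c("epi", "transitions", "treatment", "utilities", "costs",
                "mortality", "econ", "splits", "bia", "psa"))
    merge_section(sec)

  if (!is.null(config$strategies)) {
    if (length(config$strategies) == 0)
      stop("validation error: strategy list is empty", call. = FALSE)
    strat <- list()
    for (s in config$strategies) {
      if (is.null(s$id)) stop("validation error: strategy missing 'id'",
                              call. = FALSE)
      base_s <- params$strategies[[s$id]] %||%
        list(id = s$id, label = s$id, screen = TRUE,
             uptake_stage1 = 0, uptake_te = 0)
      strat[[s$id]] <- modifyList(base_s, s)
    }
    params$strategies <- strat
  } else note("strategies: default four-strategy set")

  if (!is.null(config$uncertainty))
    params$uncertainty <- modifyList(params$uncertainty, config$uncertainty)
  if (!is.null(config$seed)) params$seed <- config$seed

  params <- .normalize_params(params)
  params <- structure(params, class = "fib_params")
  validate_parameters(params)
  attr(params, "provenance") <- prov
  params
}

#' Serialise a parameter set to YAML
#'
#' The written file round-trips through [load_parameters()] to an equivalent
#' parameter set (the life table is embedded inline).
#'
#' @param params A `fib_params` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_parameters <- function(params, path) {
  x <- unclass(params)
  attr(x, "provenance") <- NULL
  x$mortality$life_table <- list(age = x$mortality$life_table$age,
                                 qx = x$mortality$life_table$qx)
  x$strategies <- unname(x$strategies)
  # named numeric vectors -> named lists so YAML keeps the names
  to_named <- function(v) as.list(v)
  x$epi$masld_prev <- to_named(x$epi$masld_prev)
  x$epi$sigfib_prev <- to_named(x$epi$sigfib_prev)
  x$transitions <- to_named(x$transitions)
  x$utilities <- to_named(x$utilities)
  x$costs$screening <- to_named(x$costs$screening)
  x$costs$state <- to_named(x$costs$state)
  x$costs$state_hospital_derived <- to_named(x$costs$state_hospital_derived)
  x$costs$visits <- to_named(x$costs$visits)
  x$splits <- lapply(x$splits, to_named)
  x$mortality$cause_split <- lapply(x$mortality$cause_split, to_named)
  x$treatment$lifestyle_duration <-
    if (is.infinite(x$treatment$lifestyle_duration)) "Inf"
    else x$treatment$lifestyle_duration
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a life table from a two-column delimited text file
#'
#' @param path File with header columns `age` and `qx` (annual all-cause
#'   death probability), whitespace-, tab- or comma-delimited.
#' @return Data frame with integer `age` and numeric `qx`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  lt <- utils::read.table(path, header = TRUE, sep = sep,
                          strip.white = TRUE)
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table must have header columns 'age' and 'qx'", call. = FALSE)
  lt <- lt[, c("age", "qx")]
  .check_prob(lt$qx, "life table qx")
  lt
}

#' @export
print.fib_params <- function(x, ...) {
  cat("<fib_params> population:", x$population,
      " start age:", x$start_age, " max age:", x$max_age, "\n")
  cat("  strategies:", paste(names(x$strategies), collapse = ", "), "\n")
  cat("  discount:", x$econ$discount, " WTP:", x$econ$wtp, "THB/QALY\n")
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  defaults applied:", length(prov), "entries\n")
  invisible(x)
}
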