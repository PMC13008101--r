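test_that("cascade fractions match hand-computed base-case arithmetic", {
  p <- default_parameters("mets")  # sig-fib prevalence 0.116 at age 50
  cs <- classify_cohort("fib4_te", p)
  expect_equal(cs$sigfib_prev, 0.116)
  expect_equal(cs$fractions[["treated_true"]],
               0.9 * 0.116 * 0.66 * 0.9 * 0.801, tolerance = 1e-12)
  expect_equal(cs$fractions[["treated_false"]],
               0.9 * 0.884 * 0.35 * 0.9 * 0.27, tolerance = 1e-12)
  expect_equal(cs$p_step1_positive, 0.116 * 0.66 + 0.884 * 0.35,
               tolerance = 1e-12)
  expect_equal(cs$screening_cost,
               0.9 * 271 + 0.9 * (0.116 * 0.66 + 0.884 * 0.35) * 0.9 * 2000,
               tolerance = 1e-9)

  te <- classify_cohort("te_alone", p)
  expect_equal(te$screening_cost, 0.8 * 2000)
  expect_equal(te$fractions[["treated_true"]], 0.8 * 0.116 * 0.801,
               tolerance = 1e-12)

  ns <- classify_cohort("no_screen", p)
  expect_equal(ns$fractions[["unscreened"]], 1)
  expect_equal(ns$screening_cost, 0)

  # zero uptake, zero cost
  p0 <- p
  p0$strategies$fib4_te$uptake_stage1 <- 0
  p0$strategies$fib4_te$uptake_te <- 0
  expect_equal(classify_cohort("fib4_te", p0)$screening_cost, 0)

  # no disease, no true positives
  pz <- p
  pz$epi$sigfib_prev[] <- 1e-12
  for (s in c("fib4_te", "safe_te", "te_alone"))
    expect_lt(classify_cohort(s, pz)$fractions[["treated_true"]], 1e-11)
})

test_that("cascade equals full decision-tree enumeration exactly", {
  for (pop in c("mets", "obesity")) {
    p <- default_parameters(pop)
    for (s in names(p$strategies)) {
      expect_equal(classify_cohort(s, p)$fractions, tree_oracle(s, p),
                   tolerance = 1e-15)
    }
  }
  # random accuracies/uptakes/prevalences
  set.seed(11)
  p <- default_parameters("mets")
  for (i in 1:25) {
    p$tests$fib4$sens <- runif(1); p$tests$fib4$spec <- runif(1)
    p$tests$safe$sens <- runif(1); p$tests$safe$spec <- runif(1)
    p$tests$te$sens <- runif(1); p$tests$te$spec <- runif(1)
    p$epi$sigfib_prev[] <- runif(6)
    p$strategies$fib4_te$uptake_stage1 <- runif(1)
    p$strategies$fib4_te$uptake_te <- runif(1)
    p$strategies$te_alone$uptake_te <- runif(1)
    for (s in c("fib4_te", "safe_te", "te_alone"))
      expect_equal(classify_cohort(s, p)$fractions, tree_oracle(s, p),
                   tolerance = 1e-15)
  }
})

test_that("cascade mass is conserved and responds monotonically", {
  set.seed(5)
  p <- default_parameters("mets")
  for (i in 1:20) {
    p$tests$fib4$sens <- runif(1); p$tests$te$sens <- runif(1)
    for (s in names(p$strategies))
      expect_equal(sum(classify_cohort(s, p)$fractions), 1,
                   tolerance = 1e-12)
  }
  # treated-true nondecreasing in each sensitivity and uptake
  base <- default_parameters("mets")
  tt <- function(p) classify_cohort("fib4_te", p)$fractions[["treated_true"]]
  for (path in list(c("tests", "fib4", "sens"), c("tests", "te", "sens"),
                    c("strategies", "fib4_te", "uptake_stage1"),
                    c("strategies", "fib4_te", "uptake_te"))) {
    vals <- vapply(seq(0.1, 1, by = 0.1),
                   function(v) tt(with_param(base, path, v)), 0)
    expect_true(all(diff(vals) >= 0))
  }
  # perfect tests and uptake recover the prevalence exactly
  perfect <- base
  perfect$tests$fib4 <- list(sens = 1, spec = 1)
  perfect$tests$te <- list(sens = 1, spec = 1)
  perfect$strategies$fib4_te$uptake_stage1 <- 1
  perfect$strategies$fib4_te$uptake_te <- 1
  fr <- classify_cohort("fib4_te", perfect)$fractions
  expect_equal(fr[["treated_true"]], 0.116, tolerance = 1e-12)
  expect_equal(fr[["treated_false"]], 0)
})

test_that("cost per true positive follows its definition and conventions", {
  p <- default_parameters("mets")
  cpt <- cost_per_true_positive("fib4_te", p)
  cs <- classify_cohort("fib4_te", p)
  expect_equal(cpt[["tests_only"]],
               cs$screening_cost / cs$fractions[["treated_true"]],
               tolerance = 1e-12)
  expect_equal(cpt[["tests_only"]],
               869.1552 / 0.049672895, tolerance = 1e-4)
  expect_true(all(diff(cpt) > 0))  # each convention adds components

  # homogeneity: doubling every unit cost doubles the ratio
  p2 <- p
  p2$costs$screening <- p$costs$screening * 2
  p2$costs$nonmedical_per_visit <- p$costs$nonmedical_per_visit * 2
  p2$treatment$lifestyle_cost <- p$treatment$lifestyle_cost * 2
  expect_equal(cost_per_true_positive("fib4_te", p2), cpt * 2,
               tolerance = 1e-12)

  # limit case: perfect TE and specificities, full uptake -> c1/pi + c_te
  lim <- p
  lim$tests$fib4$spec <- 1
  lim$tests$te <- list(sens = 1, spec = 1)
  lim$strategies$fib4_te$uptake_stage1 <- 1
  lim$strategies$fib4_te$uptake_te <- 1
  got <- cost_per_true_positive("fib4_te", lim, "tests_only")
  se1 <- lim$tests$fib4$sens
  expect_equal(unname(got), (271 / (0.116 * se1)) + 2000 / 1,
               tolerance = 1e-9)

  # undefined when nothing is detected
  p0 <- p
  p0$strategies$fib4_te$uptake_stage1 <- 0
  expect_error(cost_per_true_positive("fib4_te", p0), "undefined")
})

test_that("initial strata are Bayes-consistent and conserve mass", {
  p <- default_parameters("mets")

  ns <- build_initial_strata("no_screen", p)
  expect_length(ns, 1)
  expect_equal(ns[[1]]$mass, 1)
  expect_false(ns[[1]]$treated)
  # unconditional pools: F0+F1 = MASLD prev - sig-fib prev
  expect_equal(sum(ns[[1]]$init[c("F0", "F1")]), 0.348 - 0.116,
               tolerance = 1e-12)
  expect_equal(sum(ns[[1]]$init[c("F2", "F3", "F4_CC")]), 0.116,
               tolerance = 1e-12)

  for (s in names(p$strategies)) {
    strata <- build_initial_strata(s, p)
    masses <- vapply(strata, `[[`, 0, "mass")
    expect_equal(sum(masses), 1, tolerance = 1e-12)
    for (st in strata) expect_equal(sum(st$init), 1, tolerance = 1e-12)
    # law of total probability: mixture of stratum posteriors is the prior
    mix <- Reduce(`+`, lapply(strata, function(st) st$mass * st$init))
    expect_equal(mix, ns[[1]]$init, tolerance = 1e-12)
  }

  # treated-true stratum concentrates on F2-F4 with the configured split
  tt <- Filter(function(st) grepl("treated_true", st$label),
               build_initial_strata("fib4_te", p))[[1]]
  expect_equal(unname(tt$init[c("F2", "F3", "F4_CC")]), c(0.6, 0.25, 0.15),
               tolerance = 1e-12)
  expect_equal(sum(tt$init[c("NO_MASLD", "F0", "F1")]), 0)
  expect_true(tt$treated && tt$adherent && tt$lifestyle)

  # treated-false stratum holds no significant fibrosis
  tf <- Filter(function(st) st$label == "treated_false",
               build_initial_strata("fib4_te", p))[[1]]
  expect_equal(sum(tf$init[c("F2", "F3", "F4_CC")]), 0)
  expect_true(tf$lifestyle)

  # adherence sub-split
  pa <- p
  pa$treatment$adherence <- 0.7
  strata <- build_initial_strata("fib4_te", pa)
  labs <- vapply(strata, `[[`, "", "label")
  a <- strata[[which(labs == "treated_true_adherent")]]
  n <- strata[[which(labs == "treated_true_nonadherent")]]
  expect_equal(a$mass / (a$mass + n$mass), 0.7, tolerance = 1e-12)
  expect_true(a$adherent && !n$adherent)
  expect_equal(sum(vapply(strata, `[[`, 0, "mass")), 1, tolerance = 1e-12)

  # obesity high-age bands: sig-fib prevalence above the MASLD band is
  # clamped rather than producing negative pools
  po <- default_parameters("obesity", start_age = 65)
  st <- build_initial_strata("no_screen", po)[[1]]
  expect_true(all(st$init >= 0))
  expect_equal(sum(st$init), 1, tolerance = 1e-12)
})
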