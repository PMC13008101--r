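test_that("transition rows encode competing risks correctly", {
  p <- default_parameters("mets")

  # zero-mortality life table isolates the disease dynamics
  p0 <- default_parameters("mets",
                           life_table = data.frame(age = 0:100, qx = 0))
  p0$mortality$post_lt_mortality <- 0
  M <- build_transition_matrix(p0, 50)
  expect_equal(unname(M["F3", c("F2", "F4_CC", "F3")]),
               c(0.058, 0.044, 1 - 0.058 - 0.044), tolerance = 1e-12)
  expect_equal(rowSums(M), setNames(rep(1, 13), health_states()),
               tolerance = 1e-12)
  # death rows are absorbing unit vectors
  for (d in c("D_CVD", "D_LIVER", "D_OTHER"))
    expect_equal(unname(M[d, d]), 1)
  # LT is a one-year tunnel to POST_LT
  expect_equal(unname(M["LT", "POST_LT"]), 1)

  # transplant entry closes after the age limit
  M80 <- build_transition_matrix(p, 80)
  expect_equal(unname(M80["DC", "LT"]), 0)
  expect_equal(unname(M80["HCC", "LT"]), 0)
  M70 <- build_transition_matrix(p, 70)
  expect_gt(M70["DC", "LT"], 0)

  # treatment multiplies the three progression entries by 1 - RRR
  Mt <- build_transition_matrix(p0, 50, treated_adherent = TRUE)
  expect_equal(unname(Mt["F3", "F4_CC"]), 0.044 * 0.796, tolerance = 1e-12)
  expect_equal(unname(Mt["F2", "F3"]), 0.056 * 0.796, tolerance = 1e-12)
  expect_equal(unname(Mt["F4_CC", "DC"]), 0.043 * 0.796, tolerance = 1e-12)
  # regression entries untouched
  expect_equal(unname(Mt["F3", "F2"]), unname(M["F3", "F2"]))

  # mortality competes first: hazard ratios scale the life-table risk
  q50 <- p$mortality$life_table$qx[p$mortality$life_table$age == 50]
  M50 <- build_transition_matrix(p, 50)
  expect_equal(sum(M50["F2", c("D_CVD", "D_LIVER", "D_OTHER")]),
               q50 * 1.29, tolerance = 1e-12)
  expect_equal(sum(M50["DC", c("D_CVD", "D_LIVER", "D_OTHER")]),
               q50 * 3.13, tolerance = 1e-12)
  expect_equal(sum(M50["NO_MASLD", c("D_CVD", "D_LIVER", "D_OTHER")]),
               q50, tolerance = 1e-12)

  # infeasible exits raise an error naming the row
  bad <- p
  bad$transitions["f4_dc"] <- 0.7
  bad$transitions["f4_f3"] <- 0.3
  bad$transitions["f4_hcc"] <- 0.1
  expect_error(build_transition_matrix(bad, 50), "F4_CC")
})

test_that("cohort propagation conserves occupancy and decays geometrically", {
  # constant 10% annual mortality, no disease movement: alive mass = 0.9^k
  toy <- toy_scenario(survival = 0.9, horizon = 40)
  init <- setNames(c(1, rep(0, 12)), health_states())
  traj <- run_cohort(init, toy$params)
  alive <- rowSums(traj[, setdiff(health_states(),
                                  c("D_CVD", "D_LIVER", "D_OTHER"))])
  expect_equal(alive, 0.9^(0:40), tolerance = 1e-12)
  expect_equal(rowSums(traj), rep(1, 41), tolerance = 1e-10)

  # absorbing start: every subsequent vector identical
  dead <- setNames(c(rep(0, 12), 1), health_states())
  trd <- run_cohort(dead, default_parameters("mets"))
  expect_true(all(trd[, "D_OTHER"] == 1))

  # death mass is nondecreasing on the full model
  p <- default_parameters("mets")
  st <- build_initial_strata("no_screen", p)[[1]]
  tr <- run_cohort(st$init, p)
  dead_mass <- rowSums(tr[, c("D_CVD", "D_LIVER", "D_OTHER")])
  expect_true(all(diff(dead_mass) >= -1e-12))
  expect_equal(rowSums(tr), rep(1, nrow(tr)), tolerance = 1e-10)
})

test_that("outcome accumulation reproduces discounting identities", {
  # immortal 10-cycle run at d = 0: 10 QALYs
  toy <- toy_scenario(survival = 1, discount = 0, horizon = 10)
  init <- setNames(c(1, rep(0, 12)), health_states())
  o <- accumulate_outcomes(run_cohort(init, toy$params), toy$params)
  expect_equal(o$qaly, 10, tolerance = 1e-12)
  expect_equal(o$life_expectancy, 10, tolerance = 1e-12)

  # two immortal cycles at 3%: 1 + 1/1.03
  toy2 <- toy_scenario(survival = 1, discount = 0.03, horizon = 2)
  o2 <- accumulate_outcomes(run_cohort(init, toy2$params), toy2$params)
  expect_equal(o2$qaly, 1 + 1 / 1.03, tolerance = 1e-12)

  # zero utilities give zero QALYs
  pz <- toy_scenario(survival = 0.9, horizon = 30)$params
  pz$utilities[] <- 0
  oz <- accumulate_outcomes(run_cohort(init, pz), pz)
  expect_equal(oz$qaly, 0)

  # discounted never exceeds undiscounted; d = 0 makes them identical
  p <- default_parameters("mets")
  st <- build_initial_strata("no_screen", p)[[1]]
  o <- accumulate_outcomes(run_cohort(st$init, p), p)
  expect_lte(o$cost, o$cost_undisc)
  expect_lte(o$qaly, o$qaly_undisc)
  expect_lte(o$qaly, o$life_expectancy)  # utilities <= 1
  p0 <- p
  p0$econ$discount <- 0
  o0 <- accumulate_outcomes(run_cohort(st$init, p0), p0)
  expect_equal(o0$cost, o0$cost_undisc, tolerance = 1e-12)
  expect_equal(o0$qaly, o0$qaly_undisc, tolerance = 1e-12)
})

test_that("unit hazard ratios recover the life-table expectancy", {
  p <- default_parameters("mets")
  p$mortality$hr_noncirrhotic <- 1
  p$mortality$hr_cirrhotic <- 1
  p$mortality$metabolic_multiplier <- 1
  # keep everyone on life-table mortality (no transplant states)
  p$transitions["dc_lt"] <- 0
  p$transitions["hcc_lt"] <- 0
  st <- build_initial_strata("no_screen", p)[[1]]
  o <- accumulate_outcomes(run_cohort(st$init, p), p)
  expect_equal(o$life_expectancy,
               life_table_expectancy(p$mortality$life_table, 50, 100),
               tolerance = 1e-9)
})

test_that("treatment effect is monotone and vanishes at RRR zero", {
  p <- default_parameters("mets")
  qaly_at <- function(rrr) {
    pp <- p; pp$treatment$rrr <- rrr
    ev <- evaluate_strategies(pp, c("no_screen", "fib4_te"))
    attr(ev, "outcomes")$fib4_te$qaly
  }
  qs <- vapply(c(0, 0.1, 0.204, 0.4, 0.6), qaly_at, 0)
  expect_true(all(diff(qs) >= -1e-12))

  # RRR = 0: screening differs from no screening only by costs
  p0 <- p; p0$treatment$rrr <- 0
  ev <- evaluate_strategies(p0, c("no_screen", "fib4_te"))
  outs <- attr(ev, "outcomes")
  expect_equal(outs$fib4_te$qaly, outs$no_screen$qaly, tolerance = 1e-10)
  expect_gt(outs$fib4_te$cost, outs$no_screen$cost)

  # higher RRR lowers lifetime DC + HCC exposure of the treated stratum
  dchcc <- function(rrr) {
    pp <- p; pp$treatment$rrr <- rrr
    tt <- Filter(function(s) grepl("treated_true", s$label),
                 build_initial_strata("fib4_te", pp))[[1]]
    tr <- run_cohort(tt$init, pp, treated_adherent = TRUE)
    sum(tr[, c("DC", "HCC")])
  }
  ex <- vapply(c(0, 0.204, 0.5), dchcc, 0)
  expect_true(all(diff(ex) < 0))
})

test_that("strategy evaluation composes strata, screening costs included", {
  p <- default_parameters("mets")
  ev <- evaluate_strategies(p)
  outs <- attr(ev, "outcomes")
  # screening improves QALYs under a positive treatment effect
  expect_gte(outs$fib4_te$qaly, outs$no_screen$qaly)
  expect_gte(outs$te_alone$qaly, outs$no_screen$qaly)

  # zero test sensitivity: QALYs equal no screening, costs exceed it by
  # screening plus false-positive intervention outlays
  pz <- p
  pz$tests$fib4$sens <- 1e-12
  pz$tests$te$sens <- 1e-12
  evz <- evaluate_strategies(pz, c("no_screen", "fib4_te"))
  oz <- attr(evz, "outcomes")
  expect_equal(oz$fib4_te$qaly, oz$no_screen$qaly, tolerance = 1e-8)
  expect_gt(oz$fib4_te$cost,
            oz$no_screen$cost + oz$fib4_te$screening_cost - 1e-9)

  # stratum-weighted identity: no-screen outcome equals its single stratum
  st <- build_initial_strata("no_screen", p)[[1]]
  o <- accumulate_outcomes(run_cohort(st$init, p), p)
  expect_equal(outs$no_screen$cost, o$cost, tolerance = 1e-9)
  expect_equal(outs$no_screen$qaly, o$qaly, tolerance = 1e-9)
})
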