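test_that("ICER arithmetic and sign conventions", {
  expect_equal(compute_icer(list(cost = 0, qaly = 0),
                            list(cost = 1000, qaly = 0.01)), 100000)
  # rounded published quadruple reproduces the printed-increment ratio
  expect_equal(compute_icer(list(cost = 109897.3, qaly = 15.224),
                            list(cost = 110748.6, qaly = 15.232)),
               (110748.6 - 109897.3) / 0.008, tolerance = 1e-12)
  expect_equal(round((110748.6 - 109897.3) / 0.008, 1), 106412.5)
  # zero QALY difference is a dominance case, not a number
  expect_true(is.na(compute_icer(list(cost = 1, qaly = 1),
                                 list(cost = 2, qaly = 1))))
  # cheaper and better: negative ratio (dominant)
  expect_lt(compute_icer(list(cost = 10, qaly = 1),
                         list(cost = 5, qaly = 2)), 0)
  # antisymmetry in magnitude
  a <- list(cost = 100, qaly = 1); b <- list(cost = 300, qaly = 1.5)
  expect_equal(compute_icer(a, b), compute_icer(b, a))
})

test_that("published cost-utility quadruples yield the published frontier", {
  mets <- data.frame(
    strategy = c("no_screen", "fib4_te", "safe_te", "te_alone"),
    cost = c(109897.3, 110748.6, 111200.1, 112183.4),
    qaly = c(15.224, 15.232, 15.234, 15.233))
  fr <- dominance_frontier(mets)
  expect_equal(fr$status[fr$strategy == "te_alone"], "dominated")
  expect_equal(fr$dominated_by[fr$strategy == "te_alone"], "safe_te")
  keep <- fr[fr$status == "nondominated", ]
  expect_setequal(keep$strategy, c("no_screen", "fib4_te", "safe_te"))
  expect_equal(keep$icer[keep$strategy == "fib4_te"],
               (110748.6 - 109897.3) / 0.008, tolerance = 1e-9)
  expect_equal(keep$icer[keep$strategy == "safe_te"],
               (111200.1 - 110748.6) / 0.002, tolerance = 1e-9)

  obesity <- data.frame(
    strategy = c("no_screen", "fib4_te", "safe_te", "te_alone"),
    cost = c(168147.4, 168700.9, 169013.5, 169492.4),
    qaly = c(16.841, 16.853, 16.858, 16.862))
  fro <- dominance_frontier(obesity)
  expect_true(all(fro$status == "nondominated"))
  expect_true(all(diff(fro$icer[-1]) > 0))

  # degenerate inputs
  one <- dominance_frontier(data.frame(strategy = "a", cost = 1, qaly = 1))
  expect_equal(one$status, "nondominated")
  expect_true(is.na(one$icer))
})

test_that("dominance algorithm equals the brute-force hull on random sets", {
  set.seed(99)
  for (i in 1:300) {
    k <- sample(3:5, 1)
    df <- data.frame(strategy = letters[1:k],
                     cost = runif(k, 0, 1000), qaly = runif(k, 0, 2))
    fr <- dominance_frontier(df)
    oracle <- brute_frontier(df)
    expect_setequal(fr$strategy[fr$status == "nondominated"], oracle$ids)
    got <- fr[fr$status == "nondominated", ]
    got <- got[order(got$qaly), ]
    expect_equal(got$icer[-1], oracle$slopes, tolerance = 1e-9)
    # frontier ICERs strictly increase
    if (length(oracle$slopes) > 1)
      expect_true(all(diff(oracle$slopes) > 0))
  }
})

test_that("NMB and ICER decision rules agree on a WTP grid", {
  expect_equal(net_monetary_benefit(list(cost = 851.3, qaly = 0.008),
                                    list(cost = 0, qaly = 0), 160000),
               160000 * 0.008 - 851.3)
  expect_equal(net_monetary_benefit(list(cost = 100, qaly = 1),
                                    list(cost = 0, qaly = 1), 0), -100)
  set.seed(7)
  wtps <- seq(0, 300000, by = 15000)
  for (i in 1:200) {
    df <- data.frame(strategy = c("a", "b", "c"),
                     cost = runif(3, 0, 5000), qaly = 1 + runif(3, 0, 0.5))
    front <- brute_frontier(df)
    for (w in wtps) {
      nmb <- w * df$qaly - df$cost
      expect_equal(df$strategy[which.max(nmb)], icer_rule_choice(front, w))
    }
  }
})

test_that("threshold search matches the affine closed form and verdicts", {
  p <- default_parameters("obesity")
  ev <- evaluate_strategies(p, c("no_screen", "te_alone"))
  outs <- attr(ev, "outcomes")
  dq <- outs$te_alone$qaly - outs$no_screen$qaly
  dc <- outs$te_alone$cost - outs$no_screen$cost
  icer_cur <- dc / dq
  # cost enters the ICER linearly: dC(c) = dC(c0) + u_te * (c - c0)
  u_te <- p$strategies$te_alone$uptake_te
  icer0 <- (dc - u_te * 2000) / dq

  wtp <- (icer0 + icer_cur) / 2
  th <- threshold_te_cost("te_alone", p, wtp = wtp)
  expect_equal(th$verdict, "threshold_found")
  analytic <- 2000 + (wtp * dq - dc) / u_te
  expect_equal(th$critical_cost, analytic, tolerance = 1e-4)
  # substituting the critical cost back reproduces wtp
  expect_equal(th$icer_at_critical, wtp, tolerance = 1e-5 * wtp)

  th2 <- threshold_te_cost("te_alone", p, wtp = icer_cur * 1.1)
  expect_equal(th2$verdict, "already_cost_effective")
  expect_equal(th2$critical_cost, 2000)

  th3 <- threshold_te_cost("te_alone", p, wtp = max(icer0 * 0.5, 1))
  expect_equal(th3$verdict, "not_cost_effective_even_free")
})

test_that("scenario sweep responds to age and separates cost from QALYs", {
  # effectively infinite horizon + age-flat inputs: ICER independent of age
  lt <- data.frame(age = 0:200, qx = 0.3)
  p <- default_parameters("mets", start_age = 50, max_age = 160,
                          life_table = lt)
  p$epi$masld_prev[] <- 0.348
  p$epi$sigfib_prev[] <- 0.116
  p$mortality$lt_age_max <- 1e9
  sw <- scenario_sweep(p, ages = c(40, 60, 80))
  icers <- sw$icer_vs_no_screen[sw$strategy == "fib4_te"]
  expect_equal(icers[2] / icers[1], 1, tolerance = 1e-6)
  expect_equal(icers[3] / icers[1], 1, tolerance = 1e-6)

  # raising all state costs by 10% leaves every QALY unchanged
  p2 <- default_parameters("mets")
  sw1 <- scenario_sweep(p2, ages = c(40, 60))
  p3 <- p2
  p3$costs$state <- p2$costs$state * 1.1
  sw2 <- scenario_sweep(p3, ages = c(40, 60))
  expect_equal(sw2$qaly, sw1$qaly, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sw2$cost, sw1$cost)))

  # ICERs grow with screening age on the full parameterisation
  swf <- scenario_sweep(p2, ages = c(30, 50, 70))
  ic <- swf$icer_vs_no_screen[swf$strategy == "fib4_te"]
  expect_true(all(diff(ic) > 0))
})
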