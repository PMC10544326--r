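test_that("unit odds ratio degenerates to the population hazard", {
  inc <- generate_incidence_table("constant", 0.002, 80)
  hz <- constrained_baseline(1, inc, f = 0.01)
  expect_equal(hz$hazard_carrier, inc$rate_per_py, tolerance = 1e-12)
  expect_equal(hz$hazard_noncarrier, inc$rate_per_py, tolerance = 1e-12)
})

test_that("measure-zero carriers leave the baseline at the population rate", {
  inc <- generate_incidence_table("bc_like")
  hz <- constrained_baseline(5, inc, f = 0)
  expect_equal(hz$hazard_noncarrier, inc$rate_per_py, tolerance = 1e-12)
  expect_equal(hz$hazard_carrier, 5 * inc$rate_per_py, tolerance = 1e-12)
})

test_that("the mixture constraint holds to machine precision in every band", {
  inc <- generate_incidence_table("constant", 0.001, 80)
  f <- 0.01
  hz <- constrained_baseline(5, inc, f)
  mix <- f * hz$surv_carrier * hz$hazard_carrier +
    (1 - f) * hz$surv_noncarrier * hz$hazard_noncarrier
  target <- hz$rate_pop * (f * hz$surv_carrier + (1 - f) * hz$surv_noncarrier)
  expect_lt(max(abs(mix - target)), 1e-12)
  # also with an age-varying odds ratio
  hz2 <- constrained_baseline(function(t) 9.75 * 0.97^(t - 50), inc, f)
  mix2 <- f * hz2$surv_carrier * hz2$hazard_carrier +
    (1 - f) * hz2$surv_noncarrier * hz2$hazard_noncarrier
  target2 <- hz2$rate_pop * (f * hz2$surv_carrier +
                               (1 - f) * hz2$surv_noncarrier)
  expect_lt(max(abs(mix2 - target2)), 1e-12)
})

test_that("cumulative risk is monotone in age and in the odds ratio", {
  inc <- generate_incidence_table("bc_like")
  c5 <- cumulative_risk_curve(5, incidence = inc, f = 0.001)
  c9 <- cumulative_risk_curve(9.75, incidence = inc, f = 0.001)
  expect_true(all(diff(c5$risk_carrier) >= 0))
  expect_equal(c5$risk_carrier[c5$age == 5], 0)  # no incidence before 20
  expect_gt(c9$risk_carrier[c9$age == 80], c5$risk_carrier[c5$age == 80])
  # OR = 1 collapses onto the population curve
  c1 <- cumulative_risk_curve(1, incidence = inc, f = 0.001)
  expect_equal(c1$risk_carrier, c1$risk_population, tolerance = 1e-12)
  # CI band brackets the point estimate
  cc <- cumulative_risk_curve(9.75, 1.81, 52.69, incidence = inc, f = 0.001)
  expect_true(all(cc$ci_low <= cc$risk_carrier + 1e-12))
  expect_true(all(cc$risk_carrier <= cc$ci_high + 1e-12))
})

test_that("the recursion agrees with a discrete-time population simulation", {
  sets <- list(
    list(or = 5, f = 0.01, inc = generate_incidence_table("constant", 0.001, 80)),
    list(or = 9.75, f = 0.005, inc = generate_incidence_table("bc_like")),
    list(or = 2, f = 0.05, inc = generate_incidence_table("bc_like", 1.5))
  )
  withr::with_seed(91, {
    for (s in sets) {
      hz <- constrained_baseline(s$or, s$inc, s$f)
      width <- hz$age_end - hz$age_start
      F1 <- 1 - exp(-sum(hz$hazard_carrier * width))
      F0 <- 1 - exp(-sum(hz$hazard_noncarrier * width))
      sim <- oracle_risk_sim(hz, s$f, n = 1e6)
      expect_lt(abs(sim$F1 - F1), 3 * sim$se1)
      expect_lt(abs(sim$F0 - F0), 3 * sim$se0)
    }
  })
})

test_that("a strained rare-disease approximation is flagged", {
  inc <- generate_incidence_table("constant", 0.005, 80)
  expect_warning(constrained_baseline(20, inc, 0.01), "rare-disease")
})

test_that("threshold classification is exact at the boundary", {
  mk_curve <- function(risk80) {
    structure(
      tibble::tibble(age = c(40, 80), risk_carrier = c(risk80 / 2, risk80),
                     risk_noncarrier = c(0.01, 0.05),
                     risk_population = c(0.01, 0.05),
                     ci_low = NA_real_, ci_high = NA_real_),
      class = c("pb_risk_curve", "tbl_df", "tbl", "data.frame")
    )
  }
  rep <- threshold_report(list(hi = mk_curve(0.31), lo = mk_curve(0.29)))
  expect_equal(rep$high_risk, c(TRUE, FALSE))
  # a zero threshold marks everything as high risk
  rep0 <- threshold_report(list(lo = mk_curve(0.05)), threshold = 0)
  expect_true(all(rep0$high_risk))
  # curves must reach the threshold age
  short <- mk_curve(0.4)
  short <- short[short$age < 80, ]
  class(short) <- c("pb_risk_curve", class(short))
  expect_error(threshold_report(list(s = short)), "before threshold age")
})

test_that("invalid hazards and frequencies are rejected", {
  inc <- generate_incidence_table("bc_like")
  expect_error(constrained_baseline(5, inc, f = 1), "frequency")
  expect_error(constrained_baseline(-2, inc, f = 0.01), "positive")
  bad <- inc
  bad$rate_per_py[3] <- -1
  expect_error(constrained_baseline(5, bad, f = 0.01), "non-negative")
  gap <- inc[-3, ]
  expect_error(constrained_baseline(5, gap, f = 0.01), "contiguous")
})
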