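test_that("schedule effects match hand arithmetic and the single-fraction identity", {
  cho <- published$CHO$lq
  expect_equal(lq_effect(cho, schedule(40, 2)), 27.1376, tolerance = 1e-10)
  expect_equal(lq_effect(cho, schedule(1, 1e-12)), 0, tolerance = 1e-10)
  expect_equal(lq_effect(cho, schedule(1, 7)), -lq_log_survival(cho, 7),
               tolerance = 1e-12)

  ncih <- published$NCIH841$elq
  expect_lt(abs(elq_effect(ncih, schedule(40, 2)) - 11.0847), 1e-3)
  expect_equal(elq_effect(ncih, schedule(1, 9)), -elq_log_survival(ncih, 9),
               tolerance = 1e-12)
  # unbounded gamma delegates to the LQ effect
  p <- elq_params(0.2, 0.04, Inf)
  expect_identical(elq_effect(p, schedule(10, 3)), lq_effect(p, schedule(10, 3)))
})

test_that("LQ isoeffect closed form reproduces published single- and 24-fraction doses", {
  ref <- schedule(40, 2)
  E_cho <- lq_effect(published$CHO$lq, ref)
  expect_lt(abs(lq_isoeffect_dose(published$CHO$lq, E_cho, 1) - 24.3), 0.05)
  E_n <- lq_effect(published$NCIH841$lq, ref)
  expect_lt(abs(lq_isoeffect_dose(published$NCIH841$lq, E_n, 24) - 68.3), 0.05)
  # self-consistency: solving at the reference n returns the reference dose
  expect_equal(lq_isoeffect_dose(published$NCIH841$lq, E_n, 40), 80,
               tolerance = 1e-9)
})

test_that("LQ closed form equals numeric root finding of the effect equation", {
  set.seed(303)
  for (i in 1:10) {
    p <- random_lq_params()
    E <- lq_effect(p, schedule(40, 2))
    for (n in c(1, 3, 7, 21, 50)) {
      numeric_root <- uniroot(function(D) p$alpha * D + p$beta * D^2 / n - E,
                              c(1e-9, 1e4), tol = 1e-12)$root
      expect_equal(lq_isoeffect_dose(p, E, n), numeric_root, tolerance = 1e-9)
    }
  }
  # alpha = 0 pure-quadratic branch
  p0 <- elq_params(0, 0.08, 1)   # low-dose pair only
  expect_equal(lq_isoeffect_dose(p0, 5, 4), sqrt(4 * 5 / 0.08), tolerance = 1e-12)
})

test_that("implicit ELQ isoeffect solve reproduces published equivalences", {
  ncih <- published$NCIH841$elq
  E <- elq_effect(ncih, schedule(40, 2))
  expect_lt(abs(elq_isoeffect_dose(ncih, E, 1) - 15.9), 0.05)
  expect_lt(abs(elq_isoeffect_dose(ncih, E, 24) - 62.7), 0.05)
  E315 <- elq_effect(ncih, schedule(3, 15))
  expect_lt(abs(elq_isoeffect_dose(ncih, E315, 10) - 72.8), 0.05)
  E_pc3 <- elq_effect(published$PC3$elq, schedule(40, 2))
  expect_lt(abs(elq_isoeffect_dose(published$PC3$elq, E_pc3, 8) - 39.1), 0.05)
})

test_that("effect and isoeffect dose invert each other to 1e-8 for both models", {
  set.seed(404)
  for (i in 1:10) {
    plq <- random_lq_params()
    pelq <- random_elq_params()
    for (n in c(1, 2.5, 8, 33, 50)) {
      for (E in c(0.5, 5, 30)) {
        Dl <- lq_isoeffect_dose(plq, E, n)
        expect_equal(lq_effect(plq, schedule(n, Dl / n)), E, tolerance = 1e-8)
        De <- elq_isoeffect_dose(pelq, E, n)
        expect_equal(elq_effect(pelq, schedule(n, De / n)), E, tolerance = 1e-8)
      }
    }
  }
})

test_that("ELQ solver agrees with an independent dense bisection oracle to 1e-6 Gy", {
  ns <- c(1, 2, 4, 8, 16, 24, 30, 40, 50)
  for (cl in c("NCIH841", "PC3", "CP3")) {
    p <- published[[cl]]$elq
    E <- elq_effect(p, schedule(40, 2))
    for (n in ns) {
      expect_equal(elq_isoeffect_dose(p, E, n), bisect_elq_dose(p, E, n),
                   tolerance = 1e-6)
    }
  }
})

test_that("isoeffect curves pass through the reference schedule and reproduce the effect", {
  ref <- schedule(40, 2)
  for (cl in published) {
    for (p in list(cl$lq, cl$elq)) {
      curve <- isoeffect_curve(p, ref, n = c(1, 5, 20, 40, 50))
      expect_equal(curve$total_dose[curve$n == 40], 80, tolerance = 1e-9)
      E <- attr(curve, "effect")
      for (i in seq_len(nrow(curve))) {
        expect_equal(schedule_effect(p, schedule(curve$n[i],
                                                 curve$total_dose[i] / curve$n[i])),
                     E, tolerance = 1e-8)
      }
    }
  }
  expect_lt(abs(isoeffect_curve(published$CP3$elq, ref, 50)$total_dose - 89.0), 0.05)
})

test_that("the published isoeffect and 2 Gy survival tables are reproduced", {
  rep <- reproduce_tables()
  expect_true(all(rep$status == "pass"))
  expect_identical(nrow(rep), 90L)   # 81 dose cells + 9 survival comparisons
})

test_that("fraction ratios at 2 Gy per fraction match the published comparison", {
  expect_lt(abs(fraction_ratio(published$NCIH841$lq, published$NCIH841$elq, 2) - 1.41), 0.01)
  expect_lt(abs(fraction_ratio(published$CP3$lq, published$CP3$elq, 2) - 1.41), 0.01)
  expect_lt(abs(fraction_ratio(published$PC3$lq, published$PC3$elq, 2) - 1.36), 0.01)
  # identical models give exactly 1
  p <- elq_params(0.1, 0.05, Inf)
  expect_equal(fraction_ratio(p, p, 2), 1, tolerance = 1e-12)
  expect_error(fraction_ratio(published$PC3$lq, published$PC3$elq, 0))
})

test_that("uncertainty bands contain the nominal curve and reflect parameter precision", {
  ref <- schedule(40, 2)
  # zero uncertainties: zero-width band
  fit0 <- list(params = published$NCIH841$lq,
               pct_uncertainty = c(alpha = 0, beta = 0))
  b0 <- isoeffect_uncertainty_band(fit0, ref, n = c(1, 10, 40))
  expect_equal(b0$lower, b0$total_dose, tolerance = 1e-12)
  expect_equal(b0$upper, b0$total_dose, tolerance = 1e-12)

  # containment for all published parameter sets over n = 1..50
  for (cl in published) {
    fit <- list(params = cl$lq, pct_uncertainty = cl$lq_pct)
    b <- isoeffect_uncertainty_band(fit, ref)
    expect_true(all(b$lower <= b$total_dose + 1e-9))
    expect_true(all(b$upper >= b$total_dose - 1e-9))
  }

  # the imprecise NCIH841 LQ parameters give a wider single-fraction band
  # than the precise NCIH841 ELQ parameters
  b_lq <- isoeffect_uncertainty_band(
    list(params = published$NCIH841$lq, pct_uncertainty = published$NCIH841$lq_pct),
    ref, n = 1)
  b_elq <- isoeffect_uncertainty_band(
    list(params = published$NCIH841$elq, pct_uncertainty = published$NCIH841$elq_pct),
    ref, n = 1)
  expect_gt(b_lq$upper - b_lq$lower, b_elq$upper - b_elq$lower)
})

test_that("small alpha/beta LQ curves approximate the ELQ curve only over a fraction-number range", {
  ref <- schedule(40, 2)
  rep <- lq_approximation_report(published$CP3$elq, c(0.5, 3.28), ref,
                                 tolerance = 1)
  row05 <- rep[rep$alpha_beta == 0.5, ]
  # agreement holds over a long contiguous run reaching n = 50 ...
  expect_equal(row05$n_to, 50)
  expect_gt(row05$n_agree, 35)
  # ... but breaks down at small fraction numbers, where the 0.5 curve
  # dips below the ELQ curve
  detail <- attr(rep, "detail")
  d1 <- detail[detail$alpha_beta == 0.5 & detail$n == 1, ]
  expect_lt(d1$D_lq, d1$D_elq - 1)
  # the published alpha/beta = 3.28 fit agrees only near the anchor
  expect_lt(rep[rep$alpha_beta == 3.28, "n_agree"], row05$n_agree)

  # a candidate equal to an LQ-limit ELQ's own ratio agrees everywhere
  p <- elq_params(0.15, 0.05, Inf)
  rep2 <- lq_approximation_report(p, 3, ref, tolerance = 1e-6)
  expect_equal(rep2$n_from, 1)
  expect_equal(rep2$n_to, 50)

  # at 15 Gy per fraction the 0.5 approximation fails: 113 vs 98.9 Gy at n = 20
  rep3 <- lq_approximation_report(published$NCIH841$elq, 0.5, schedule(3, 15),
                                  n = c(10, 20), tolerance = 1)
  d3 <- attr(rep3, "detail")
  expect_gt(abs(d3$diff_Gy[d3$n == 20]), 1)
  expect_lt(abs(d3$D_lq[d3$n == 20] - 113), 0.5)
  expect_lt(abs(d3$D_elq[d3$n == 20] - 98.9), 0.1)
})

test_that("schedule parsing and validation behave", {
  s <- parse_schedule("40x2")
  expect_equal(c(s$n, s$d, s$total_dose), c(40, 2, 80))
  expect_equal(parse_schedule(" 3 X 15 ")$total_dose, 45)
  expect_error(parse_schedule("abc"), "cannot parse")
  expect_error(schedule(0.5, 2), ">= 1")
  expect_error(schedule(10, 0))
})
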