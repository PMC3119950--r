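test_that("LQ log survival matches hand-computed values and the zero-dose identity", {
  ncih <- published$NCIH841$lq
  expect_equal(lq_log_survival(ncih, 2), -0.3912, tolerance = 1e-12)
  expect_equal(exp(lq_log_survival(ncih, 2)), 0.676, tolerance = 5e-4)
  # hand arithmetic with the CHO parameters at 5 Gy
  cho <- published$CHO$lq
  expect_equal(lq_log_survival(cho, 5), -2.2175, tolerance = 1e-10)
  expect_identical(lq_log_survival(cho, 0), 0)
  expect_error(lq_log_survival(cho, -1), "non-negative")
})

test_that("ELQ log survival matches published 2 Gy survivals and the zero-dose identity", {
  expect_equal(exp(elq_log_survival(published$NCIH841$elq, 2)), 0.758,
               tolerance = 7e-4)
  expect_equal(exp(elq_log_survival(published$PC3$elq, 2)), 0.734,
               tolerance = 7e-4)
  expect_equal(elq_log_survival(published$CP3$elq, 0), 0)
  expect_error(elq_log_survival(published$PC3$elq, -0.5), "non-negative")
})

test_that("both models are strictly decreasing in dose for random valid parameters", {
  set.seed(101)
  d <- seq(0, 25, by = 0.25)
  for (i in 1:25) {
    expect_true(all(diff(lq_log_survival(random_lq_params(), d)) < 0))
    expect_true(all(diff(elq_log_survival(random_elq_params(), d)) < 0))
  }
})

test_that("unbounded gamma makes the ELQ collapse exactly to the LQ", {
  p <- elq_params(0.2, 0.05, Inf)
  d <- seq(0, 30, by = 0.5)
  expect_identical(elq_log_survival(p, d), lq_log_survival(p, d))
  # near-limit: gamma = 1e6 agrees within 1e-4 over 0..20 Gy for all
  # published parameter sets
  for (cl in published) {
    big <- elq_params(cl$lq$alpha, cl$lq$beta, 1e6)
    dd <- seq(0, 20, by = 0.5)
    expect_lt(max(abs(elq_log_survival(big, dd) - lq_log_survival(cl$lq, dd))),
              1e-4)
  }
})

test_that("finite-gamma ELQ log survival strictly exceeds the LQ form at equal (alpha, beta)", {
  set.seed(202)
  d <- c(0.5, 1, 2, 5, 10, 20)
  for (i in 1:25) {
    p <- random_elq_params()
    expect_true(all(elq_log_survival(p, d) >
                      lq_log_survival(lq_params(max(p$alpha, 1e-12), p$beta), d) -
                      1e-300))
    expect_true(all(elq_log_survival(p, d) > -p$alpha * d - p$beta * d^2))
  }
})

test_that("protraction factor has the acute limit, exact mid value and long-exposure asymptote", {
  expect_identical(protraction_factor(0), 1)
  expect_equal(protraction_factor(2), 0.5 * (exp(-2) + 1), tolerance = 1e-12)
  expect_equal(protraction_factor(2), 0.567668, tolerance = 1e-6)
  expect_equal(protraction_factor(20), 2 * (20 - 1) / 20^2, tolerance = 1e-3)
  x <- c(0.001, 0.01, 0.1, 1, 5, 10, 50)
  expect_true(all(diff(protraction_factor(x)) < 0))
  expect_true(all(protraction_factor(x) > 0 & protraction_factor(x) <= 1))
  # series switchover is continuous at the 1e-4 boundary
  expect_equal(protraction_factor(1e-4 - 1e-12), protraction_factor(1e-4 + 1e-12),
               tolerance = 1e-9)
  expect_error(protraction_factor(-0.1), "non-negative")
})

test_that("gamma follows 2*beta/(delta + lambda/R) with the correct limits", {
  expect_equal(gamma_from_protraction(0.05, protraction_spec(1, 0.5)), 0.2)
  expect_equal(gamma_from_protraction(0.05, protraction_spec(Inf, 0.5, delta = 0.1)),
               1.0)
  expect_identical(gamma_from_protraction(0.03, protraction_spec(Inf, 0.5)), Inf)
})

test_that("ELQ equals the dose-rate form with gamma = 2*beta*R/lambda (independent oracle)", {
  # oracle: ln S = -(a + 2bR/l) d + 2b(R/l)^2 (1 - exp(-l d / R))
  protracted_lq <- function(a, b, lam, R, d) {
    -(a + 2 * b * R / lam) * d + 2 * b * (R / lam)^2 * (1 - exp(-lam * d / R))
  }
  d <- seq(0, 20, by = 0.25)
  cases <- list(c(a = 0.1, b = 0.05, lam = 0.46, R = 30),
                c(a = 0, b = 0.08, lam = 1.4, R = 60),
                c(a = 0.25, b = 0.033, lam = 0.7, R = 0.9))
  for (cs in cases) {
    g <- gamma_from_protraction(cs["b"], protraction_spec(cs["R"], cs["lam"]))
    p <- elq_params(cs["a"], cs["b"], g)
    expect_equal(elq_log_survival(p, d),
                 protracted_lq(cs["a"], cs["b"], cs["lam"], cs["R"], d),
                 tolerance = 1e-12)
  }
})

test_that("low-dose cubic series agrees with the exact ELQ to fourth order", {
  p <- published$NCIH841$elq
  expect_lt(abs(elq_log_survival(p, 0.5) - elq_low_dose_series(p, 0.5)), 1e-3)
  # Taylor remainder is O(d^4): halving d shrinks the gap ~16-fold
  gap <- function(d) abs(elq_log_survival(p, d) - elq_low_dose_series(p, d))
  expect_equal(gap(0.2) / gap(0.1), 16, tolerance = 0.15)
  # unbounded gamma: the cubic term vanishes and both equal the LQ exactly
  pl <- elq_params(0.2, 0.04, Inf)
  expect_identical(elq_low_dose_series(pl, c(1, 5, 10)),
                   lq_log_survival(pl, c(1, 5, 10)))
})

test_that("high-dose asymptote has slope -(alpha+gamma), the extrapolation intercept, and exponential approach", {
  p <- published$NCIH841$elq
  expect_equal(elq_high_dose_asymptote(p, 1) - elq_high_dose_asymptote(p, 0),
               -1.282, tolerance = 1e-12)
  expect_equal(elq_high_dose_asymptote(p, 0), 1.282^2 / (2 * 0.07477),
               tolerance = 1e-12)
  expect_equal(elq_high_dose_asymptote(p, 0), 10.99, tolerance = 1e-4)
  expect_lt(abs(elq_log_survival(p, 200) - elq_high_dose_asymptote(p, 200)),
            1e-6)
  p2 <- elq_params(0.1, 0.05, 1)
  expect_equal(elq_high_dose_asymptote(p2, 1) - elq_high_dose_asymptote(p2, 0),
               -1.1, tolerance = 1e-12)
})

test_that("parameter constructors enforce domain invariants", {
  expect_error(lq_params(-0.1, 0.05))
  expect_error(lq_params(0.1, 0))
  expect_error(elq_params(0.1, 0.05, 0))
  expect_error(elq_params(0.1, 0.05, -1))
  expect_true(gamma_is_unbounded(elq_params(0.1, 0.05, Inf)))
  expect_false(gamma_is_unbounded(elq_params(0.1, 0.05, 2)))
  expect_equal(alpha_beta_ratio(lq_params(0.1164, 0.0396)), 2.9394, tolerance = 1e-4)
  expect_error(protraction_spec(-1, 0.5))
  expect_error(protraction_spec(1, 0.5, delta = -0.1))
})
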