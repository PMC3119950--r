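# Shared test helpers: published parameter sets, an independent bisection
# oracle for the implicit ELQ isoeffect equation, and random parameter
# draws for property-style tests.

published <- cell_line_parameters()

# Independent of elq_isoeffect_dose(): plain interval bisection on the
# effect mismatch, with the effect itself recomputed from first principles
# (n times the per-fraction log kill).
bisect_elq_dose <- function(params, E, n, lo = 1e-9, hi = 1e4, iter = 200) {
  a <- params$alpha; b <- params$beta; g <- params$gamma
  eff <- function(D) {
    d <- D / n
    n * ((a + g) * d + g^2 / (2 * b) * (exp(-2 * b * d / g) - 1))
  }
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (eff(mid) < E) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

random_lq_params <- function() {
  lq_params(alpha = runif(1, 0, 0.5), beta = runif(1, 0.01, 0.1))
}

random_elq_params <- function() {
  elq_params(alpha = runif(1, 0, 0.3), beta = runif(1, 0.01, 0.1),
             gamma = runif(1, 0.3, 3))
}

# small noiseless dataset builder used across fitting tests
exact_dataset <- function(params, doses = c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 15)) {
  generate_dataset(generator_config(params, doses = doses, noise_cv = 0))
}
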