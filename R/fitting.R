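# Weighted least-squares fitting of the LQ and ELQ survival models.
#
# Residuals are formed either in linear survival space,
#   r_i = (S_i - S(d_i; theta)) / sd_i,
# or in log-survival space,
#   r_i = (ln S_i - ln S(d_i; theta)) / (sd_i / S_i),
# the latter using the delta-method standard deviation of the log.  Under
# the proportional-SD convention (sd_i = c * S_i) linear-space weighting is
# relative least squares; the constant c rescales the WSSR only.

# raw evaluators that tolerate out-of-domain parameters during optimisation
.lq_logS <- function(a, b, d) -a * d - b * d^2
.elq_logS <- function(a, b, g, d) {
  if (!is.finite(g)) return(.lq_logS(a, b, d))
  -(a + g) * d - g^2 / (2 * b) * expm1(-2 * b * d / g)
}

.fit_residuals <- function(data, fit_space) {
  d <- data$dose; sf <- data$surviving_fraction; sd <- data$sd
  if (any(sd <= 0)) stop("degenerate weight: sd must be > 0", call. = FALSE)
  if (fit_space == "linear") {
    function(logS) (sf - exp(logS)) / sd
  } else {
    sd_log <- sd / sf
    function(logS) (log(sf) - logS) / sd_log
  }
}

#' Weighted sum of squared residuals
#'
#' \eqn{\sum_i ((obs_i - fit_i)/sd_i)^2} in the chosen fit space.  Zero if
#' and only if the model interpolates every point.
#'
#' @param data A [survival_dataset].
#' @param model Either a `survival_params` object or a function mapping a
#'   dose vector to log survival.
#' @param fit_space `"linear"` (residuals on surviving fractions) or
#'   `"log"` (residuals on log survival with delta-method SDs).
#' @return The WSSR (dimensionless, >= 0).
#' @export
compute_wssr <- function(data, model, fit_space = c("linear", "log")) {
  stopifnot(inherits(data, "survival_dataset"))
  fit_space <- match.arg(fit_space)
  logS <- if (is.function(model)) model(data$dose) else log_survival(model, data$dose)
  sum(.fit_residuals(data, fit_space)(logS)^2)
}

# run nls.lm from one start; returns list(par, wssr, info) or NULL on error
.lm_once <- function(start, resid_fn, lower, upper) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 1000, maxfev = 100000)
  ans <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       upper = upper, control = ctrl),
    error = function(e) NULL)
  if (is.null(ans)) return(NULL)
  list(par = ans$par, wssr = ans$deviance, info = ans$info,
       message = ans$message)
}

# pick lowest WSSR; among near-ties (1e-8 relative) lowest gamma
.pick_best <- function(fits, gamma_index = NA_integer_) {
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("fit failure: no start converged", call. = FALSE)
  w <- vapply(fits, `[[`, numeric(1), "wssr")
  cand <- which(w <= min(w) * (1 + 1e-8) + 1e-300)
  if (!is.na(gamma_index) && length(cand) > 1L) {
    g <- vapply(fits[cand], function(f) f$par[gamma_index], numeric(1))
    cand <- cand[which.min(g)]
  }
  fits[[cand[1L]]]
}

# central-difference Jacobian of the residual vector
.num_jacobian <- function(fn, par) {
  m <- length(fn(par)); p <- length(par)
  J <- matrix(0, m, p)
  for (j in seq_len(p)) {
    h <- max(1e-7, abs(par[j]) * 1e-7)
    up <- par; up[j] <- up[j] + h
    lo <- par; lo[j] <- lo[j] - h
    J[, j] <- (fn(up) - fn(lo)) / (2 * h)
  }
  J
}

# Gauss-Newton covariance at the optimum, optionally scaled by reduced
# chi-square; singular curvature gives Inf standard errors, not an error.
.gn_uncertainty <- function(resid_fn, par, wssr, n, scale_by_residual = TRUE) {
  J <- .num_jacobian(resid_fn, par)
  p <- length(par)
  s2 <- if (scale_by_residual && n > p) wssr / (n - p) else 1
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    return(list(se = rep(Inf, p), cov = matrix(NA_real_, p, p),
                singular = TRUE))
  }
  list(se = sqrt(diag(cov)), cov = cov, singular = FALSE)
}

.check_fit_data <- function(data, n_par) {
  stopifnot(inherits(data, "survival_dataset"))
  if (nrow(data) < n_par + 2L)
    stop(sprintf("insufficient data: %d points for a %d-parameter fit (need >= %d)",
                 nrow(data), n_par, n_par + 2L), call. = FALSE)
}

.new_fit <- function(model_kind, params, free, est, se, cov, wssr, data,
                     fit_space, alpha_fixed_to_zero = FALSE,
                     gamma_unbounded = FALSE, singular = FALSE) {
  pct <- 100 * se / abs(est)
  names(pct) <- names(se) <- free
  structure(list(
    model_kind = model_kind,
    params = params,
    wssr = wssr,
    se = se,
    pct_uncertainty = pct,
    cov = cov,
    free_parameters = free,
    alpha_fixed_to_zero = alpha_fixed_to_zero,
    gamma_unbounded = gamma_unbounded,
    singular_curvature = singular,
    n_points = nrow(data),
    fit_space = fit_space,
    label = attr(data, "label")
  ), class = "survival_fit")
}

#' Fit the linear-quadratic model to dose-survival data
#'
#' Minimises the weighted sum of squared residuals over `(alpha, beta)`
#' with a bound-constrained Levenberg-Marquardt trust-region search
#' ([minpack.lm::nls.lm]) started from several deterministic initial
#' points.  `alpha` is constrained non-negative, `beta` strictly positive.
#' Percentage parameter uncertainties come from the Gauss-Newton
#' covariance at the optimum scaled by reduced chi-square.
#'
#' @param data A [survival_dataset] with at least 4 points.
#' @param fit_space `"linear"` (default) or `"log"`; see [compute_wssr()].
#' @return A `survival_fit` object.
#' @seealso [fit_elq()], [parameter_uncertainty()]
#' @export
fit_lq <- function(data, fit_space = c("linear", "log")) {
  fit_space <- match.arg(fit_space)
  .check_fit_data(data, 2L)
  rfun <- .fit_residuals(data, fit_space)
  resid_fn <- function(p) rfun(.lq_logS(p[1], p[2], data$dose))

  # crude log-linear regression start, clipped into bounds
  y <- -log(data$surviving_fraction)
  co <- tryCatch(stats::coef(stats::lm(y ~ 0 + data$dose + I(data$dose^2))),
                 error = function(e) c(0.1, 0.03))
  start0 <- c(max(co[1], 0), max(co[2], 1e-4))
  starts <- list(start0, c(0.1, 0.05), c(0.3, 0.02))
  lower <- c(0, 1e-12); upper <- c(Inf, Inf)

  best <- .pick_best(lapply(starts, .lm_once, resid_fn = resid_fn,
                            lower = lower, upper = upper))
  if (!best$info %in% c(1:4, 6, 7))
    stop(sprintf("LQ fit failed to converge: %s", best$message), call. = FALSE)
  unc <- .gn_uncertainty(resid_fn, best$par, best$wssr, nrow(data))
  .new_fit("LQ", lq_params(best$par[1], best$par[2]),
           free = c("alpha", "beta"), est = best$par, se = unc$se,
           cov = unc$cov, wssr = best$wssr, data = data,
           fit_space = fit_space, singular = unc$singular)
}

#' Fit the extended linear-quadratic model to dose-survival data
#'
#' Stage one fits `(alpha, beta, gamma)` with `alpha` unconstrained (the
#' sign of `alpha` is informative about curvature at low dose).  If the
#' unconstrained estimate of `alpha` is negative — or `fix_alpha_zero` is
#' set — the fit is repeated with `alpha` fixed at exactly zero and the
#' `alpha_fixed_to_zero` flag is raised.  If the `gamma` estimate exceeds
#' `gamma_ceiling` the data carry no evidence of high-dose linearity and
#' the result is reported as the LQ limit (`gamma = Inf`, parameters and
#' uncertainties from [fit_lq()]).
#'
#' Each stage is a bound-constrained Levenberg-Marquardt search multistarted
#' from five deterministic initial points, including the LQ solution with
#' large `gamma`; ties are broken by lowest WSSR then lowest `gamma`.  The
#' multistart guarantees the nesting property WSSR(ELQ) <= WSSR(LQ).
#'
#' @inheritParams fit_lq
#' @param gamma_ceiling Divergence ceiling for `gamma` in per Gy (default
#'   1e4); above it the LQ-limit result is reported.
#' @param fix_alpha_zero Force the alpha-fixed-to-zero refit path.
#' @return A `survival_fit` object.
#' @export
fit_elq <- function(data, fit_space = c("linear", "log"),
                    gamma_ceiling = 1e4, fix_alpha_zero = FALSE) {
  fit_space <- match.arg(fit_space)
  .check_fit_data(data, 3L)
  rfun <- .fit_residuals(data, fit_space)
  lqfit <- fit_lq(data, fit_space)
  aLQ <- lqfit$params$alpha; bLQ <- lqfit$params$beta

  run_stage <- function(alpha_fixed) {
    if (alpha_fixed) {
      resid_fn <- function(p) rfun(.elq_logS(0, p[1], p[2], data$dose))
      starts <- list(c(bLQ, 1e5), c(2 * bLQ, 1), c(2 * bLQ, 0.5),
                     c(1.5 * bLQ, 2), c(bLQ, 5))
      lower <- c(1e-12, 1e-12); gi <- 2L
    } else {
      resid_fn <- function(p) rfun(.elq_logS(p[1], p[2], p[3], data$dose))
      starts <- list(c(aLQ, bLQ, 1e5), c(0, 2 * bLQ, 1), c(0, 2 * bLQ, 0.5),
                     c(aLQ, 1.5 * bLQ, 2), c(aLQ / 2, bLQ, 5))
      lower <- c(-Inf, 1e-12, 1e-12); gi <- 3L
    }
    best <- .pick_best(lapply(starts, .lm_once, resid_fn = resid_fn,
                              lower = lower, upper = rep(Inf, length(lower))),
                       gamma_index = gi)
    if (!best$info %in% c(1:4, 6, 7))
      stop(sprintf("ELQ fit failed to converge: %s", best$message),
           call. = FALSE)
    best$resid_fn <- resid_fn
    best
  }

  alpha_fixed <- isTRUE(fix_alpha_zero)
  best <- run_stage(alpha_fixed)
  if (!alpha_fixed && best$par[1] < 0) {   # negative-alpha refit rule
    alpha_fixed <- TRUE
    best <- run_stage(TRUE)
  }

  gam <- if (alpha_fixed) best$par[2] else best$par[3]
  if (gam > gamma_ceiling) {
    # LQ limit: gamma diverged, report the two-parameter fit
    return(.new_fit("ELQ",
                    elq_params(lqfit$params$alpha, lqfit$params$beta, Inf),
                    free = c("alpha", "beta"),
                    est = c(lqfit$params$alpha, lqfit$params$beta),
                    se = lqfit$se, cov = lqfit$cov, wssr = lqfit$wssr,
                    data = data, fit_space = fit_space,
                    alpha_fixed_to_zero = alpha_fixed,
                    gamma_unbounded = TRUE, singular = lqfit$singular_curvature))
  }

  unc <- .gn_uncertainty(best$resid_fn, best$par, best$wssr, nrow(data))
  if (alpha_fixed) {
    params <- elq_params(0, best$par[1], best$par[2])
    free <- c("beta", "gamma")
  } else {
    params <- elq_params(max(best$par[1], 0), best$par[2], best$par[3])
    free <- c("alpha", "beta", "gamma")
  }
  .new_fit("ELQ", params, free = free, est = best$par, se = unc$se,
           cov = unc$cov, wssr = best$wssr, data = data,
           fit_space = fit_space, alpha_fixed_to_zero = alpha_fixed,
           singular = unc$singular)
}

#' Percentage parameter uncertainties of a fit
#'
#' Recomputes the Gauss-Newton (Jacobian-based) covariance of the weighted
#' objective at the optimum and reports, for each free parameter,
#' `100 * standard error / estimate`.  Fixed parameters (an alpha pinned
#' to zero, an unbounded gamma) carry no uncertainty.  Singular curvature
#' yields `Inf` entries rather than an error.
#'
#' @param fit A `survival_fit` from [fit_lq()] or [fit_elq()].
#' @param data The [survival_dataset] that was fitted.
#' @param scale_by_residual Scale the covariance by reduced chi-square
#'   (default `TRUE`); with `FALSE` the raw unit-weight covariance is used,
#'   under which doubling all `sd` values doubles each standard error.
#' @return A list with `pct` (named percentages), `se`, and `cov`.
#' @export
parameter_uncertainty <- function(fit, data, scale_by_residual = TRUE) {
  stopifnot(inherits(fit, "survival_fit"))
  rfun <- .fit_residuals(data, fit$fit_space)
  p <- fit$params
  est <- vapply(fit$free_parameters, function(nm) p[[nm]], numeric(1))
  resid_fn <- if (fit$model_kind == "LQ" || fit$gamma_unbounded) {
    function(v) rfun(.lq_logS(v[1], v[2], data$dose))
  } else if (fit$alpha_fixed_to_zero) {
    function(v) rfun(.elq_logS(0, v[1], v[2], data$dose))
  } else {
    function(v) rfun(.elq_logS(v[1], v[2], v[3], data$dose))
  }
  unc <- .gn_uncertainty(resid_fn, unname(est), fit$wssr, nrow(data),
                         scale_by_residual = scale_by_residual)
  pct <- 100 * unc$se / abs(est)
  names(pct) <- fit$free_parameters
  list(pct = pct, se = stats::setNames(unc$se, fit$free_parameters),
       cov = unc$cov)
}

#' @describeIn alpha_beta_ratio For a fit, returns the ratio together with
#'   its percentage uncertainty from first-order propagation assuming
#'   independent alpha and beta (quadrature of the two percentage
#'   uncertainties).
#' @export
alpha_beta_ratio.survival_fit <- function(x, ...) {
  ratio <- x$params$alpha / x$params$beta
  pa <- x$pct_uncertainty["alpha"]
  pb <- x$pct_uncertainty["beta"]
  pct <- if (is.na(pa) || is.na(pb)) NA_real_ else sqrt(pa^2 + pb^2)
  c(ratio = unname(ratio), pct_uncertainty = unname(pct))
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("%s fit%s: %d points, WSSR = %.6g (%s space)\n",
              x$model_kind,
              if (nzchar(x$label)) paste0(" to '", x$label, "'") else "",
              x$n_points, x$wssr, x$fit_space))
  p <- x$params
  show <- function(nm, val, unit) {
    if (nm %in% x$free_parameters) {
      cat(sprintf("  %-5s = %.6g %s (%.3g%%)\n", nm, val, unit,
                  x$pct_uncertainty[nm]))
    } else {
      cat(sprintf("  %-5s = %.6g %s (fixed)\n", nm, val, unit))
    }
  }
  show("alpha", p$alpha, "/Gy")
  show("beta", p$beta, "/Gy^2")
  if (x$model_kind == "ELQ") {
    if (x$gamma_unbounded) cat("  gamma = unbounded (LQ limit)\n")
    else show("gamma", p$gamma, "/Gy")
  }
  if (x$alpha_fixed_to_zero) cat("  [alpha was fixed to zero on refit]\n")
  invisible(x)
}

#' Serialise a fit to a JSON record
#'
#' Writes parameters, percentage uncertainties, WSSR and flags as a
#' machine-readable JSON file (full precision).
#'
#' @param fit A `survival_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "survival_fit"))
  pars <- unclass(fit$params)
  if (!is.null(pars$gamma) && is.infinite(pars$gamma))
    pars$gamma <- "unbounded"
  rec <- list(
    model = fit$model_kind,
    label = fit$label,
    parameters = pars,
    pct_uncertainty = as.list(fit$pct_uncertainty),
    wssr = fit$wssr,
    alpha_fixed_to_zero = fit$alpha_fixed_to_zero,
    gamma_unbounded = fit$gamma_unbounded,
    n_points = fit$n_points,
    fit_space = fit$fit_space
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
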