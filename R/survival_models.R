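#' Log survival under the linear-quadratic model
#'
#' Evaluates \eqn{\ln S = -\alpha d - \beta d^2}.
#'
#' @param params An [lq_params] object (an `elq_params` object is accepted;
#'   its `gamma` is ignored and only the low-dose `(alpha, beta)` pair is
#'   used).
#' @param dose Dose(s) in Gy, non-negative.  Vectorised.
#' @return Log surviving fraction (dimensionless, <= 0).
#' @export
#' @examples
#' lq_log_survival(lq_params(0.1164, 0.0396), 2)   # -0.3912
lq_log_survival <- function(params, dose) {
  stopifnot(inherits(params, "survival_params"))
  d <- .check_dose(dose)
  -params$alpha * d - params$beta * d^2
}

#' Log survival under the extended linear-quadratic model
#'
#' Evaluates
#' \deqn{\ln S = -(\alpha+\gamma) d + \frac{\gamma^2}{2\beta}
#'   \left(1 - e^{-2\beta d/\gamma}\right),}
#' computed with `expm1()` so the large-\eqn{\gamma} regime does not lose
#' precision to cancellation.  With `gamma = Inf` the evaluation delegates
#' exactly to [lq_log_survival()].
#'
#' @param params An [elq_params] object.
#' @param dose Dose(s) in Gy, non-negative.  Vectorised.
#' @return Log surviving fraction (dimensionless, <= 0).
#' @export
#' @examples
#' p <- elq_params(0, 0.07477, 1.282)
#' exp(elq_log_survival(p, 2))   # 0.758
elq_log_survival <- function(params, dose) {
  stopifnot(inherits(params, "elq_params"))
  d <- .check_dose(dose)
  if (gamma_is_unbounded(params)) return(lq_log_survival(params, d))
  a <- params$alpha; b <- params$beta; g <- params$gamma
  -(a + g) * d - g^2 / (2 * b) * expm1(-2 * b * d / g)
}

#' Generic log survival
#'
#' Dispatches to [lq_log_survival()] or [elq_log_survival()] on the class
#' of `params`.
#'
#' @param params A `survival_params` object.
#' @param dose Dose(s) in Gy.
#' @return Log surviving fraction.
#' @export
log_survival <- function(params, dose) UseMethod("log_survival")

#' @export
log_survival.lq_params <- function(params, dose) lq_log_survival(params, dose)

#' @export
log_survival.elq_params <- function(params, dose) elq_log_survival(params, dose)

#' Constant-dose-rate Lea-Catcheside protraction factor
#'
#' For an exposure at constant dose rate with first-order repair, the
#' quadratic term of the LQ is reduced by
#' \deqn{G(\lambda T) = \frac{2}{(\lambda T)^2}
#'   \left(e^{-\lambda T} + \lambda T - 1\right),}
#' where T is the exposure time and \eqn{\lambda} the repair rate.
#' G decreases from 1 (acute limit) towards 0, with
#' \eqn{G \sim 2/(\lambda T)} for long exposures.  Arguments below 1e-4 are
#' evaluated by the Taylor series \eqn{1 - x/3 + x^2/12} to avoid
#' catastrophic cancellation.
#'
#' @param lambda_T Dimensionless product \eqn{\lambda T >= 0}.  Vectorised.
#' @return G in (0, 1].
#' @export
#' @examples
#' protraction_factor(0)    # 1
#' protraction_factor(2)    # 0.567668
protraction_factor <- function(lambda_T) {
  if (!is.numeric(lambda_T) || anyNA(lambda_T))
    stop("'lambda_T' must be numeric without NA", call. = FALSE)
  if (any(lambda_T < 0))
    stop("'lambda_T' must be non-negative", call. = FALSE)
  x <- as.numeric(lambda_T)
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 12
  xl <- x[!small]
  out[!small] <- 2 / xl^2 * (exp(-xl) + xl - 1)
  out
}

#' Map a protraction specification to the ELQ gamma parameter
#'
#' Under the generalised dose-protraction picture,
#' \eqn{\gamma = 2\beta / (\delta + \lambda/R)}.  With `delta = 0` this is
#' \eqn{2\beta R/\lambda}, the classical constant-dose-rate correspondence;
#' with `delta > 0`, `gamma` stays finite even for an unbounded dose rate.
#' `delta = 0` together with an infinite dose rate yields the unbounded
#' sentinel `Inf` (the LQ limit).
#'
#' @param beta Quadratic coefficient, per Gy^2.
#' @param spec A [protraction_spec].
#' @return `gamma` in per Gy (possibly `Inf`).
#' @export
#' @examples
#' gamma_from_protraction(0.05, protraction_spec(dose_rate = 1, repair_rate = 0.5))
gamma_from_protraction <- function(beta, spec) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta), beta > 0,
            inherits(spec, "protraction_spec"))
  denom <- spec$delta + spec$repair_rate / spec$dose_rate
  if (denom == 0) return(Inf)
  2 * beta / denom
}

#' Low-dose cubic expansion of the ELQ log survival
#'
#' Third-order truncation
#' \deqn{\ln S \approx -\alpha d - \beta d^2 + \frac{2\beta^2}{3\gamma} d^3,}
#' used as a small-dose consistency check against [elq_log_survival()]
#' (agreement is \eqn{O(d^4)}).  With `gamma` unbounded the cubic term
#' vanishes and the LQ form is returned.
#'
#' @inheritParams elq_log_survival
#' @return Truncated log surviving fraction.
#' @export
elq_low_dose_series <- function(params, dose) {
  stopifnot(inherits(params, "elq_params"))
  d <- .check_dose(dose)
  if (gamma_is_unbounded(params)) return(lq_log_survival(params, d))
  a <- params$alpha; b <- params$beta; g <- params$gamma
  -a * d - b * d^2 + (2 * b^2) / (3 * g) * d^3
}

#' High-dose linear asymptote of the ELQ log survival
#'
#' \deqn{\ln S \approx -(\alpha+\gamma) d + \frac{\gamma^2}{2\beta},}
#' i.e. a straight line of slope \eqn{-(\alpha+\gamma)} with extrapolation
#' number \eqn{e^{\gamma^2/(2\beta)}} on the survival axis.  The exact ELQ
#' approaches this form exponentially fast as dose grows.
#'
#' @inheritParams elq_log_survival
#' @return Asymptotic log surviving fraction.
#' @export
elq_high_dose_asymptote <- function(params, dose) {
  stopifnot(inherits(params, "elq_params"))
  if (gamma_is_unbounded(params))
    stop("high-dose asymptote undefined for unbounded gamma (LQ limit)",
         call. = FALSE)
  d <- .check_dose(dose)
  a <- params$alpha; b <- params$beta; g <- params$gamma
  -(a + g) * d + g^2 / (2 * b)
}
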