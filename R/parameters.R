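#' Linear-quadratic model parameters
#'
#' Constructs a validated parameter set for the two-parameter
#' linear-quadratic (LQ) survival model \eqn{\ln S = -\alpha d - \beta d^2}.
#'
#' @param alpha Linear coefficient, per Gy.  Must be non-negative.
#' @param beta Quadratic coefficient, per Gy^2.  Must be strictly positive.
#'
#' @return An object of class `lq_params` with elements `alpha` and `beta`.
#' @seealso [elq_params()], [alpha_beta_ratio()], [lq_log_survival()]
#' @export
#' @examples
#' p <- lq_params(alpha = 0.1164, beta = 0.0396)
#' alpha_beta_ratio(p)
lq_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = c("lq_params", "survival_params"))
}

#' Extended linear-quadratic model parameters
#'
#' Constructs a validated parameter set for the three-parameter extended
#' linear-quadratic (ELQ) model
#' \deqn{\ln S = -(\alpha+\gamma) d + \frac{\gamma^2}{2\beta}
#'   \left(1 - e^{-2\beta d/\gamma}\right).}
#' At low dose the model behaves like the LQ with the same `alpha` and
#' `beta`; at high dose log-survival is linear with slope
#' \eqn{-(\alpha+\gamma)} and extrapolation number \eqn{\gamma^2/(2\beta)}.
#'
#' `gamma = Inf` is the sentinel for the unbounded-\eqn{\gamma} (pure LQ)
#' limit: every evaluation then delegates exactly to the LQ form with the
#' same `(alpha, beta)`.
#'
#' @param alpha Low-dose linear coefficient, per Gy.  Non-negative.
#' @param beta Low-dose quadratic coefficient, per Gy^2.  Strictly positive.
#' @param gamma High-dose slope offset, per Gy (high-dose slope is
#'   `alpha + gamma`).  Strictly positive, or `Inf` for the LQ limit.
#'
#' @return An object of class `elq_params`.
#' @seealso [lq_params()], [elq_log_survival()], [gamma_from_protraction()]
#' @export
#' @examples
#' elq_params(alpha = 0, beta = 0.07477, gamma = 1.282)
#' elq_params(alpha = 0.269, beta = 0.0349, gamma = Inf)  # LQ limit
elq_params <- function(alpha, beta, gamma = Inf) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(gamma), length(gamma) == 1L, !is.na(gamma))
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  if (gamma <= 0) stop("'gamma' must be > 0 (use Inf for the LQ limit)",
                       call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma)),
            class = c("elq_params", "survival_params"))
}

#' Test for the unbounded-gamma (LQ) limit of an ELQ parameter set
#'
#' @param params An `elq_params` object.
#' @return `TRUE` if `gamma` is the unbounded sentinel (`Inf`).
#' @export
gamma_is_unbounded <- function(params) {
  stopifnot(inherits(params, "elq_params"))
  is.infinite(params$gamma)
}

#' Alpha/beta ratio of a parameter set or fit
#'
#' The \eqn{\alpha/\beta} ratio (in Gy) is the dose at which the linear and
#' quadratic contributions to cell killing are equal; it governs
#' fractionation sensitivity.
#'
#' @param x An `lq_params`, `elq_params`, or [survival_fit] object.
#' @param ... Unused.
#' @return The ratio in Gy (for a fit, see [survival_fit] for the
#'   uncertainty-propagated variant).
#' @export
alpha_beta_ratio <- function(x, ...) UseMethod("alpha_beta_ratio")

#' @export
alpha_beta_ratio.survival_params <- function(x, ...) x$alpha / x$beta

#' Constant-dose-rate protraction specification
#'
#' Describes a protracted exposure: dose rate `R` (Gy per hour), first-order
#' sublethal-damage repair rate `lambda` (per hour), and a
#' dose-rate-independent term `delta` (per Gy).  `delta = 0` recovers the
#' classical dose-protraction-modified LQ; a positive `delta` keeps the
#' high-dose slope finite even at unbounded dose rate.  `lambda` and `R`
#' must share the same time unit (hours by convention here); no unit
#' conversion is performed.
#'
#' @param dose_rate Dose rate R, Gy per hour.  Positive; may be `Inf`
#'   (acute exposure).
#' @param repair_rate Repair rate lambda, per hour.  Strictly positive and
#'   finite.
#' @param delta Dose-rate-independent coefficient, per Gy.  Non-negative.
#'
#' @return An object of class `protraction_spec`.
#' @seealso [gamma_from_protraction()], [protraction_factor()]
#' @export
protraction_spec <- function(dose_rate, repair_rate, delta = 0) {
  stopifnot(is.numeric(dose_rate), length(dose_rate) == 1L, !is.na(dose_rate),
            is.numeric(repair_rate), length(repair_rate) == 1L,
            is.finite(repair_rate),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (dose_rate <= 0) stop("'dose_rate' must be > 0", call. = FALSE)
  if (repair_rate <= 0) stop("'repair_rate' must be > 0", call. = FALSE)
  if (delta < 0) stop("'delta' must be >= 0", call. = FALSE)
  structure(list(dose_rate = as.numeric(dose_rate),
                 repair_rate = as.numeric(repair_rate),
                 delta = as.numeric(delta)),
            class = "protraction_spec")
}

#' @export
print.lq_params <- function(x, ...) {
  cat(sprintf("LQ parameters: alpha = %.6g /Gy, beta = %.6g /Gy^2 (alpha/beta = %.4g Gy)\n",
              x$alpha, x$beta, x$alpha / x$beta))
  invisible(x)
}

#' @export
print.elq_params <- function(x, ...) {
  g <- if (is.infinite(x$gamma)) "unbounded (LQ limit)" else
    sprintf("%.6g /Gy", x$gamma)
  cat(sprintf("ELQ parameters: alpha = %.6g /Gy, beta = %.6g /Gy^2, gamma = %s\n",
              x$alpha, x$beta, g))
  if (is.finite(x$gamma))
    cat(sprintf("  high-dose slope %.6g /Gy, extrapolation number %.6g\n",
                x$alpha + x$gamma, x$gamma^2 / (2 * x$beta)))
  invisible(x)
}

#' @export
print.protraction_spec <- function(x, ...) {
  cat(sprintf("Protraction: dose rate %.4g Gy/h, repair rate %.4g /h, delta %.4g /Gy\n",
              x$dose_rate, x$repair_rate, x$delta))
  invisible(x)
}

# shared dose-vector validation
.check_dose <- function(dose) {
  if (!is.numeric(dose) || anyNA(dose))
    stop("'dose' must be a numeric vector without NA", call. = FALSE)
  if (any(dose < 0))
    stop("'dose' must be non-negative", call. = FALSE)
  as.numeric(dose)
}
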