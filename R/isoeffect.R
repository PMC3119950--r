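# Isoeffect calculations.  The effect of a fractionated schedule is
# E = -ln(total survival) assuming complete interfraction repair of
# sublethal damage and no repopulation, so E = n * (-ln S(d)) with
# d = D/n.  For the LQ, E = alpha*D + beta*D^2/n and the isoeffect total
# dose has a closed form; for the ELQ the relation
#   (alpha+gamma) D - n*gamma^2/(2 beta) (1 - exp(-2 beta D/(n gamma))) = E
# is implicit and is solved by bracketed root finding.

#' Fractionation schedule
#'
#' A schedule of `n` fractions of `d` Gy each (total dose `n * d`).
#' Fraction numbers may be non-integer when tracing continuous isoeffect
#' curves.
#'
#' @param n Fraction count, >= 1 (real values allowed).
#' @param d Dose per fraction in Gy, > 0.
#' @return An object of class `schedule` with elements `n`, `d`,
#'   `total_dose`.
#' @seealso [parse_schedule()]
#' @export
#' @examples
#' schedule(40, 2)
schedule <- function(n, d) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(d), length(d) == 1L, is.finite(d))
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (d <= 0) stop("'d' must be > 0", call. = FALSE)
  structure(list(n = as.numeric(n), d = as.numeric(d),
                 total_dose = as.numeric(n) * as.numeric(d)),
            class = "schedule")
}

#' Parse a schedule given as "NxD" text
#'
#' E.g. `"40x2"` is 40 fractions of 2 Gy; `"3x15"` is 3 fractions of
#' 15 Gy.
#'
#' @param text Schedule string, fractions then Gy per fraction.
#' @return A [schedule].
#' @export
parse_schedule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^\\s*([0-9.]+)\\s*[xX]\\s*([0-9.]+)\\s*$", text))[[1]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse schedule '%s' (expected e.g. '40x2')", text),
         call. = FALSE)
  schedule(as.numeric(m[2]), as.numeric(m[3]))
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("Schedule: %g x %g Gy (total %g Gy)\n", x$n, x$d, x$total_dose))
  invisible(x)
}

#' Effect of a schedule under the LQ model
#'
#' \eqn{E = \alpha D + \beta D^2 / n}, the negative log of total survival.
#'
#' @param params An [lq_params] (or `elq_params`, using its low-dose
#'   `(alpha, beta)`).
#' @param sched A [schedule].
#' @return Effect E (dimensionless, >= 0).
#' @export
#' @examples
#' lq_effect(lq_params(0.2697, 0.03476), schedule(40, 2))  # 27.14
lq_effect <- function(params, sched) {
  stopifnot(inherits(params, "survival_params"), inherits(sched, "schedule"))
  D <- sched$total_dose
  params$alpha * D + params$beta * D^2 / sched$n
}

#' Effect of a schedule under the ELQ model
#'
#' \eqn{E = (\alpha+\gamma) D - n \frac{\gamma^2}{2\beta}
#'   (1 - e^{-2\beta D/(n\gamma)})}, equal to
#' `n * (-elq_log_survival(params, D/n))`.  Unbounded `gamma` delegates to
#' [lq_effect()].
#'
#' @param params An [elq_params].
#' @param sched A [schedule].
#' @return Effect E (dimensionless, >= 0).
#' @export
elq_effect <- function(params, sched) {
  stopifnot(inherits(params, "elq_params"), inherits(sched, "schedule"))
  if (gamma_is_unbounded(params)) return(lq_effect(params, sched))
  sched$n * (-elq_log_survival(params, sched$d))
}

#' Generic schedule effect
#'
#' @param params A `survival_params` object.
#' @param sched A [schedule].
#' @return Effect E.
#' @export
schedule_effect <- function(params, sched) UseMethod("schedule_effect")

#' @export
schedule_effect.lq_params <- function(params, sched) lq_effect(params, sched)

#' @export
schedule_effect.elq_params <- function(params, sched) elq_effect(params, sched)

#' LQ isoeffect total dose (closed form)
#'
#' Solves \eqn{\beta D^2/n + \alpha D - E = 0} for the positive root
#' \deqn{D = \frac{n}{2\beta}\left(\sqrt{\alpha^2 + 4\beta E/n} -
#'   \alpha\right),}
#' with the pure-quadratic branch \eqn{D = \sqrt{nE/\beta}} when
#' \eqn{\alpha = 0}.
#'
#' @param params An [lq_params] (or `elq_params`; low-dose pair used).
#' @param E Target effect, > 0.
#' @param n Fraction count(s), >= 1.  Vectorised.
#' @return Total dose(s) D in Gy.
#' @export
lq_isoeffect_dose <- function(params, E, n) {
  stopifnot(inherits(params, "survival_params"),
            is.numeric(E), length(E) == 1L, E > 0,
            is.numeric(n), all(n >= 1))
  a <- params$alpha; b <- params$beta
  if (a == 0) return(sqrt(n * E / b))
  n / (2 * b) * (sqrt(a^2 + 4 * b * E / n) - a)
}

#' ELQ isoeffect total dose (implicit solve)
#'
#' Finds the unique `D > 0` with `elq_effect(params, schedule(n, D/n)) = E`.
#' The effect is strictly increasing in D, and the root is bracketed
#' analytically: the lower bound `E/(alpha+gamma)` drops the positive
#' repair term, and the upper bound adds the asymptote offset
#' `n*gamma^2 / (2*beta*(alpha+gamma))`.  The bracketed root from
#' [stats::uniroot()] is polished by two Newton steps so the residual
#' effect mismatch is below 1e-9.
#'
#' @param params An [elq_params]; unbounded `gamma` delegates to
#'   [lq_isoeffect_dose()].
#' @param E Target effect, > 0.
#' @param n Fraction count(s), >= 1.  Vectorised.
#' @return Total dose(s) D in Gy.
#' @export
#' @examples
#' p <- elq_params(0, 0.07477, 1.282)
#' E <- elq_effect(p, schedule(40, 2))
#' elq_isoeffect_dose(p, E, 1)   # 15.9 Gy
elq_isoeffect_dose <- function(params, E, n) {
  stopifnot(inherits(params, "elq_params"),
            is.numeric(E), length(E) == 1L, E > 0,
            is.numeric(n), all(n >= 1))
  if (gamma_is_unbounded(params)) return(lq_isoeffect_dose(params, E, n))
  a <- params$alpha; b <- params$beta; g <- params$gamma
  slope <- a + g
  vapply(as.numeric(n), function(ni) {
    eff <- function(D) slope * D + ni * g^2 / (2 * b) *
      expm1(-2 * b * D / (ni * g))
    lo <- E / slope
    hi <- lo + ni * g^2 / (2 * b * slope)
    f <- function(D) eff(D) - E
    # analytic bracket: f(lo) <= 0 <= f(hi); tiny margins guard roundoff
    root <- tryCatch(
      stats::uniroot(f, lower = lo * (1 - 1e-12), upper = hi * (1 + 1e-12),
                     tol = 1e-12 * max(1, hi))$root,
      error = function(e)
        stop(sprintf("isoeffect bracket failed at n = %g: %s", ni,
                     conditionMessage(e)), call. = FALSE))
    for (i in 1:2) {  # Newton polish to machine precision
      deriv <- slope - g * exp(-2 * b * root / (ni * g))
      root <- root - f(root) / deriv
    }
    root
  }, numeric(1))
}

#' Generic isoeffect total dose
#'
#' @param params A `survival_params` object.
#' @param E Target effect.
#' @param n Fraction count(s).
#' @return Total dose(s) in Gy.
#' @export
isoeffect_dose <- function(params, E, n) UseMethod("isoeffect_dose")

#' @export
isoeffect_dose.lq_params <- function(params, E, n) lq_isoeffect_dose(params, E, n)

#' @export
isoeffect_dose.elq_params <- function(params, E, n) elq_isoeffect_dose(params, E, n)

#' Isoeffect curve over a range of fraction numbers
#'
#' Computes the effect E of the reference schedule under `params`, then the
#' isoeffective total dose at every fraction number in `n`.  The curve
#' passes exactly through the reference schedule.
#'
#' @param params An [lq_params] or [elq_params].
#' @param reference A [schedule] defining the effect level.
#' @param n Fraction numbers (default `1:50`).
#' @return An `isoeffect_curve`: a data frame with columns `n` and
#'   `total_dose` (Gy) plus attributes `effect`, `reference`, `params`.
#' @export
#' @examples
#' isoeffect_curve(lq_params(0.1164, 0.0396), schedule(40, 2), n = c(1, 24, 40))
isoeffect_curve <- function(params, reference, n = 1:50) {
  stopifnot(inherits(params, "survival_params"), inherits(reference, "schedule"))
  E <- schedule_effect(params, reference)
  D <- isoeffect_dose(params, E, n)
  structure(data.frame(n = as.numeric(n), total_dose = D),
            effect = E, reference = reference, params = params,
            class = c("isoeffect_curve", "data.frame"))
}

#' @export
print.isoeffect_curve <- function(x, ...) {
  ref <- attr(x, "reference")
  cat(sprintf("Isoeffect curve: E = %.4f (reference %g x %g Gy)\n",
              attr(x, "effect"), ref$n, ref$d))
  print.data.frame(x, ...)
  invisible(x)
}

#' Fraction-number ratio for equal effect at a fixed dose per fraction
#'
#' If an LQ and an ELQ parameterisation of the same cells are compared at
#' dose-per-fraction `d`, equal total effect requires
#' \eqn{n_{ELQ} / n_{LQ} = \ln S_{LQ}(d) / \ln S_{ELQ}(d)} fractions, since
#' total log survival is additive over fractions.
#'
#' @param lq An [lq_params].
#' @param elq An [elq_params].
#' @param d Dose per fraction in Gy, > 0.
#' @return The dimensionless ratio `n_ELQ / n_LQ`.
#' @export
#' @examples
#' fraction_ratio(lq_params(0.1164, 0.0396), elq_params(0, 0.07477, 1.282), 2)
fraction_ratio <- function(lq, elq, d) {
  stopifnot(inherits(lq, "survival_params"), inherits(elq, "elq_params"),
            is.numeric(d), length(d) == 1L, d > 0)
  num <- lq_log_survival(lq, d)
  den <- elq_log_survival(elq, d)
  if (num == 0 || den == 0)
    stop("zero log survival at this dose; ratio undefined", call. = FALSE)
  num / den
}

#' LQ parameter set with a prescribed alpha/beta ratio
#'
#' Isoeffect total doses anchored to a reference schedule depend only on
#' the \eqn{\alpha/\beta} ratio, not on the absolute scale of
#' \eqn{(\alpha, \beta)}: the LQ isoeffect relation reduces to
#' \eqn{D (1 + d / (\alpha/\beta)) = const} (the biologically-effective-dose
#' cancellation).  This helper fixes the scale by the convention
#' `alpha = 1`, which is immaterial for any anchored isoeffect
#' calculation.
#'
#' @param alpha_beta The desired ratio in Gy, > 0.
#' @param alpha Scale convention (default 1 per Gy).
#' @return An [lq_params] with `alpha/beta = alpha_beta`.
#' @export
lq_params_from_ratio <- function(alpha_beta, alpha = 1) {
  stopifnot(is.numeric(alpha_beta), length(alpha_beta) == 1L, alpha_beta > 0)
  lq_params(alpha, alpha / alpha_beta)
}

#' Isoeffect uncertainty band from parameter uncertainties
#'
#' Propagates per-parameter standard errors to the isoeffect curve by
#' corner evaluation: every combination of free parameters at plus or minus
#' one standard error is evaluated (effect level re-derived from the
#' reference schedule at each corner), and the per-n minimum and maximum
#' isoeffect doses over all corners and the nominal curve are reported.
#' Corners violating parameter-domain constraints are clipped to the
#' boundary and flagged.  The band contains the nominal curve by
#' construction.
#'
#' @param fit A `survival_fit` (from [fit_lq()]/[fit_elq()]) or a list with
#'   elements `params` (a `survival_params`) and `pct_uncertainty`
#'   (named percentages for the free parameters).
#' @param reference A [schedule].
#' @param n Fraction numbers (default `1:50`).
#' @return A data frame with columns `n`, `total_dose` (nominal), `lower`,
#'   `upper` (Gy); attribute `clipped` reports whether any corner was
#'   clipped to the parameter domain.
#' @export
isoeffect_uncertainty_band <- function(fit, reference, n = 1:50) {
  stopifnot(inherits(reference, "schedule"))
  params <- fit$params
  pct <- fit$pct_uncertainty
  stopifnot(inherits(params, "survival_params"), !is.null(pct))
  free <- names(pct)[!is.na(pct)]
  nominal <- isoeffect_curve(params, reference, n)$total_dose

  lo <- hi <- nominal
  clipped <- FALSE
  if (length(free)) {
    signs <- expand.grid(rep(list(c(-1, 1)), length(free)))
    for (k in seq_len(nrow(signs))) {
      p <- unclass(params)
      for (j in seq_along(free)) {
        nm <- free[j]
        val <- p[[nm]] * (1 + signs[k, j] * pct[[nm]] / 100)
        # clip to the parameter domain (alpha >= 0; beta, gamma > 0)
        min_ok <- if (nm == "alpha") 0 else 1e-12
        if (val < min_ok) { val <- min_ok; clipped <- TRUE }
        p[[nm]] <- val
      }
      corner <- if (inherits(params, "elq_params"))
        elq_params(p$alpha, p$beta, p$gamma) else lq_params(p$alpha, p$beta)
      Dk <- isoeffect_curve(corner, reference, n)$total_dose
      lo <- pmin(lo, Dk); hi <- pmax(hi, Dk)
    }
  }
  structure(data.frame(n = as.numeric(n), total_dose = nominal,
                       lower = lo, upper = hi),
            clipped = clipped, class = c("isoeffect_band", "data.frame"))
}

#' Agreement of small-alpha/beta LQ curves with an ELQ isoeffect curve
#'
#' For each candidate \eqn{\alpha/\beta} ratio, anchors an LQ isoeffect
#' curve to the same reference schedule as the ELQ curve (see
#' [lq_params_from_ratio()]) and reports the maximal contiguous run of
#' fraction numbers over which the two total doses agree within
#' `tolerance` Gy.
#'
#' @param elq An [elq_params].
#' @param alpha_beta_candidates Numeric vector of candidate ratios in Gy.
#' @param reference A [schedule].
#' @param n Fraction numbers to scan (default `1:50`).
#' @param tolerance Agreement tolerance in Gy (default 1).
#' @return A data frame with one row per candidate: `alpha_beta`,
#'   `n_from`, `n_to` (bounds of the longest agreement run; `NA` if
#'   empty), `n_agree` (count within tolerance anywhere), and
#'   `max_abs_diff_Gy`.  Attribute `detail` holds the per-(candidate, n)
#'   dose differences.
#' @export
lq_approximation_report <- function(elq, alpha_beta_candidates, reference,
                                    n = 1:50, tolerance = 1) {
  stopifnot(inherits(elq, "elq_params"), is.numeric(alpha_beta_candidates),
            all(alpha_beta_candidates > 0), inherits(reference, "schedule"),
            is.numeric(tolerance), tolerance > 0)
  D_elq <- isoeffect_curve(elq, reference, n)$total_dose
  detail <- NULL
  rows <- lapply(alpha_beta_candidates, function(ab) {
    D_lq <- isoeffect_curve(lq_params_from_ratio(ab), reference, n)$total_dose
    diff <- D_lq - D_elq
    detail <<- rbind(detail, data.frame(alpha_beta = ab, n = as.numeric(n),
                                        D_lq = D_lq, D_elq = D_elq,
                                        diff_Gy = diff))
    ok <- abs(diff) <= tolerance
    if (!any(ok)) {
      return(data.frame(alpha_beta = ab, n_from = NA_real_, n_to = NA_real_,
                        n_agree = 0L, max_abs_diff_Gy = max(abs(diff))))
    }
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    data.frame(alpha_beta = ab, n_from = as.numeric(n[starts[best]]),
               n_to = as.numeric(n[ends[best]]),
               n_agree = sum(ok), max_abs_diff_Gy = max(abs(diff)))
  })
  structure(do.call(rbind, rows), detail = detail,
            class = c("lq_approximation_report", "data.frame"))
}
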