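# Synthetic clonogenic-survival data with proportional multiplicative
# noise, emulating the statistical structure the fitting module assumes:
# the standard deviation of a point is proportional to its value.

#' Configuration for the synthetic survival-data generator
#'
#' @param params True model parameters ([lq_params] or [elq_params]).
#' @param doses Dose grid in Gy: strictly increasing, non-negative.  The
#'   default grid (0.5 to 15 Gy in 12 points, denser at low dose) mimics a
#'   typical extended-dose-range clonogenic experiment.
#' @param noise_cv Proportional coefficient of variation of each point
#'   (default 0.05, i.e. 5 percent).  `0` gives exact model values.
#' @param replicates Independent draws per dose; the reported point is
#'   their mean and the reported SD is `noise_cv * value / sqrt(replicates)`.
#' @param seed Master seed (integer).  Per-dose substreams are derived
#'   from it, so extending the grid does not reshuffle existing draws.
#' @param noise `"lognormal"` (default; positive support, parameterised to
#'   match the model mean and the requested CV) or `"truncnormal"`
#'   (normal draws, redrawn into positive range).
#' @param label Dataset label.
#' @return A `generator_config` object.
#' @seealso [generate_dataset()], [cell_line_fixtures()]
#' @export
generator_config <- function(params,
                             doses = c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 15),
                             noise_cv = 0.05, replicates = 1L, seed = 1L,
                             noise = c("lognormal", "truncnormal"),
                             label = "synthetic") {
  stopifnot(inherits(params, "survival_params"),
            is.numeric(noise_cv), length(noise_cv) == 1L, noise_cv >= 0,
            is.numeric(replicates), replicates >= 1,
            is.numeric(seed), length(seed) == 1L)
  doses <- .check_dose(doses)
  if (length(doses) >= 2L && any(diff(doses) <= 0))
    stop("'doses' must be strictly increasing", call. = FALSE)
  noise <- match.arg(noise)
  structure(list(params = params, doses = doses,
                 noise_cv = as.numeric(noise_cv),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), noise = noise,
                 label = as.character(label)[1L]),
            class = "generator_config")
}

# deterministic 32-bit substream seed for dose index i
.substream_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + i * 1000003) %% 2147483629)
}

#' Generate a synthetic dose-survival dataset
#'
#' Draws, at each dose, surviving fractions from a positive-support
#' distribution with mean equal to the model value and standard deviation
#' `noise_cv` times the model value, then truncates to (0, 1].  The
#' recorded `sd` column follows the proportional convention applied to the
#' observed value, matching what the fitting module assumes for real data
#' without error bars.  A fixed seed gives bit-identical output; each dose
#' has its own derived substream.
#'
#' @param config A [generator_config].
#' @return A [survival_dataset].  If truncation at 1 affected more than
#'   1 percent of draws, attribute `truncation_warning` is `TRUE` (with a
#'   warning).
#' @export
#' @examples
#' cfg <- generator_config(elq_params(0, 0.07477, 1.282), noise_cv = 0.05, seed = 7)
#' generate_dataset(cfg)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  mu <- exp(log_survival(config$params, config$doses))
  cv <- config$noise_cv
  n_trunc <- 0L
  if (cv == 0) {
    sf <- mu
  } else {
    sf <- numeric(length(mu))
    for (i in seq_along(mu)) {
      set.seed(.substream_seed(config$seed, i))
      draws <- if (config$noise == "lognormal") {
        sdlog <- sqrt(log1p(cv^2))
        stats::rlnorm(config$replicates,
                      meanlog = log(mu[i]) - sdlog^2 / 2, sdlog = sdlog)
      } else {
        x <- stats::rnorm(config$replicates, mean = mu[i], sd = cv * mu[i])
        while (any(x <= 0))  # redraw into positive support
          x[x <= 0] <- stats::rnorm(sum(x <= 0), mean = mu[i], sd = cv * mu[i])
        x
      }
      n_trunc <- n_trunc + sum(draws > 1)
      draws[draws > 1] <- 1
      sf[i] <- mean(draws)
    }
    sf <- pmin(sf, 1)
  }
  total <- length(mu) * config$replicates
  warn <- n_trunc > 0.01 * total
  if (warn)
    warning(sprintf("truncation at S = 1 affected %d of %d draws (> 1%%)",
                    n_trunc, total), call. = FALSE)
  sd <- if (cv == 0) NULL else cv * sf / sqrt(config$replicates)
  out <- survival_dataset(config$doses, sf, sd = sd, label = config$label)
  attr(out, "truncation_warning") <- warn
  out
}

#' Generator configurations emulating the four reference cell lines
#'
#' Returns named [generator_config]s for CHO, NCIH841, PC3 and CP3 whose
#' true parameters are the published ELQ fits (CHO in its LQ limit,
#' unbounded gamma) from [cell_line_parameters()].  The measurement dose
#' rates of the original experiments are attached as metadata.  The
#' original dose grids and error bars are not published, so these fixtures
#' are statistical stand-ins sharing the assumed error structure, not
#' reconstructions of the digitized datasets.
#'
#' @param noise_cv Proportional CV for all fixtures (default 0.05).
#' @param seed Master seed; fixture i uses `seed + i - 1`.
#' @return Named list of `generator_config` objects, each with a
#'   `dose_rate_Gy_min` attribute.
#' @export
#' @examples
#' fx <- cell_line_fixtures(seed = 42)
#' gamma_is_unbounded(fx$CHO$params)   # TRUE
cell_line_fixtures <- function(noise_cv = 0.05, seed = 1L) {
  pars <- cell_line_parameters()
  out <- list()
  for (i in seq_along(pars)) {
    nm <- names(pars)[i]
    cfg <- generator_config(pars[[nm]]$elq, noise_cv = noise_cv,
                            seed = seed + i - 1L, label = nm)
    attr(cfg, "dose_rate_Gy_min") <- pars[[nm]]$dose_rate_Gy_min
    out[[nm]] <- cfg
  }
  out
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Generator '%s': %s, %d doses (%.3g-%.3g Gy), cv = %g, %d replicate(s), seed %d, %s noise\n",
              x$label, class(x$params)[1], length(x$doses), min(x$doses),
              max(x$doses), x$noise_cv, x$replicates, x$seed, x$noise))
  invisible(x)
}
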