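#' Clonogenic dose-survival dataset
#'
#' Container for one cell line's dose/surviving-fraction measurements.
#' Doses must be non-negative and strictly increasing; surviving fractions
#' must lie in (0, 1].  If per-point standard deviations are not supplied,
#' the proportional-error convention is applied: the effective standard
#' deviation of a point is `sd_scale` times its surviving fraction.
#'
#' @param dose Numeric vector of doses in Gy, strictly increasing, >= 0.
#' @param surviving_fraction Numeric vector in (0, 1], same length.
#' @param sd Optional per-point standard deviations (> 0).  If `NULL`,
#'   `sd_scale * surviving_fraction` is used.
#' @param label Character label for the dataset (e.g. a cell-line name).
#' @param sd_scale Proportionality constant of the proportional-SD
#'   convention (default 1).  It only rescales the weighted sum of squared
#'   residuals, not the fitted parameters.
#'
#' @return A `survival_dataset`: a data frame with columns `dose`,
#'   `surviving_fraction`, `sd` and attributes `label` and `sd_assumed`.
#' @seealso [read_survival_dataset()], [fit_lq()], [generate_dataset()]
#' @export
survival_dataset <- function(dose, surviving_fraction, sd = NULL,
                             label = "", sd_scale = 1) {
  dose <- .check_dose(dose)
  if (length(dose) != length(surviving_fraction))
    stop("'dose' and 'surviving_fraction' lengths differ", call. = FALSE)
  if (length(dose) >= 2L && any(diff(dose) <= 0))
    stop("doses must be strictly increasing", call. = FALSE)
  sf <- as.numeric(surviving_fraction)
  if (anyNA(sf) || any(sf <= 0) || any(sf > 1))
    stop("surviving fractions must lie in (0, 1]", call. = FALSE)
  sd_assumed <- is.null(sd)
  if (sd_assumed) {
    sd <- sd_scale * sf
  } else {
    sd <- as.numeric(sd)
    if (length(sd) != length(sf) || anyNA(sd) || any(sd <= 0))
      stop("'sd' must be positive and match the data length", call. = FALSE)
  }
  structure(
    data.frame(dose = dose, surviving_fraction = sf, sd = sd),
    label = as.character(label)[1L],
    sd_assumed = sd_assumed,
    class = c("survival_dataset", "data.frame")
  )
}

#' Read a dose-survival dataset from delimited text
#'
#' Expects a comma-separated file with a header row and columns
#' `dose_Gy`, `surviving_fraction` and optionally `sd`; lines starting with
#' `#` are comments.
#'
#' @param path Path to the file.
#' @param label Dataset label; defaults to the file name.
#' @param sd_scale Passed to [survival_dataset()] when no `sd` column is
#'   present.
#' @return A [survival_dataset].
#' @export
read_survival_dataset <- function(path, label = NULL, sd_scale = 1) {
  if (!file.exists(path))
    stop(sprintf("dataset file not found: '%s'", path), call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("dose_Gy", "surviving_fraction")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  survival_dataset(
    dose = tab$dose_Gy,
    surviving_fraction = tab$surviving_fraction,
    sd = if ("sd" %in% names(tab)) tab$sd else NULL,
    label = if (is.null(label)) basename(path) else label,
    sd_scale = sd_scale
  )
}

#' Write a dose-survival dataset as delimited text
#'
#' Writes the format read by [read_survival_dataset()] at full precision
#' (round-trip lossless).
#'
#' @param data A [survival_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_dataset <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# survival dataset: %s", attr(data, "label")), con)
  out <- data.frame(dose_Gy = format(data$dose, digits = 17, trim = TRUE),
                    surviving_fraction = format(data$surviving_fraction,
                                                digits = 17, trim = TRUE),
                    sd = format(data$sd, digits = 17, trim = TRUE))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset '%s': %d points, doses %.3g-%.3g Gy%s\n",
              attr(x, "label"), nrow(x), min(x$dose), max(x$dose),
              if (isTRUE(attr(x, "sd_assumed"))) " (proportional SD assumed)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}
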