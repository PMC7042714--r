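#' Fit a log-linear SEC molecular-weight calibration
#'
#' Apparent molecular weight decays approximately log-linearly with fraction
#' number on a size-exclusion column. The calibration is an ordinary
#' least-squares fit of `ln(MW)` on apex fraction of standard proteins of
#' known MW, giving the map `MW(f) = exp(a + b * f)` with `b < 0`.
#'
#' @param standards A data frame with columns `mw_kda` (> 0) and
#'   `apex_fraction`; at least 2 standards with distinct apex fractions.
#' @return A `sec_calibration` object with elements `intercept` (natural-log
#'   kDa), `slope` (natural-log kDa per fraction), the underlying `lm` fit
#'   and the standards table.
#' @export
#' @examples
#' cal <- fit_calibration(data.frame(
#'   protein = c("s1", "s2"), mw_kda = c(1000, 10), apex_fraction = c(10, 30)
#' ))
#' apparent_mw(cal, 20) # 100 kDa
fit_calibration <- function(standards) {
  standards <- tibble::as_tibble(standards)
  if (!all(c("mw_kda", "apex_fraction") %in% names(standards))) {
    abort("standards need columns `mw_kda` and `apex_fraction`")
  }
  if (any(standards$mw_kda <= 0)) abort("standard MW must be > 0")
  if (dplyr::n_distinct(standards$apex_fraction) < 2) {
    abort("need >= 2 standards with distinct apex fractions")
  }
  fit <- lm(log(mw_kda) ~ apex_fraction, data = standards)
  b <- unname(coef(fit)[2])
  if (b >= 0) {
    abort("fitted slope >= 0: apparent MW must decrease with fraction")
  }
  structure(
    list(intercept = unname(coef(fit)[1]), slope = b, fit = fit,
         standards = standards),
    class = "sec_calibration"
  )
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf(
    "<sec_calibration> ln MW(kDa) = %.4f %+.4f * fraction  (n = %d standards)\n",
    x$intercept, x$slope, nrow(x$standards)
  ))
  invisible(x)
}

#' Apparent molecular weight at a fraction
#'
#' @param calibration A [fit_calibration()] result.
#' @param fraction Fraction number(s); non-integer values and values outside
#'   the calibrated range are allowed (extrapolation).
#' @return Apparent MW in kDa, strictly decreasing in fraction.
#' @export
apparent_mw <- function(calibration, fraction) {
  stopifnot(inherits(calibration, "sec_calibration"))
  exp(calibration$intercept + calibration$slope * fraction)
}

#' Expected elution fraction of a given molecular weight
#'
#' Inverse of [apparent_mw()]: `(ln MW - a) / b`.
#'
#' @param calibration A [fit_calibration()] result.
#' @param mw_kda Molecular weight(s) in kDa.
#' @return Real-valued fraction position(s).
#' @export
expected_fraction <- function(calibration, mw_kda) {
  stopifnot(inherits(calibration, "sec_calibration"))
  (log(mw_kda) - calibration$intercept) / calibration$slope
}

#' Read a SEC calibration standards table
#'
#' TSV with columns `protein`, `mw_kda`, `apex_fraction`.
#'
#' @param path File path.
#' @return A tibble of standards suitable for [fit_calibration()].
#' @export
read_calibration <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(),
    mw_kda = readr::col_double(),
    apex_fraction = readr::col_double()
  ), progress = FALSE)
}

#' @export
tidy.sec_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = summary(x$fit)$coefficients[, "Std. Error"]
  )
}

#' @export
glance.sec_calibration <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    n_standards = nrow(x$standards),
    mw_range_kda = paste0(
      signif(min(x$standards$mw_kda), 3), "-",
      signif(max(x$standards$mw_kda), 3)
    )
  )
}
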