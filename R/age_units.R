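#' Convert ages to days post-conception
#'
#' Harmonizes the three age encodings found across prenatal methylation
#' datasets to a single scale anchored at conception:
#' \itemize{
#'   \item `dpc`: returned unchanged;
#'   \item `weeks_pc`: weeks post-conception, multiplied by 7;
#'   \item `years`: postnatal years (negative values allowed for the
#'     prenatal convention), converted as `years * 365 + 280`, i.e. birth
#'     is fixed at 280 dpc.
#' }
#'
#' Some pipeline descriptions state the weeks-to-days step as a division
#' by 7, which is dimensionally inconsistent (14 weeks of gestation is 98
#' days, not 2). The default multiplies; `strict_literal = TRUE`
#' reproduces the literal division for auditing such pipelines.
#'
#' @param value numeric age values.
#' @param unit character vector of units, `"dpc"`, `"weeks_pc"` or
#'   `"years"`, recycled against `value`.
#' @param strict_literal divide weeks by 7 instead of multiplying (audit
#'   mode; see Details).
#' @return numeric vector of ages in days post-conception (always > 0).
#' @export
to_dpc <- function(value, unit, strict_literal = FALSE) {
  n <- max(length(value), length(unit))
  value <- rep_len(as.numeric(value), n)
  unit <- rep_len(as.character(unit), n)
  if (!all(unit %in% VALID_AGE_UNITS)) {
    stop("unknown age unit: ", paste(setdiff(unique(unit), VALID_AGE_UNITS), collapse = ", "))
  }
  week_factor <- if (strict_literal) 1 / 7 else 7
  out <- ifelse(unit == "dpc", value,
         ifelse(unit == "weeks_pc", value * week_factor,
                value * 365 + 280))
  bad <- which(!is.na(out) & out <= 0)
  if (length(bad)) {
    stop(sprintf("age converts to %g dpc (<= 0, pre-conception) at position %d",
                 out[bad[1]], bad[1]))
  }
  out
}

#' Convert days post-conception back to another unit
#'
#' Exact inverse of [to_dpc()]: `to_dpc(from_dpc(x, u), u) == x`.
#'
#' @param dpc numeric ages in days post-conception (> 0).
#' @param unit target unit.
#' @return numeric vector in the requested unit.
#' @export
from_dpc <- function(dpc, unit) {
  n <- max(length(dpc), length(unit))
  dpc <- rep_len(as.numeric(dpc), n)
  unit <- rep_len(as.character(unit), n)
  if (!all(unit %in% VALID_AGE_UNITS)) {
    stop("unknown age unit: ", paste(setdiff(unique(unit), VALID_AGE_UNITS), collapse = ", "))
  }
  if (any(dpc <= 0, na.rm = TRUE)) stop("dpc must be positive")
  ifelse(unit == "dpc", dpc,
  ifelse(unit == "weeks_pc", dpc / 7,
         (dpc - 280) / 365))
}

#' Log-linear age transform used by multi-tissue clocks
#'
#' Maps chronological age in years onto the scale such clocks are trained
#' on: logarithmic below `adult_age`, linear above, continuous and
#' differentiable at the knot.
#'
#' @param age_years chronological age in years (> -1).
#' @param adult_age knot age in years (default 20).
#' @return transformed score; `horvath_transform(adult_age) == 0`.
#' @seealso [horvath_anti_transform()]
#' @export
horvath_transform <- function(age_years, adult_age = 20) {
  stopifnot(adult_age > 0)
  ifelse(age_years < adult_age,
         log((age_years + 1) / (adult_age + 1)),
         (age_years - adult_age) / (adult_age + 1))
}

#' Invert the log-linear age transform
#'
#' Back-transforms a clock's raw linear-predictor score to age in years:
#' `(1 + adult_age) * exp(score) - 1` for negative scores,
#' `(1 + adult_age) * score + adult_age` otherwise. The two branches meet
#' at `score = 0` (age `adult_age`); as the score tends to minus infinity
#' the age tends to -1 year, i.e. conception.
#'
#' @param score raw linear predictor of an age-transformed clock.
#' @param adult_age knot age in years (default 20).
#' @return predicted age in years.
#' @export
horvath_anti_transform <- function(score, adult_age = 20) {
  stopifnot(adult_age > 0)
  ifelse(score < 0,
         (1 + adult_age) * exp(score) - 1,
         (1 + adult_age) * score + adult_age)
}

#' Classify developmental stage from age in dpc
#'
#' Embryonic below 63 dpc, fetal from 63 up to birth (280 dpc),
#' postnatal from 280 dpc.
#'
#' @param dpc numeric ages in days post-conception (> 0).
#' @return factor with levels embryonic, fetal, postnatal.
#' @export
classify_stage <- function(dpc) {
  dpc <- as.numeric(dpc)
  if (any(dpc <= 0, na.rm = TRUE)) stop("dpc must be positive")
  out <- ifelse(dpc < 63, "embryonic", ifelse(dpc < 280, "fetal", "postnatal"))
  factor(out, levels = c("embryonic", "fetal", "postnatal"))
}
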