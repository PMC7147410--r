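#' Neoplasia-free survivorship curve
#'
#' `F(a)` is the fraction of the age-50 cohort that is alive and free of
#' colorectal neoplasia (CRC and adenomas) at integer age `a`. It is the
#' sufficient statistic for the cumulative false-positive rate in this model:
#' cumFP depends on the mortality and incidence schedules only through `F`.
#'
#' @param ages Integer vector of consecutive ages.
#' @param surv Numeric vector: `F(a)` for each age, non-increasing, in
#'   `(0, 1]` at the first age and non-negative thereafter.
#' @return A data frame with columns `age` and `surv`, of class
#'   `survivorship_curve`; `attr(x, "f50")` holds the value at the first age.
#' @export
survivorship_curve <- function(ages, surv) {
  ages <- as.integer(ages)
  if (length(ages) != length(surv)) stop("`ages` and `surv` lengths differ")
  if (length(ages) > 1L && !all(diff(ages) == 1L)) stop("non-consecutive ages")
  if (anyNA(surv) || !all(is.finite(surv))) stop("non-finite survivorship values")
  if (any(surv < 0) || any(surv > 1)) stop("survivorship must lie in [0,1]")
  if (surv[1L] <= 0) stop("survivorship at the first age must be positive")
  if (any(diff(surv) > 1e-12)) stop("survivorship must be non-increasing in age")
  structure(
    data.frame(age = ages, surv = as.numeric(surv)),
    f50 = surv[1L],
    class = c("survivorship_curve", "data.frame")
  )
}

#' Evaluate a survivorship curve at given ages
#'
#' @param curve A [survivorship_curve()].
#' @param ages Integer ages covered by the curve.
#' @return Numeric `F(a)` values.
#' @export
survivorship_at <- function(curve, ages) {
  stopifnot(inherits(curve, "survivorship_curve"))
  idx <- match(as.integer(ages), curve$age)
  if (anyNA(idx)) {
    stop(sprintf("survivorship curve not defined at age %d",
                 as.integer(ages)[which(is.na(idx))[1L]]))
  }
  curve$surv[idx]
}

#' Linear survivorship curve over ages 50-74
#'
#' Parametric curve `F(a) = f50 * (1 - (1 - ratio_74) * (a - 50) / 24)`:
#' `F(50) = f50` (the neoplasia-free fraction at age 50) and
#' `F(74) = f50 * ratio_74`. A linear decline in the lesion-free population is
#' the simplest shape consistent with the published anchor values, and the
#' cumFP results are anchored to it by calibration (see [fit_scale_f50()]).
#'
#' @param f50 Fraction of 50-year-olds alive and neoplasia-free, in `(0, 1]`.
#' @param ratio_74 Target ratio `F(74)/F(50)`, in `(0, 1]`.
#' @return A [survivorship_curve()] over ages 50 to 74.
#' @examples
#' linear_survivorship(0.8374, 0.54)
#' @export
linear_survivorship <- function(f50, ratio_74) {
  if (!is.finite(f50) || f50 <= 0 || f50 > 1) stop("`f50` must be in (0, 1]")
  if (!is.finite(ratio_74) || ratio_74 <= 0 || ratio_74 > 1) {
    stop("`ratio_74` must be in (0, 1]")
  }
  ages <- 50:74
  survivorship_curve(ages, f50 * (1 - (1 - ratio_74) * (ages - 50) / 24))
}

#' Fit the survivorship scale f50 to a published cumFP anchor
#'
#' At fixed shape (fixed `ratio_74`), the closed-form cumFP of any scenario is
#' proportional to `f50`. The scale is therefore identified by a single
#' printed cumFP value: compute the unit-scale cumFP `U` (the closed form on
#' the linear curve with `f50 = 1`) and set `f50 = (anchor_value / 100000) / U`.
#'
#' @param ratio_74 Shape parameter `F(74)/F(50)`.
#' @param anchor_scenario A base-case (no-dependence) [screening_scenario()]
#'   whose published age-74 cumFP anchors the scale.
#' @param anchor_value Published age-74 cumFP for that scenario, per 100,000
#'   persons alive at age 50, in `(0, 100000)`.
#' @return The fitted `f50` (scalar fraction).
#' @examples
#' fit_scale_f50(0.54, screening_scenario(50, 74, 2, 0.98), 15102)
#' @export
fit_scale_f50 <- function(ratio_74, anchor_scenario, anchor_value) {
  stopifnot(inherits(anchor_scenario, "screening_scenario"))
  if (anchor_scenario$dependence_reduction != 0) {
    stop("anchor scenario must assume conditional independence (delta = 0)")
  }
  if (!is.finite(anchor_value) || anchor_value <= 0 || anchor_value >= 1e5) {
    stop("`anchor_value` must lie in (0, 100000)")
  }
  unit <- linear_survivorship(1, ratio_74)
  series <- cumfp_closed_form(unit, anchor_scenario)
  U <- series$cumfp[series$age == max(series$age)] / 1e5
  if (U <= 0) stop("anchor scenario has no screening rounds in range (U = 0)")
  f50 <- (anchor_value / 1e5) / U
  if (f50 > 1 + 1e-9) {
    stop(sprintf("anchor value %g requires f50 = %.4f > 1; shape and anchor inconsistent",
                 anchor_value, f50))
  }
  min(f50, 1)
}

#' Calibrate the linear survivorship curve to published anchors
#'
#' Convenience wrapper: fits `f50` with [fit_scale_f50()] and returns the
#' calibrated [linear_survivorship()] curve. The defaults are the model's
#' canonical calibration: `F(74)/F(50) = 0.54` (about 54% of lesion-free
#' 50-year-olds still lesion-free at 74) with the biennial / specificity-0.98
#' / start-50 scenario anchored at an age-74 cumFP of 15,102 per 100,000.
#'
#' @inheritParams fit_scale_f50
#' @return A calibrated [survivorship_curve()]; the fitted scale is in
#'   `attr(x, "f50")`.
#' @examples
#' curve <- calibrate_survivorship()
#' attr(curve, "f50")  # about 0.837
#' @export
calibrate_survivorship <- function(ratio_74 = 0.54,
                                   anchor_scenario = screening_scenario(50, 74, 2, 0.98),
                                   anchor_value = 15102) {
  f50 <- fit_scale_f50(ratio_74, anchor_scenario, anchor_value)
  linear_survivorship(f50, ratio_74)
}

#' Derive an incidence schedule reproducing a target survivorship
#'
#' Inverts the cohort engine's exit dynamics: given mortality `q(a)` and a
#' target free-survivorship `F`, the annual neoplasia incidence
#' `i(a) = 1 - (F(a+1)/F(a)) / (1 - q(a))` makes the engine's free-state
#' occupancy track `F` exactly. Values within `tol` below 0 or above 1 are
#' clipped (floating-point guard); larger violations indicate that mortality
#' alone already exceeds the attrition `F` requires, and are an error.
#'
#' @param curve Target [survivorship_curve()].
#' @param mortality A mortality [annual_schedule()] covering the curve's ages.
#' @param tol Clipping tolerance for derived probabilities.
#' @return An incidence [annual_schedule()] over the curve ages except the last.
#' @export
derive_incidence_from_survivorship <- function(curve, mortality, tol = 1e-9) {
  stopifnot(inherits(curve, "survivorship_curve"))
  n <- nrow(curve)
  if (n < 2L) stop("curve must cover at least two ages")
  ages <- curve$age[-n]
  q <- schedule_prob(mortality, ages)
  ratio <- curve$surv[-1L] / curve$surv[-n]
  if (any(q >= 1)) stop(sprintf("mortality is 1 at age %d; no survivors to derive incidence for",
                                ages[which(q >= 1)[1L]]))
  i <- 1 - ratio / (1 - q)
  bad <- which(i < -tol | i > 1 + tol)
  if (length(bad)) {
    stop(sprintf(paste0("cannot derive incidence at age %d: survival ratio %.6f ",
                        "incompatible with mortality %.6f"),
                 ages[bad[1L]], ratio[bad[1L]], q[bad[1L]]))
  }
  annual_schedule(ages, pmin(1, pmax(0, i)), "incidence")
}
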