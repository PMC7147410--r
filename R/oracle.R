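#' First-false-positive round weights
#'
#' Probability that a person who is still neoplasia-free at round `r` and has
#' never tested false-positive gets their first false positive at that round:
#' `w_r = p_r * prod_{j<r}(1 - p_j)`. In the base case (constant `p`) this is
#' the geometric `(1-s) * s^(r-1)`. The identity behind it: under the model a
#' person free at round `r` has attended and survived all earlier rounds
#' lesion-free, so their test history is a sequence of independent Bernoulli
#' trials with the per-round probabilities.
#'
#' @param fp_probs Per-round false-positive probabilities `p_r`.
#' @return Numeric vector `w_r`, same length; `sum(w) <= 1`.
#' @export
first_fp_round_weights <- function(fp_probs) {
  if (any(fp_probs < 0 | fp_probs > 1)) stop("probabilities must be in [0, 1]")
  fp_probs * cumprod(c(1, 1 - fp_probs))[seq_along(fp_probs)]
}

#' Closed-form cumulative false-positive series
#'
#' Analytic counterpart of the cohort engine: the cumFP at age `a` per
#' 100,000 persons alive at age 50 is the survivorship-weighted sum over all
#' screening rounds held by then,
#' `cumFP(a) = 100000 * sum_{r: a_r <= a} F(a_r) * w_r`,
#' with `F` the alive-and-neoplasia-free survivorship and `w_r` the
#' first-FP weights of [first_fp_round_weights()]. Exact (not approximate)
#' under the engine's screening-before-transitions cycle order; used as the
#' engine's independent test oracle and for calibration.
#'
#' @param curve A [survivorship_curve()] defined at every screening age.
#' @param scenario A [screening_scenario()].
#' @return A `cumfp_series` data frame over the curve's ages (denominator:
#'   all persons alive at 50).
#' @examples
#' cf <- cumfp_closed_form(calibrate_survivorship(),
#'                         screening_scenario(50, 74, 2, 0.98))
#' tail(cf, 1)  # 15102 at age 74 by construction
#' @export
cumfp_closed_form <- function(curve, scenario) {
  stopifnot(inherits(curve, "survivorship_curve"),
            inherits(scenario, "screening_scenario"))
  screen_ages <- build_screening_ages(scenario)
  w <- first_fp_round_weights(per_round_fp_probabilities(scenario))
  contrib <- survivorship_at(curve, screen_ages) * w
  ages <- curve$age[curve$age >= scenario$start_age & curve$age <= scenario$stop_age]
  vals <- vapply(ages, function(a) 1e5 * sum(contrib[screen_ages <= a]), numeric(1))
  structure(
    data.frame(age = ages, cumfp = vals),
    denominator = "all_at_50",
    class = c("cumfp_series", "data.frame")
  )
}

#' Survivorship curve implied by mortality and incidence schedules
#'
#' Forward recursion `F(a+1) = F(a) * (1 - i(a)) * (1 - q(a))` starting from
#' `F(start) = 1 - prevalence_at_start`; equals the engine's free-state
#' occupancy (per person alive at the start age) at every screening instant.
#'
#' @param mortality Mortality [annual_schedule()].
#' @param incidence Incidence [annual_schedule()].
#' @param prevalence_at_start Neoplasia prevalence at the first age.
#' @param ages Integer ages to cover (default 50:74); schedules must cover
#'   all but the last.
#' @return A [survivorship_curve()].
#' @export
survivorship_from_schedules <- function(mortality, incidence,
                                        prevalence_at_start = 0, ages = 50:74) {
  ages <- as.integer(ages)
  q <- schedule_prob(mortality, ages[-length(ages)])
  i <- schedule_prob(incidence, ages[-length(ages)])
  surv <- cumprod(c(1 - prevalence_at_start, (1 - i) * (1 - q)))
  survivorship_curve(ages, surv)
}

#' Invert a cumFP series to the survivorship at screening ages
#'
#' Algebraic inverse of [cumfp_closed_form()]: the increment of cumFP across
#' round `r` identifies `F(a_r) = (cumFP(a_r) - cumFP(a_{r-1})) / (100000 * w_r)`.
#' Defined only at screening ages (no interpolation); enables calibration
#' directly from a published cumFP column.
#'
#' @param series A `cumfp_series` (per 100,000 alive at 50) sampled at least
#'   at every screening age.
#' @param scenario The [screening_scenario()] that produced the series
#'   (`delta` must be known).
#' @return A data frame with columns `age` (the screening ages) and `surv`.
#' @export
invert_cumfp_to_survivorship <- function(series, scenario) {
  stopifnot(inherits(series, "cumfp_series"), inherits(scenario, "screening_scenario"))
  if (is.unsorted(series$age)) stop("series ages must be increasing")
  if (any(diff(series$cumfp) < -1e-9)) stop("cumFP series must be non-decreasing")
  screen_ages <- build_screening_ages(scenario)
  idx <- match(screen_ages, series$age)
  if (anyNA(idx)) {
    stop(sprintf("series is missing screening age %d", screen_ages[which(is.na(idx))[1L]]))
  }
  w <- first_fp_round_weights(per_round_fp_probabilities(scenario))
  if (any(w == 0)) stop("zero first-FP weight; survivorship not identifiable at that round")
  at_rounds <- series$cumfp[idx]
  increments <- diff(c(0, at_rounds))
  data.frame(age = screen_ages, surv = increments / (1e5 * w))
}
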