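#' Define a screening scenario
#'
#' A scenario fixes the screening schedule (start age, stop age, interval),
#' the per-test specificity `s`, and the conditional-dependence reduction
#' `delta`: an absolute (percentage-point) drop in the false-positive
#' probability applied from the second round onward, among persons whose
#' prior tests were all true negatives. `delta = 0` is the base case
#' (conditional independence of sequential testing); `delta = 0.01` is the
#' standard sensitivity variant.
#'
#' @param start_age First screening age (integer years).
#' @param stop_age Last eligible screening age (integer years, default 74).
#' @param interval Years between rounds (integer >= 1).
#' @param specificity Per-test specificity `s` in `(0, 1]`; the per-round
#'   false-positive probability is `1 - s`.
#' @param dependence_reduction Absolute reduction `delta >= 0` of the
#'   false-positive probability from round 2 on; must satisfy
#'   `1 - s - delta >= 0`.
#' @param label Scenario label used as a table column name; auto-generated
#'   when `NULL`.
#' @return A list of class `screening_scenario`.
#' @examples
#' screening_scenario(50, 74, 2, 0.98)
#' screening_scenario(50, 74, 1, 0.98, dependence_reduction = 0.01)
#' @export
screening_scenario <- function(start_age, stop_age = 74, interval, specificity,
                               dependence_reduction = 0, label = NULL) {
  start_age <- as.integer(start_age); stop_age <- as.integer(stop_age)
  interval <- as.integer(interval)
  if (start_age > stop_age) stop("`start_age` must not exceed `stop_age`")
  if (interval < 1L) stop("`interval` must be >= 1 year")
  if (!is.finite(specificity) || specificity <= 0 || specificity > 1) {
    stop("`specificity` must be in (0, 1]")
  }
  if (!is.finite(dependence_reduction) || dependence_reduction < 0) {
    stop("`dependence_reduction` must be >= 0")
  }
  if (1 - specificity - dependence_reduction < 0) {
    stop("`dependence_reduction` exceeds the false-positive probability 1 - specificity")
  }
  if (is.null(label)) {
    label <- sprintf("start%d_int%d_spec%g", start_age, interval, 100 * specificity)
    if (dependence_reduction > 0) {
      label <- paste0(label, sprintf("_dep%g", 100 * dependence_reduction))
    }
  }
  structure(
    list(start_age = start_age, stop_age = stop_age, interval = interval,
         specificity = specificity, dependence_reduction = dependence_reduction,
         label = label),
    class = "screening_scenario"
  )
}

#' @export
print.screening_scenario <- function(x, ...) {
  cat(sprintf("screening scenario '%s': ages %d-%d every %d yr, specificity %.3g%s\n",
              x$label, x$start_age, x$stop_age, x$interval, x$specificity,
              if (x$dependence_reduction > 0) {
                sprintf(", FP prob -%g pp after a true negative", 100 * x$dependence_reduction)
              } else ""))
  invisible(x)
}

#' Screening ages of a scenario
#'
#' Rounds run from `start_age` in steps of `interval`; both endpoints are
#' test-eligible, so the last round is the largest age on the grid that does
#' not exceed `stop_age`.
#'
#' @param scenario A [screening_scenario()].
#' @return Integer vector of screening ages.
#' @examples
#' build_screening_ages(screening_scenario(50, 74, 3, 0.98))  # 50,53,...,74
#' @export
build_screening_ages <- function(scenario) {
  stopifnot(inherits(scenario, "screening_scenario"))
  seq.int(scenario$start_age, scenario$stop_age, by = scenario$interval)
}

#' Per-round false-positive probabilities
#'
#' Round 1 has FP probability `1 - s`; under the dependence variant every
#' later round has `1 - s - delta`. With perfect adherence, a neoplasia-free
#' person with no prior false positive has exactly `r - 1` prior true
#' negatives at round `r`, so "one or more prior true negatives" is
#' equivalent to "round index >= 2" for the population at risk of a first FP.
#'
#' @param scenario A [screening_scenario()].
#' @param n_rounds Number of rounds (defaults to the scenario's own count).
#' @return Numeric vector `p_r` of length `n_rounds`.
#' @examples
#' per_round_fp_probabilities(screening_scenario(50, 74, 2, 0.98,
#'                                               dependence_reduction = 0.01))
#' @export
per_round_fp_probabilities <- function(scenario,
                                       n_rounds = length(build_screening_ages(scenario))) {
  stopifnot(inherits(scenario, "screening_scenario"), n_rounds >= 1)
  p1 <- 1 - scenario$specificity
  pr <- 1 - scenario$specificity - scenario$dependence_reduction
  c(p1, rep(pr, n_rounds - 1L))
}

#' The 11-scenario study catalogue
#'
#' The standard scenario grid: all combinations of screening interval
#' (1, 2, 3 years) and specificity (0.98, 0.95, 0.92) starting at age 50,
#' plus starting ages 54 and 58 at the 2-year interval with specificity 0.98
#' — 11 base-case scenarios, all stopping at age 74. With
#' `sensitivity = TRUE` the catalogue instead holds each scenario's
#' conditional-dependence twin (`delta = 0.01`).
#'
#' @param sensitivity Return the `delta = 0.01` twins instead of the base case.
#' @return A named list of [screening_scenario()] objects (names = labels).
#' @examples
#' length(scenario_catalogue())  # 11
#' @export
scenario_catalogue <- function(sensitivity = FALSE) {
  delta <- if (sensitivity) 0.01 else 0
  grid <- expand.grid(interval = c(1L, 2L, 3L), spec = c(0.98, 0.95, 0.92),
                      KEEP.OUT.ATTRS = FALSE)
  scens <- c(
    lapply(seq_len(nrow(grid)), function(k) {
      screening_scenario(50, 74, grid$interval[k], grid$spec[k],
                         dependence_reduction = delta)
    }),
    list(
      screening_scenario(54, 74, 2, 0.98, dependence_reduction = delta),
      screening_scenario(58, 74, 2, 0.98, dependence_reduction = delta)
    )
  )
  names(scens) <- vapply(scens, `[[`, character(1), "label")
  scens
}
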