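#' @title Annual-cycle Markov cohort engine
#' @description Five-state deterministic cohort model: alive and
#' neoplasia-free without / with a prior false positive (`free_no_fp`,
#' `free_fp`), alive with neoplasia without / with a prior false positive
#' (`neo_no_fp`, `neo_fp`), and `dead`. `cum_fp` counts persons who ever
#' received a false-positive result; it is never decremented by later
#' neoplasia onset or death.
#' @name engine
NULL

STATE_NAMES <- c("free_no_fp", "free_fp", "neo_no_fp", "neo_fp", "dead", "cum_fp")

#' Initial state of the screening cohort
#'
#' @param cohort_size Number of persons alive at the start age.
#' @param prevalence_at_start Fraction of the cohort already carrying
#'   colorectal neoplasia at the start age, in `[0, 1]`.
#' @return Named numeric state vector (`free_no_fp`, `free_fp`, `neo_no_fp`,
#'   `neo_fp`, `dead`, `cum_fp`).
#' @examples
#' initial_state(100000, 0.1626)
#' @export
initial_state <- function(cohort_size, prevalence_at_start = 0) {
  if (!is.finite(cohort_size) || cohort_size < 0) stop("`cohort_size` must be >= 0")
  if (!is.finite(prevalence_at_start) || prevalence_at_start < 0 || prevalence_at_start > 1) {
    stop("`prevalence_at_start` must be in [0, 1]")
  }
  stats::setNames(
    c(cohort_size * (1 - prevalence_at_start), 0,
      cohort_size * prevalence_at_start, 0, 0, 0),
    STATE_NAMES
  )
}

#' Apply one screening round to a state vector
#'
#' Only persons alive, neoplasia-free and without a prior false positive can
#' generate a (first) false positive; a fraction `fp_prob` of `free_no_fp`
#' moves to `free_fp` and is added to `cum_fp`. All other states are
#' untouched, so nobody is counted twice.
#'
#' @param state Named state vector as from [initial_state()].
#' @param fp_prob Per-round false-positive probability in `[0, 1]`.
#' @return Updated state vector.
#' @export
apply_screening <- function(state, fp_prob) {
  if (!is.finite(fp_prob) || fp_prob < 0 || fp_prob > 1) {
    stop("`fp_prob` must be in [0, 1]")
  }
  new_fp <- state[["free_no_fp"]] * fp_prob
  state[["free_no_fp"]] <- state[["free_no_fp"]] - new_fp
  state[["free_fp"]] <- state[["free_fp"]] + new_fp
  state[["cum_fp"]] <- state[["cum_fp"]] + new_fp
  state
}

#' Apply one year of neoplasia incidence and death
#'
#' Within-cycle order: incidence first (each free state loses fraction `i_a`
#' to the matching neoplasia state, preserving the false-positive flag), then
#' all-cause death (every alive state loses fraction `q_a` to `dead`).
#' `cum_fp` is unchanged: first-FP events persist through neoplasia onset
#' and death.
#'
#' @param state Named state vector.
#' @param i_a Annual neoplasia incidence probability in `[0, 1]`.
#' @param q_a Annual death probability in `[0, 1]`.
#' @return Updated state vector.
#' @export
apply_transitions <- function(state, i_a, q_a) {
  if (!is.finite(i_a) || i_a < 0 || i_a > 1) stop("`i_a` must be in [0, 1]")
  if (!is.finite(q_a) || q_a < 0 || q_a > 1) stop("`q_a` must be in [0, 1]")
  onset_no_fp <- state[["free_no_fp"]] * i_a
  onset_fp <- state[["free_fp"]] * i_a
  state[["free_no_fp"]] <- state[["free_no_fp"]] - onset_no_fp
  state[["free_fp"]] <- state[["free_fp"]] - onset_fp
  state[["neo_no_fp"]] <- state[["neo_no_fp"]] + onset_no_fp
  state[["neo_fp"]] <- state[["neo_fp"]] + onset_fp
  alive <- c("free_no_fp", "free_fp", "neo_no_fp", "neo_fp")
  deaths <- sum(state[alive]) * q_a
  state[alive] <- state[alive] * (1 - q_a)
  state[["dead"]] <- state[["dead"]] + deaths
  state
}

#' Run the cohort model under a screening scenario
#'
#' Evolves the cohort one annual cycle at a time from the scenario's start
#' age to its stop age. At each age: if the age is a screening age, the
#' round's false-positive probability (first round `1 - s`, later rounds
#' `1 - s - delta`) is applied first; then one year of neoplasia incidence
#' and death. The trajectory records the post-screening, pre-transition
#' state at every age.
#'
#' @param mortality Mortality [annual_schedule()] covering
#'   `[start_age, stop_age]`.
#' @param incidence Incidence [annual_schedule()] covering the same range.
#' @param scenario A [screening_scenario()].
#' @param cohort_size Cohort size at the start age (default 100,000).
#' @param prevalence_at_start Neoplasia prevalence at the start age.
#' @param run_from First simulated age (default: the scenario's start age).
#'   May be earlier than the first screening round, e.g. to run every
#'   scenario of a catalogue from age 50 against a common reference cohort.
#' @return A data frame of class `cohort_trajectory` with one row per age
#'   (columns `age`, the five states and `cum_fp`); cohort size, prevalence
#'   and the scenario are carried in attributes.
#' @examples
#' curve <- calibrate_survivorship()
#' mort <- make_gompertz_mortality()
#' inc <- derive_incidence_from_survivorship(curve, mort)
#' traj <- run_cohort(mort, inc, screening_scenario(50, 74, 2, 0.98),
#'                    prevalence_at_start = 1 - attr(curve, "f50"))
#' tail(traj, 1)
#' @export
run_cohort <- function(mortality, incidence, scenario,
                       cohort_size = 1e5, prevalence_at_start = 0,
                       run_from = scenario$start_age) {
  stopifnot(inherits(scenario, "screening_scenario"))
  if (run_from > scenario$start_age) stop("`run_from` must not exceed the scenario start age")
  ages <- seq.int(run_from, scenario$stop_age)
  # transitions are applied at every age except the last recorded one
  q <- schedule_prob(mortality, ages[-length(ages)])
  i <- schedule_prob(incidence, ages[-length(ages)])
  screen_ages <- build_screening_ages(scenario)
  fp_probs <- per_round_fp_probabilities(scenario)

  state <- initial_state(cohort_size, prevalence_at_start)
  out <- matrix(NA_real_, nrow = length(ages), ncol = length(STATE_NAMES),
                dimnames = list(NULL, STATE_NAMES))
  for (k in seq_along(ages)) {
    r <- match(ages[k], screen_ages)
    if (!is.na(r)) state <- apply_screening(state, fp_probs[r])
    out[k, ] <- state
    if (k < length(ages)) state <- apply_transitions(state, i[k], q[k])
  }
  structure(
    cbind(data.frame(age = ages), as.data.frame(out)),
    cohort_size = cohort_size,
    prevalence_at_start = prevalence_at_start,
    scenario = scenario,
    class = c("cohort_trajectory", "data.frame")
  )
}

#' Cumulative false-positive series from a trajectory
#'
#' Rescales the trajectory's `cum_fp` counter to "per 100,000" under the
#' chosen reference population: all persons alive at the start age
#' (`"all_at_50"`) or only those neoplasia-free at the start age
#' (`"free_at_50"`).
#'
#' @param traj A `cohort_trajectory` from [run_cohort()].
#' @param denominator `"all_at_50"` or `"free_at_50"`.
#' @return A data frame of class `cumfp_series` with columns `age`, `cumfp`.
#' @export
cumfp_series <- function(traj, denominator = c("all_at_50", "free_at_50")) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  denominator <- match.arg(denominator)
  size <- attr(traj, "cohort_size")
  D <- switch(denominator,
              all_at_50 = size,
              free_at_50 = size * (1 - attr(traj, "prevalence_at_start")))
  if (D <= 0) stop("reference population is empty")
  structure(
    data.frame(age = traj$age, cumfp = 1e5 * traj$cum_fp / D),
    denominator = denominator,
    class = c("cumfp_series", "data.frame")
  )
}
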