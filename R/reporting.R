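#' Round half-up to integers
#'
#' Reporting-time rounding for "per 100,000" cells (0.5 always rounds up,
#' unlike base [round()]'s round-half-even). Internal math is never rounded.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Cumulative false-positive table over a scenario set
#'
#' Runs the cohort engine for each scenario on schedules consistent with the
#' given survivorship curve and assembles the cumFP-by-age table (rows: ages
#' 50-74; one column per scenario label). All runs start the cohort at age 50
#' with neoplasia prevalence `1 - f50`, so later-starting scenarios share the
#' same reference population.
#'
#' @param curve A [survivorship_curve()] over ages 50-74 (typically from
#'   [calibrate_survivorship()]).
#' @param scenarios List of [screening_scenario()] objects (default: the
#'   11-scenario catalogue).
#' @param mortality Mortality [annual_schedule()]; the incidence schedule is
#'   derived from it and the curve, and the resulting table is invariant to
#'   how attrition is split between the two.
#' @param denominator `"all_at_50"` or `"free_at_50"`.
#' @return Data frame with column `age` and one unrounded cumFP column per
#'   scenario, in catalogue order.
#' @examples
#' tab <- cumfp_table(calibrate_survivorship())
#' tab[tab$age == 74, "start50_int2_spec98"]  # 15102
#' @export
cumfp_table <- function(curve, scenarios = scenario_catalogue(),
                        mortality = make_gompertz_mortality(),
                        denominator = c("all_at_50", "free_at_50")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(curve, "survivorship_curve"))
  f50 <- attr(curve, "f50")
  incidence <- derive_incidence_from_survivorship(curve, mortality)
  cols <- lapply(scenarios, function(sc) {
    traj <- run_cohort(mortality, incidence, sc,
                       cohort_size = 1e5, prevalence_at_start = 1 - f50,
                       run_from = min(curve$age))
    cumfp_series(traj, denominator)$cumfp
  })
  out <- cbind(data.frame(age = curve$age), as.data.frame(cols, check.names = FALSE))
  names(out) <- c("age", vapply(scenarios, `[[`, character(1), "label"))
  out
}

#' Reproduce the study's result tables
#'
#' Calibrates the linear survivorship curve to the published anchors and
#' produces the three headline tables: the base-case cumFP per 100,000
#' 50-year-olds for all 11 scenarios, its conditional-dependence sensitivity
#' twin (`delta = 0.01`), and the base case re-expressed per 100,000 persons
#' neoplasia-free at age 50. Cells are rounded half-up to integers only when
#' written to disk.
#'
#' @inheritParams calibrate_survivorship
#' @param mortality Mortality [annual_schedule()] used for the engine runs.
#' @param out_dir If non-`NULL`, writes `table_base.csv`,
#'   `table_sensitivity.csv` and `table_free50.csv` there (created if needed).
#' @param verbose Print the calibrated scale and per-scenario age-74 values.
#' @return List with elements `f50`, `curve`, `base`, `sensitivity`,
#'   `free50` (tables unrounded).
#' @export
reproduce_cumfp_tables <- function(ratio_74 = 0.54,
                                   anchor_scenario = screening_scenario(50, 74, 2, 0.98),
                                   anchor_value = 15102,
                                   mortality = make_gompertz_mortality(),
                                   out_dir = NULL, verbose = FALSE) {
  curve <- calibrate_survivorship(ratio_74, anchor_scenario, anchor_value)
  f50 <- attr(curve, "f50")
  base <- cumfp_table(curve, scenario_catalogue(), mortality, "all_at_50")
  sens <- cumfp_table(curve, scenario_catalogue(sensitivity = TRUE), mortality, "all_at_50")
  free50 <- cumfp_table(curve, scenario_catalogue(), mortality, "free_at_50")
  if (verbose) {
    message(sprintf("calibrated f50 = %.6f (ratio_74 = %g, anchor %g)",
                    f50, ratio_74, anchor_value))
    at74 <- round_half_up(unlist(base[base$age == 74, -1]))
    message(paste(sprintf("  %s: %d", names(at74), at74), collapse = "\n"))
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_result_table(base, file.path(out_dir, "table_base.csv"))
    write_result_table(sens, file.path(out_dir, "table_sensitivity.csv"))
    write_result_table(free50, file.path(out_dir, "table_free50.csv"))
  }
  list(f50 = f50, curve = curve, base = base, sensitivity = sens, free50 = free50)
}

#' Write / read a cumFP result table
#'
#' Cells are rounded half-up to integers per 100,000 at serialization time;
#' the `age` column is written as-is. The written file reads back losslessly.
#'
#' @param table A table from [cumfp_table()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the table (reader).
#' @export
write_result_table <- function(table, path) {
  out <- table
  out[-1] <- lapply(out[-1], round_half_up)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Percent differences between scenarios at age 74
#'
#' For each ordered pair of scenario labels `(A, B)` reports
#' `100 * (A - B) / B` at the table's final age.
#'
#' @param table A table from [cumfp_table()].
#' @param pairs List of character pairs `c(label_A, label_B)`.
#' @return Data frame with columns `scenario`, `baseline`, `pct_diff`.
#' @examples
#' tab <- cumfp_table(calibrate_survivorship())
#' compare_scenarios(tab, list(c("start50_int1_spec98", "start50_int2_spec98")))
#' @export
compare_scenarios <- function(table, pairs) {
  last <- table[which.max(table$age), , drop = FALSE]
  res <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(table))) {
      stop(sprintf("unknown scenario label '%s'", setdiff(pr, names(table))[1L]))
    }
    a <- last[[pr[1L]]]; b <- last[[pr[2L]]]
    if (b == 0) stop(sprintf("zero baseline for '%s'", pr[2L]))
    data.frame(scenario = pr[1L], baseline = pr[2L], pct_diff = 100 * (a - b) / b)
  })
  do.call(rbind, res)
}

#' External-consistency check against the Zorzi et al. FIT programme
#'
#' The north-eastern-Italy FIT programme reported, for persons aged 50-54 at
#' entry, about 91-98 per 1000 neoplasia-free regular attenders with at least
#' one positive test over five biennial rounds. This check computes the
#' model's closed-form analogue: cumFP over five biennial rounds starting at
#' age 52 (midpoint of the entry range) at specificity 0.975, per 1000 of
#' the age-50 cohort.
#'
#' @param curve A calibrated [survivorship_curve()] covering ages 52-60.
#' @param specificity Per-test specificity (default 0.975).
#' @param start_age First round age (default 52).
#' @param interval Years between rounds (default 2).
#' @param n_rounds Number of rounds (default 5).
#' @return Scalar cumFP per 1000.
#' @examples
#' zorzi_check(calibrate_survivorship())  # about 88 per 1000
#' @export
zorzi_check <- function(curve, specificity = 0.975, start_age = 52,
                        interval = 2, n_rounds = 5) {
  stop_age <- start_age + interval * (n_rounds - 1L)
  sc <- screening_scenario(start_age, stop_age, interval, specificity,
                           label = "external_check")
  series <- cumfp_closed_form(curve, sc)
  series$cumfp[which.max(series$age)] / 100  # per 100,000 -> per 1000
}
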