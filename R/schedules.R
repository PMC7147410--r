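#' Age-indexed annual probability schedules
#'
#' A schedule maps consecutive integer ages to annual transition
#' probabilities: either the probability of death within the year
#' (`type = "mortality"`) or the probability that a neoplasia-free person
#' develops colorectal neoplasia within the year (`type = "incidence"`).
#'
#' @param ages Integer vector of consecutive ages (years).
#' @param probability Numeric vector of annual probabilities in `[0, 1]`,
#'   one per age.
#' @param type Either `"mortality"` or `"incidence"`.
#'
#' @return A data frame with columns `age` and `probability`, of class
#'   `annual_schedule`, with the schedule type stored in
#'   `attr(x, "schedule_type")`.
#' @examples
#' annual_schedule(50:74, rep(0.01, 25), "mortality")
#' @export
annual_schedule <- function(ages, probability, type = c("mortality", "incidence")) {
  type <- match.arg(type)
  ages <- as.integer(ages)
  if (length(ages) == 0L) stop("schedule must cover at least one age")
  if (length(ages) != length(probability)) {
    stop("`ages` and `probability` must have the same length")
  }
  if (anyNA(ages) || anyNA(probability) || !all(is.finite(probability))) {
    stop("schedule contains missing or non-finite values")
  }
  if (length(ages) > 1L && !all(diff(ages) == 1L)) {
    stop("non-consecutive ages in schedule")
  }
  bad <- which(probability < 0 | probability > 1)
  if (length(bad)) {
    stop(sprintf("probability out of [0,1] at age %d (value %g)",
                 ages[bad[1L]], probability[bad[1L]]))
  }
  structure(
    data.frame(age = ages, probability = as.numeric(probability)),
    schedule_type = type,
    class = c("annual_schedule", "data.frame")
  )
}

#' Look up schedule probabilities at given ages
#'
#' @param schedule An [annual_schedule()].
#' @param ages Integer ages, all of which must be covered by the schedule.
#' @return Numeric vector of probabilities, one per requested age.
#' @export
schedule_prob <- function(schedule, ages) {
  stopifnot(inherits(schedule, "annual_schedule"))
  idx <- match(as.integer(ages), schedule$age)
  if (anyNA(idx)) {
    stop(sprintf("schedule does not cover age %d",
                 as.integer(ages)[which(is.na(idx))[1L]]))
  }
  schedule$probability[idx]
}

#' Synthetic Gompertz all-cause mortality schedule
#'
#' Generates an adult mortality schedule of Gompertz form
#' `q(a) = min(1, a_coeff * exp(b_coeff * a))`, a standard stand-in for a
#' national life table over the screening age range.
#'
#' The defaults (`a_coeff = 3e-5`, `b_coeff = 0.09`) give annual death
#' probabilities of about 0.0027 at age 50 and 0.023 at age 74, typical of a
#' contemporary Western-European population.
#'
#' @param a_coeff Baseline hazard scale (> 0).
#' @param b_coeff Exponential age slope per year (>= 0).
#' @param ages Integer ages to cover.
#' @return A mortality [annual_schedule()].
#' @examples
#' make_gompertz_mortality()
#' @export
make_gompertz_mortality <- function(a_coeff = 3e-5, b_coeff = 0.09, ages = 50:75) {
  if (!is.finite(a_coeff) || a_coeff <= 0) stop("`a_coeff` must be > 0")
  if (!is.finite(b_coeff) || b_coeff < 0) stop("`b_coeff` must be >= 0")
  q <- pmin(1, a_coeff * exp(b_coeff * as.numeric(ages)))
  annual_schedule(ages, q, "mortality")
}

#' Read an age/probability schedule from CSV
#'
#' Expects a two-column UTF-8 CSV with header `age,probability`, integer
#' consecutive ages, and probabilities in `[0, 1]`. No interpolation is
#' performed: a gap in the ages is an error, so data problems surface rather
#' than being hidden.
#'
#' @param path Path to the CSV file.
#' @param type Schedule type, `"mortality"` or `"incidence"`.
#' @return An [annual_schedule()].
#' @seealso [write_schedule_csv()]
#' @export
read_schedule_csv <- function(path, type = c("mortality", "incidence")) {
  type <- match.arg(type)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!identical(names(raw), c("age", "probability"))) {
    stop(sprintf("expected header 'age,probability' in %s, got '%s'",
                 path, paste(names(raw), collapse = ",")))
  }
  age_num <- suppressWarnings(as.numeric(raw$age))
  prob_num <- suppressWarnings(as.numeric(raw$probability))
  # data lines start at 2 (line 1 is the header)
  bad <- which(is.na(age_num) | age_num != round(age_num))
  if (length(bad)) stop(sprintf("non-integer age at line %d of %s", bad[1L] + 1L, path))
  bad <- which(is.na(prob_num))
  if (length(bad)) stop(sprintf("non-numeric probability at line %d of %s", bad[1L] + 1L, path))
  bad <- which(prob_num < 0 | prob_num > 1)
  if (length(bad)) {
    stop(sprintf("probability %s out of [0,1] at line %d of %s",
                 raw$probability[bad[1L]], bad[1L] + 1L, path))
  }
  if (length(age_num) > 1L && !all(diff(age_num) == 1)) {
    gap <- which(diff(age_num) != 1)[1L]
    stop(sprintf("non-consecutive ages at line %d of %s (age %d follows %d)",
                 gap + 2L, path, as.integer(age_num[gap + 1L]), as.integer(age_num[gap])))
  }
  annual_schedule(age_num, prob_num, type)
}

#' Write a schedule to CSV
#'
#' Inverse of [read_schedule_csv()]; the round trip is lossless (probabilities
#' are written with full precision).
#'
#' @param schedule An [annual_schedule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "annual_schedule"))
  df <- data.frame(age = schedule$age,
                   probability = format(schedule$probability, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
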