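# Shared fixtures: random-but-reproducible schedules and scenarios for
# property-style tests.

random_schedules <- function(ages = 50:75, max_i = 0.08, max_q = 0.05) {
  n <- length(ages)
  list(
    incidence = annual_schedule(ages, runif(n, 0, max_i), "incidence"),
    mortality = annual_schedule(ages, runif(n, 0, max_q), "mortality")
  )
}

random_scenario <- function() {
  s <- sample(c(0.98, 0.95, 0.92, 0.9), 1)
  delta <- sample(c(0, 0.01, 0.02), 1)
  screening_scenario(
    start_age = sample(50:60, 1),
    stop_age = 74,
    interval = sample(1:4, 1),
    specificity = s,
    dependence_reduction = min(delta, 1 - s)
  )
}

# cumFP at the trajectory end per person alive at the run start
engine_cumfp_at <- function(traj, age) {
  traj$cum_fp[traj$age == age] / attr(traj, "cohort_size")
}
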