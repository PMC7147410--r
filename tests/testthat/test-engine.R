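test_that("initial state splits the cohort by neoplasia prevalence", {
  s <- initial_state(100000, 0)
  expect_equal(s[["free_no_fp"]], 100000)
  expect_equal(sum(s[c("free_fp", "neo_no_fp", "neo_fp", "dead", "cum_fp")]), 0)

  s2 <- initial_state(100000, 0.1626)
  expect_equal(s2[["free_no_fp"]], 83740)
  expect_equal(s2[["neo_no_fp"]], 16260)
  expect_equal(sum(s2[c("free_no_fp", "free_fp", "neo_no_fp", "neo_fp", "dead")]),
               100000)
  expect_error(initial_state(-1), "cohort_size")
  expect_error(initial_state(10, 1.1), "prevalence")
})

test_that("screening moves first-FP mass out of free_no_fp and accumulates cum_fp", {
  s <- apply_screening(initial_state(100000, 0), 0.02)
  expect_equal(s[["free_fp"]], 2000)
  expect_equal(s[["cum_fp"]], 2000)
  expect_equal(s[["free_no_fp"]], 98000)

  expect_identical(apply_screening(s, 0), s)

  # two rounds: complement rule 1 - 0.98^2 of the original cohort
  s2 <- apply_screening(s, 0.02)
  expect_equal(s2[["cum_fp"]], 100000 * (1 - 0.98^2), tolerance = 1e-12)
})

test_that("annual transitions apply incidence then death, preserving the FP flag", {
  s <- initial_state(1000, 0)
  s <- apply_transitions(s, i_a = 0.02, q_a = 0)
  expect_equal(s[["neo_no_fp"]], 20)
  expect_equal(s[["free_no_fp"]], 980)

  s <- initial_state(1000, 0.5)
  s <- apply_transitions(s, i_a = 0, q_a = 0.01)
  expect_equal(s[["dead"]], 10)
  expect_equal(s[["cum_fp"]], 0)

  # i = 1 empties both free states into the matching neoplasia states
  s <- apply_screening(initial_state(1000, 0), 0.1)
  s <- apply_transitions(s, i_a = 1, q_a = 0)
  expect_equal(s[["free_no_fp"]] + s[["free_fp"]], 0)
  expect_equal(s[["neo_fp"]], 100)
  expect_equal(s[["cum_fp"]], 100)
})

test_that("with no attrition the cohort run reproduces the geometric complement", {
  ages <- 50:74
  zero_i <- annual_schedule(ages, rep(0, 25), "incidence")
  zero_q <- annual_schedule(ages, rep(0, 25), "mortality")
  sc <- screening_scenario(50, 74, 1, 0.98)
  traj <- run_cohort(zero_q, zero_i, sc)
  expect_equal(engine_cumfp_at(traj, 74), 1 - 0.98^25, tolerance = 1e-12)
})

test_that("cohort mass is conserved and cum_fp is monotone on random schedules", {
  set.seed(42)
  for (rep in 1:10) {
    sch <- random_schedules()
    sc <- random_scenario()
    traj <- run_cohort(sch$mortality, sch$incidence, sc,
                       cohort_size = 1e5, prevalence_at_start = runif(1, 0, 0.4))
    mass <- unname(rowSums(traj[c("free_no_fp", "free_fp", "neo_no_fp", "neo_fp", "dead")]))
    expect_equal(mass, rep(1e5, nrow(traj)), tolerance = 1e-9)
    expect_true(all(diff(traj$cum_fp) >= -1e-9))
    expect_true(all(traj$cum_fp >= traj$free_fp + traj$neo_fp - 1e-9))
    expect_true(all(as.matrix(traj[-1]) >= -1e-12))
  }
})

test_that("cumFP is monotone in frequency, FP probability, and start age", {
  curve <- calibrate_survivorship()
  tab <- cumfp_table(curve)
  # more frequent screening dominates at every age
  expect_true(all(tab$start50_int1_spec98 >= tab$start50_int2_spec98 - 1e-9))
  expect_true(all(tab$start50_int2_spec98 >= tab$start50_int3_spec98 - 1e-9))
  # lower specificity dominates
  expect_true(all(tab$start50_int2_spec92 >= tab$start50_int2_spec95 - 1e-9))
  expect_true(all(tab$start50_int2_spec95 >= tab$start50_int2_spec98 - 1e-9))
  # earlier start dominates at age 74
  at74 <- tab[tab$age == 74, ]
  expect_gt(at74$start50_int2_spec98, at74$start54_int2_spec98)
  expect_gt(at74$start54_int2_spec98, at74$start58_int2_spec98)
})

test_that("cumFP depends on the schedules only through the free-survival product", {
  set.seed(7)
  ages <- 50:75
  i <- runif(26, 0, 0.05)
  q <- runif(26, 0, 0.03)
  sc <- screening_scenario(50, 74, 2, 0.95, dependence_reduction = 0.01)
  split <- run_cohort(annual_schedule(ages, q, "mortality"),
                      annual_schedule(ages, i, "incidence"), sc)
  # same per-age product (1-i)(1-q), but all attrition booked as incidence
  all_inc <- 1 - (1 - i) * (1 - q)
  merged <- run_cohort(annual_schedule(ages, rep(0, 26), "mortality"),
                       annual_schedule(ages, all_inc, "incidence"), sc)
  expect_equal(split$cum_fp, merged$cum_fp, tolerance = 1e-12)
})

test_that("the dependence variant never exceeds the base case and collapses at delta = 0", {
  set.seed(11)
  sch <- random_schedules()
  base <- screening_scenario(50, 74, 2, 0.95)
  dep <- screening_scenario(50, 74, 2, 0.95, dependence_reduction = 0.02)
  t_base <- run_cohort(sch$mortality, sch$incidence, base)
  t_dep <- run_cohort(sch$mortality, sch$incidence, dep)
  expect_true(all(t_dep$cum_fp <= t_base$cum_fp + 1e-9))

  dep0 <- screening_scenario(50, 74, 2, 0.95, dependence_reduction = 0)
  t_dep0 <- run_cohort(sch$mortality, sch$incidence, dep0)
  expect_equal(t_dep0$cum_fp, t_base$cum_fp, tolerance = 0)
})

test_that("cumfp_series rescales to the requested reference population", {
  ages <- 50:74
  zero_i <- annual_schedule(ages, rep(0, 25), "incidence")
  zero_q <- annual_schedule(ages, rep(0, 25), "mortality")
  sc <- screening_scenario(50, 74, 2, 0.98)
  traj <- run_cohort(zero_q, zero_i, sc, cohort_size = 2e5, prevalence_at_start = 0.2)
  all50 <- cumfp_series(traj, "all_at_50")
  free50 <- cumfp_series(traj, "free_at_50")
  expect_equal(free50$cumfp, all50$cumfp / 0.8, tolerance = 1e-12)
  expect_true(all(diff(all50$cumfp) >= 0))

  # no screening rounds before the first age: series starts at the first round
  expect_equal(all50$cumfp[1], 1e5 * 0.8 * 0.02, tolerance = 1e-12)
})
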