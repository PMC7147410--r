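test_that("first-FP round weights are geometric in the base case and sum below 1", {
  w <- first_fp_round_weights(rep(0.02, 13))
  expect_equal(w, 0.02 * 0.98^(0:12), tolerance = 1e-15)
  expect_lte(sum(w), 1)

  w_dep <- first_fp_round_weights(c(0.02, 0.01, 0.01))
  expect_equal(w_dep, c(0.02, 0.01 * 0.98, 0.01 * 0.98 * 0.99), tolerance = 1e-15)
  expect_true(all(first_fp_round_weights(runif(10)) >= 0))
})

test_that("closed form reduces to the geometric complement with no attrition", {
  flat <- linear_survivorship(1, 1)
  sc <- screening_scenario(50, 74, 2, 0.98)
  series <- cumfp_closed_form(flat, sc)
  expect_equal(series$cumfp[series$age == 74], 1e5 * (1 - 0.98^13), tolerance = 1e-9)

  # single round: 100000 * F(50) * (1 - s)
  one <- screening_scenario(50, 50, 1, 0.95)
  curve <- linear_survivorship(0.8, 0.54)
  s1 <- cumfp_closed_form(curve, one)
  expect_equal(s1$cumfp, 1e5 * 0.8 * 0.05, tolerance = 1e-12)
})

test_that("engine and closed form agree on randomized schedules and scenarios", {
  set.seed(101)
  for (rep in 1:20) {
    sch <- random_schedules()
    sc <- random_scenario()
    prev <- runif(1, 0, 0.3)
    curve <- survivorship_from_schedules(sch$mortality, sch$incidence,
                                         prevalence_at_start = prev,
                                         ages = sc$start_age:75)
    oracle <- cumfp_closed_form(curve, sc)
    traj <- run_cohort(sch$mortality, sch$incidence, sc,
                       cohort_size = 1e5, prevalence_at_start = prev)
    engine <- cumfp_series(traj, "all_at_50")
    common <- intersect(oracle$age, engine$age)
    expect_equal(engine$cumfp[match(common, engine$age)],
                 oracle$cumfp[match(common, oracle$age)],
                 tolerance = 1e-9)
  }
})

test_that("survivorship recursion handles the degenerate schedules", {
  ages <- 50:55
  i <- annual_schedule(ages, rep(0.02, 6), "incidence")
  q0 <- annual_schedule(ages, rep(0, 6), "mortality")
  curve <- survivorship_from_schedules(q0, i, ages = ages)
  expect_equal(survivorship_at(curve, 51), 0.98)

  i0 <- annual_schedule(ages, rep(0, 6), "incidence")
  flat <- survivorship_from_schedules(q0, i0, ages = ages)
  expect_true(all(flat$surv == 1))
})

test_that("cumFP column inversion recovers the survivorship at screening ages", {
  set.seed(5)
  curve <- linear_survivorship(0.9, 0.6)
  for (sc in list(screening_scenario(50, 74, 2, 0.98),
                  screening_scenario(50, 74, 3, 0.92),
                  screening_scenario(54, 74, 2, 0.98, dependence_reduction = 0.01))) {
    series <- cumfp_closed_form(curve, sc)
    rec <- invert_cumfp_to_survivorship(series, sc)
    ages <- build_screening_ages(sc)
    expect_equal(rec$surv, survivorship_at(curve, ages), tolerance = 1e-10)
    # and the forward map reproduces the series at screening ages
    rebuilt <- cumfp_closed_form(
      survivorship_curve(min(ages):max(ages),
                         approx(rec$age, rec$surv, xout = min(ages):max(ages))$y),
      sc)
    expect_equal(rebuilt$cumfp[match(ages, rebuilt$age)],
                 series$cumfp[match(ages, series$age)], tolerance = 1e-9)
  }
})

test_that("inversion handles the hand-computable two-round column", {
  sc <- screening_scenario(50, 52, 2, 0.98)
  series <- structure(data.frame(age = c(50, 52), cumfp = c(2000, 3921)),
                      denominator = "all_at_50",
                      class = c("cumfp_series", "data.frame"))
  rec <- invert_cumfp_to_survivorship(series, sc)
  expect_equal(rec$surv, c(2000 / (0.02 * 1e5), 1921 / (0.98 * 0.02 * 1e5)),
               tolerance = 1e-12)
  expect_equal(rec$surv[1], 1)

  # a column flat after round 1 implies nobody lesion-free at later rounds
  flat <- structure(data.frame(age = c(50, 52), cumfp = c(2000, 2000)),
                    denominator = "all_at_50",
                    class = c("cumfp_series", "data.frame"))
  expect_equal(invert_cumfp_to_survivorship(flat, sc)$surv[2], 0)

  bad <- structure(data.frame(age = c(50, 52), cumfp = c(2000, 1000)),
                   denominator = "all_at_50",
                   class = c("cumfp_series", "data.frame"))
  expect_error(invert_cumfp_to_survivorship(bad, sc), "non-decreasing")
})
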