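test_that("mean-shift PIF matches its closed form", {
  expect_equal(potential_impact_fraction(1.2, 0), 0)
  expect_equal(potential_impact_fraction(1.2, -1), 1 - 1.2^-1)
  expect_equal(potential_impact_fraction(1.2, -1), 0.16667, tolerance = 1e-4)
  # negative shift with rr > 1 lowers incidence; positive shift raises it
  expect_gt(potential_impact_fraction(1.2, -0.5), 0)
  expect_lt(potential_impact_fraction(1.2, 0.5), 0)
  expect_error(potential_impact_fraction(-1, 0.1), "positive")
})

test_that("integral PIF agrees with mean shift as the BMI spread vanishes", {
  ms <- potential_impact_fraction(1.2, -0.05)
  int <- potential_impact_fraction(1.2, -0.05, method = "integral",
                                   bmi_mean = 27, bmi_sd = 1e-3)
  expect_equal(int, ms, tolerance = 1e-6)
  # with a realistic spread the two differ, but only slightly
  int_wide <- potential_impact_fraction(1.2, -0.05, method = "integral",
                                        bmi_mean = 27, bmi_sd = 4.5)
  expect_false(identical(int_wide, ms))
  expect_equal(int_wide, ms, tolerance = 0.1)
})

test_that("incidence adjustment applies 1 - pif with guards", {
  expect_equal(adjust_incidence(0.01, 0), 0.01)
  expect_equal(adjust_incidence(0.01, 0.1667), 0.008333, tolerance = 1e-4)
  expect_error(adjust_incidence(0.01, 1), "below 1")
  expect_error(adjust_incidence(-0.01, 0), "non-negative")
})

test_that("discounting matches hand arithmetic", {
  expect_equal(discount(c(100, 100), 0.03), 100 + 100 / 1.03)
  expect_equal(discount(c(100, 100), 0.03), 197.087, tolerance = 1e-3)
  expect_equal(discount(c(5, 7, 9), 0), 21)
  expect_equal(discount(100, 0.05, years = 0), 100)
  expect_equal(discount(100, 0.05, years = 3, reference_year = 3), 100)
  expect_error(discount(100, -0.01), "non-negative")
})

test_that("disease process follows the geometric closed form", {
  # incidence rate chosen so the annual conversion probability is exactly 0.1
  ages <- 60:63
  pop <- toy_population(ages, count = 1000, mortality = 0.0)
  dis <- toy_diseases(ages, names = "diabetes", incidence = -log(0.9),
                      case_fatality = 0, prevalence = 0)
  traj <- run_disease_process(dis, pop)
  prev3 <- traj$prevalent[traj$sex == "male" & traj$cohort_age == 60 &
                            traj$year == 3]
  expect_equal(prev3, 1000 * (1 - 0.9^3), tolerance = 1e-9) # 271
  # zero incidence, zero entry prevalence: everyone stays susceptible
  dis0 <- toy_diseases(ages, names = "diabetes", incidence = 0,
                       case_fatality = 0.1, prevalence = 0)
  traj0 <- run_disease_process(dis0, pop)
  expect_true(all(traj0$susceptible == 1000 * (traj0$age <= 63)))
  expect_true(all(traj0$prevalent == 0))
})

test_that("disease processes conserve people across random rate draws", {
  set.seed(31)
  for (k in 1:25) {
    ages <- 40:70
    dis <- toy_diseases(
      ages, names = "diabetes",
      incidence = stats::runif(1, 0, 0.2),
      case_fatality = stats::runif(1, 0, 0.3),
      prevalence = stats::runif(1, 0, 0.4)
    ) |>
      dplyr::mutate(remission = stats::runif(1, 0, 0.1))
    pop <- toy_population(ages, count = 1234)
    traj <- run_disease_process(dis, pop)
    total <- traj$susceptible + traj$prevalent + traj$dead
    expect_true(all(abs(total - 1234) / 1234 < 1e-9))
    expect_true(all(traj$susceptible >= 0 & traj$prevalent >= 0 &
                      traj$dead >= 0))
  }
})

test_that("with no morbidity and no disease, HALYs equal life years", {
  ages <- 60:80
  pop <- toy_population(ages, morbidity = 0)
  out <- run_mslt(pop, toy_diseases(ages)[0, ])
  expect_equal(out$summary$halys, out$summary$life_years)
  expect_lte(out$summary$halys_disc, out$summary$halys)
})

test_that("a single cohort with constant mortality matches the geometric form", {
  ages <- 50:129
  pop <- toy_population(ages, count = 0, mortality = 0.2, morbidity = 0)
  pop$count[pop$age == 50] <- 1000
  out <- run_mslt(pop, toy_diseases(ages)[0, ])
  # sum_t l_t (1 - q/2) with l_t = (1-q)^t -> (1 - q/2) / q per person
  expect_equal(out$summary$life_years / 2000, (1 - 0.1) / 0.2,
               tolerance = 1e-6)
})

test_that("disease disability strictly reduces HALYs", {
  ages <- 60:80
  pop <- toy_population(ages)
  with_dis <- run_mslt(pop, toy_diseases(ages, names = "diabetes",
                                         incidence = 0.02, case_fatality = 0,
                                         prevalence = 0.1, dw = 0.2,
                                         cost = 0, rr = 1.2))
  without <- run_mslt(pop, toy_diseases(ages)[0, ])
  expect_lt(with_dis$summary$halys, without$summary$halys)
  expect_equal(with_dis$summary$life_years, without$summary$life_years)
})

test_that("a null intervention changes nothing, exactly", {
  b <- synthetic_bundle(1, max_age = 60)
  ref <- run_mslt(b$population, b$diseases)
  zero_shift <- tibble::tibble(sex = b$population$sex,
                               age = b$population$age,
                               delta_kj = 0, delta_weight = 0, delta_bmi = 0)
  int <- run_mslt(b$population, b$diseases, bshift = zero_shift)
  cmp <- compare_populations(ref, int)
  expect_identical(cmp$halys_gained, 0)
  expect_identical(cmp$cost_offsets, 0)
  expect_true(all(cmp$deaths_averted[[1]]$deaths_averted == 0))
})

test_that("identical strata are required for comparison", {
  b <- synthetic_bundle(1, max_age = 40)
  b2 <- synthetic_bundle(1, max_age = 41)
  ref <- run_mslt(b$population, b$diseases)
  other <- run_mslt(b2$population, b2$diseases)
  expect_error(compare_populations(ref, other), "strata")
})

test_that("HALY gains grow with the BMI shift and are locally linear", {
  b <- synthetic_bundle(1)
  ref <- run_mslt(b$population, b$diseases)
  gains <- purrr::map_dbl(c(0.05, 0.1, 0.2), function(d) {
    bs <- tibble::tibble(sex = b$population$sex, age = b$population$age,
                         delta_kj = -d * 100, delta_weight = -d,
                         delta_bmi = -d)
    cmp <- compare_populations(ref, run_mslt(b$population, b$diseases,
                                             bshift = bs))
    cmp$halys_gained
  })
  expect_true(all(diff(gains) > 0))
  slopes <- gains / c(0.05, 0.1, 0.2)
  expect_lt(max(slopes) / min(slopes) - 1, 0.1)
  # discounting shrinks the gains
  bs <- tibble::tibble(sex = b$population$sex, age = b$population$age,
                       delta_kj = -10, delta_weight = -0.1, delta_bmi = -0.04)
  int <- run_mslt(b$population, b$diseases, bshift = bs)
  cmp <- compare_populations(ref, int)
  expect_lt(cmp$halys_gained, cmp$halys_gained_undisc)
})

test_that("the largest mortality benefit falls on the highest RR x burden disease", {
  b <- synthetic_bundle(1)
  eff <- scenario_effect(b$consumption, b$package_shares, scenario("A1"))
  bs <- body_shift(b$population, eff)
  ref <- run_mslt(b$population, b$diseases)
  int <- run_mslt(b$population, b$diseases, bshift = bs)
  averted <- compare_populations(ref, int)$deaths_averted[[1]]
  top <- averted$disease[which.max(averted$deaths_averted)]
  expect_identical(top, "ischaemic heart disease")
})

test_that("deterministic life table agrees with a stochastic microsimulation", {
  ages <- 60:62
  pop <- toy_population(ages, count = 1000, mortality = 0.03)
  dis <- toy_diseases(ages)
  out <- run_mslt(pop, dis)
  ms <- microsim_oracle(pop, dis, n_per_cohort = 4000, seed = 7)
  expect_lt(abs(out$summary$life_years - ms$life_years), 3 * ms$life_years_se)
  expect_lt(abs(out$summary$halys - ms$halys), 3 * ms$halys_se)
  for (nm in unique(dis$disease)) {
    traj <- run_disease_process(dplyr::filter(dis, disease == nm), pop)
    det_prev <- sum(traj$prevalent[traj$age == max(ages)])
    expect_lt(abs(det_prev - ms$prevalent_end[[nm]]),
              3 * ms$prevalent_end_se[[nm]] + 1e-9)
  }
})
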