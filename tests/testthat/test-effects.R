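shares_600 <- tibble::tibble(
  package_size = 600, single_serve = TRUE, volume_share = 1
)

test_that("scenario registry holds the ten default scenarios", {
  sc <- default_scenarios()
  expect_setequal(sc$id, c(paste0("A", 1:6), paste0("B", 1:4)))
  expect_true(all(sc$adherence[sc$mandatory] == 1))
  expect_true(all(sc$adherence[!sc$mandatory] == 0.2))
  expect_true(all(!(sc$compensation > 0 & sc$substitution > 0)))
  expect_error(scenario("C1"), "Unknown scenario")
})

test_that("excess volume fraction follows the share-weighted excess formula", {
  expect_equal(excess_volume_fraction(shares_600, cap = 375), 225 / 600)
  all_small <- tibble::tibble(
    package_size = c(250, 375), single_serve = TRUE, volume_share = c(0.4, 0.6)
  )
  expect_equal(excess_volume_fraction(all_small, cap = 375), 0)
  # non-single-serve sizes never contribute, whatever their volume
  mixed <- tibble::tibble(
    package_size = c(600, 2000), single_serve = c(TRUE, FALSE),
    volume_share = c(0.5, 0.5)
  )
  expect_equal(excess_volume_fraction(mixed, cap = 375), 0.5 * 225 / 600)
  expect_error(excess_volume_fraction(shares_600, cap = 0), "positive")
})

test_that("affected share covers reach, not removed volume", {
  sh <- synthetic_bundle(1)$package_shares
  aff <- affected_volume_share(sh, cap = 375)
  expect_equal(aff, 0.27 * 0.59, tolerance = 1e-9)
  expect_equal(round(100 * aff), 16)
  expect_equal(affected_volume_share(sh, cap = 1e6), 0)
  expect_equal(affected_volume_share(shares_600, cap = 375), 1)
})

test_that("package cap effect reproduces the published mean energy change", {
  b <- synthetic_bundle(1)
  eff <- package_cap_effect(b$consumption, b$package_shares, scenario("A1"))
  expect_true(all(eff$delta_kj <= 0))
  expect_true(all(abs(eff$delta_kj) <= eff$ssb_energy))
  # population-mean intake of 564.4 kJ/day falls by 14.4 kJ/day
  frac <- excess_volume_fraction(b$package_shares, 375)
  expect_equal(564.4 * frac, 14.4, tolerance = 1e-6)
  # per-band changes match the published table at its printed precision
  cell <- function(s, bnd) eff$delta_kj[eff$sex == s & eff$age_band == bnd]
  expect_equal(round(cell("male", "20+"), 1), -17.5)
  expect_equal(round(cell("female", "20+"), 1), -14.2)
  expect_equal(round(cell("male", "2-12"), 1), -11.9)
  expect_equal(round(cell("female", "2-12"), 1), -10.9)
  expect_equal(round(cell("male", "13-19"), 1), -17.5)
  expect_equal(round(cell("female", "13-19"), 1), -15.3)
})

test_that("compensation and substitution modify the cap effect as specified", {
  b <- synthetic_bundle(1)
  sc <- scenario("A1")
  full_comp <- dplyr::mutate(sc, compensation = 1)
  eff <- package_cap_effect(b$consumption, b$package_shares, full_comp)
  expect_true(all(eff$delta_kj == 0))

  # substituters drop all their SSB energy under the default scope
  sub <- dplyr::mutate(sc, substitution = 0.1)
  eff_sub <- package_cap_effect(b$consumption, b$package_shares, sub)
  frac <- excess_volume_fraction(b$package_shares, 375)
  expected <- -(frac * 0.9 + 0.1) * b$consumption$ssb_energy
  expect_equal(eff_sub$delta_kj, expected)

  # under the affected_only scope they only drop the above-cap products
  eff_aff <- package_cap_effect(b$consumption, b$package_shares, sub,
                                substitution_scope = "affected_only")
  aff <- affected_volume_share(b$package_shares, 375)
  expect_equal(eff_aff$delta_kj, -(frac * 0.9 + 0.1 * aff) *
                 b$consumption$ssb_energy)
  expect_true(all(abs(eff_aff$delta_kj) < abs(eff_sub$delta_kj)))

  expect_error(package_cap_effect(b$consumption, b$package_shares,
                                  scenario("B1")), "package_cap")
})

test_that("energy reduction effect is a uniform percentage cut", {
  b <- synthetic_bundle(1)
  eff <- energy_reduction_effect(b$consumption, scenario("B1"))
  cell <- function(s, bnd) eff$delta_kj[eff$sex == s & eff$age_band == bnd]
  expect_equal(cell("female", "20+"), -557.6 * 0.05) # -27.88, prints -27.9
  expect_equal(round(cell("female", "20+"), 1), -27.9)
  expect_equal(round(cell("male", "2-12"), 1), -23.3)
  zero <- dplyr::mutate(scenario("B1"), kj_reduction = 0)
  expect_true(all(energy_reduction_effect(b$consumption, zero)$delta_kj == 0))
  bad <- dplyr::mutate(scenario("B1"), kj_reduction = 1.5)
  expect_error(energy_reduction_effect(b$consumption, bad), "0, 1")
})

test_that("voluntary effects scale the mandatory effect by adherence", {
  b <- synthetic_bundle(1)
  for (pair in list(c("A1", "A4"), c("A2", "A5"), c("A3", "A6"),
                    c("B1", "B3"), c("B2", "B4"))) {
    mand <- scenario_effect(b$consumption, b$package_shares, scenario(pair[1]))
    vol <- scenario_effect(b$consumption, b$package_shares, scenario(pair[2]))
    expect_equal(vol$delta_kj, 0.2 * mand$delta_kj, tolerance = 1e-12)
  }
  # voluntary 5% reformulation for adult women: 557.6 * 0.05 * 0.2
  eff <- energy_reduction_effect(b$consumption, scenario("B3"))
  expect_equal(eff$delta_kj[eff$sex == "female" & eff$age_band == "20+"],
               -5.576)
})

test_that("effect magnitude is monotone in its drivers", {
  b <- synthetic_bundle(1)
  base <- scenario("B1")
  cuts <- c(0.01, 0.05, 0.1, 0.3)
  mags <- purrr::map_dbl(cuts, function(k) {
    sc <- dplyr::mutate(base, kj_reduction = k)
    -sum(energy_reduction_effect(b$consumption, sc)$delta_kj)
  })
  expect_true(all(diff(mags) > 0))

  comps <- c(0, 0.25, 0.5, 1)
  cap_mags <- purrr::map_dbl(comps, function(cm) {
    sc <- dplyr::mutate(scenario("A1"), compensation = cm)
    -sum(package_cap_effect(b$consumption, b$package_shares, sc)$delta_kj)
  })
  expect_true(all(diff(cap_mags) < 0))
})
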