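#' Generate a synthetic population table
#'
#' Builds a single-year-of-age population for both sexes with the structure the
#' life-table model expects: person counts, annual all-cause mortality
#' probabilities, background morbidity (prevalent years lived with disability
#' per person-year), mean height and weight, and the mean and standard
#' deviation of the BMI distribution within each stratum. Values are stylised
#' but demographically plausible for a high-income population: mortality
#' follows a Gompertz-type rise (forced non-decreasing beyond age 40),
#' background morbidity rises slowly with age, heights follow a growth curve
#' with a sex-specific adult plateau, and mean BMI rises from childhood values
#' to an adult plateau in the high 20s.
#'
#' @param seed Integer seed; identical seeds give identical tables.
#' @param max_age Oldest age simulated (last birthday), at least 2.
#'
#' @return A tibble with one row per (sex, age) and columns `sex`, `age`,
#'   `count`, `mortality_rate`, `morbidity_rate`, `mean_height`,
#'   `mean_weight`, `bmi_mean`, `bmi_sd`.
#' @export
#' @examples
#' pop <- generate_population(seed = 1)
#' dplyr::count(pop, sex)
generate_population <- function(seed = 1L, max_age = 100L) {
  stopifnot_scalar_number(seed, "seed")
  stopifnot_scalar_number(max_age, "max_age")
  if (max_age < 2) abort("`max_age` must be at least 2.")

  withr_seed(seed, {
    ages <- 2:max_age
    purrr::map_dfr(c("male", "female"), function(sex) {
      n <- length(ages)
      f <- sex == "female"

      # population pyramid: broad plateau, tapering after 60
      count <- 145000 * exp(-pmax(ages - 60, 0)^2 / 1800) *
        exp(-pmax(ages - 30, 0) * 0.004)
      count <- round(count * exp(stats::rnorm(n, 0, 0.02)))

      # all-cause mortality: childhood floor + Gompertz rise
      m <- 2e-4 + exp(-9.9 + 0.092 * ages) * (if (f) 0.8 else 1)
      m <- m * exp(stats::rnorm(n, 0, 0.04))
      q <- 1 - exp(-m)
      over40 <- ages >= 40
      q[over40] <- cummax(q[over40])
      q <- pmin(q, 0.999)

      # background morbidity (YLD rate), exclusive of the modelled diseases
      ydr <- 0.03 + 0.0021 * pmax(ages - 20, 0)
      ydr <- pmin(ydr * exp(stats::rnorm(n, 0, 0.03)), 0.95)

      # growth curve with adult plateau and mild old-age shrinkage
      anchor_age <- c(2, 5, 10, 13, 16, 19, 30, 70, max(100, max_age))
      anchor_ht <- if (f) {
        c(0.89, 1.09, 1.38, 1.57, 1.62, 1.63, 1.62, 1.60, 1.57)
      } else {
        c(0.90, 1.11, 1.40, 1.60, 1.73, 1.76, 1.76, 1.74, 1.70)
      }
      height <- stats::approx(anchor_age, anchor_ht, xout = ages)$y

      bmi_mean <- 15.5 + 9 * stats::plogis((ages - 32) / 14) +
        stats::rnorm(n, 0, 0.15)
      bmi_mean <- pmax(bmi_mean, 13)
      bmi_sd <- pmin(2 + ages / 35, 4.8)

      tibble::tibble(
        sex = sex,
        age = ages,
        count = pmax(count, 0),
        mortality_rate = q,
        morbidity_rate = ydr,
        mean_height = height,
        mean_weight = round(bmi_mean * height^2, 1),
        bmi_mean = bmi_mean,
        bmi_sd = bmi_sd
      )
    })
  })
}

#' Names of the nine obesity-related diseases in the default bundle
#' @return Character vector of length nine.
#' @export
obesity_disease_names <- function() {
  c(
    "ischaemic heart disease", "hypertensive heart disease",
    "ischemic stroke", "diabetes", "colorectal cancer", "kidney cancer",
    "breast cancer", "endometrial cancer", "osteoarthritis"
  )
}

# stylised epidemiology for each disease: logistic incidence ramp by age,
# case fatality and disability typical of burden-of-disease inputs, relative
# risk per +1 kg/m^2 BMI. IHD is deliberately the largest RR x burden so the
# leading cause of averted deaths mirrors what is seen empirically.
disease_params <- function() {
  tibble::tribble(
    ~disease, ~inc_max, ~inc_mid, ~inc_slope, ~cf, ~duration, ~dw, ~cost, ~rr0, ~male_mult, ~female_only,
    "ischaemic heart disease", 0.025, 62, 9, 0.080, 6, 0.35, 9000, 1.15, 1.35, FALSE,
    "hypertensive heart disease", 0.004, 66, 9, 0.060, 8, 0.25, 6000, 1.20, 1.10, FALSE,
    "ischemic stroke", 0.008, 71, 8, 0.100, 6, 0.40, 12000, 1.10, 1.10, FALSE,
    "diabetes", 0.012, 52, 11, 0.015, 25, 0.20, 5000, 1.25, 1.05, FALSE,
    "colorectal cancer", 0.003, 66, 9, 0.120, 5, 0.30, 20000, 1.05, 1.15, FALSE,
    "kidney cancer", 0.0012, 63, 9, 0.150, 5, 0.30, 22000, 1.30, 1.40, FALSE,
    "breast cancer", 0.0025, 56, 12, 0.040, 8, 0.25, 18000, 1.05, NA, TRUE,
    "endometrial cancer", 0.0010, 61, 9, 0.050, 7, 0.25, 15000, 1.35, NA, TRUE,
    "osteoarthritis", 0.010, 56, 10, 0.000, 30, 0.15, 3000, 1.20, 0.80, FALSE
  )
}

#' Generate the nine-disease epidemiology bundle
#'
#' Produces, for each of the nine obesity-related diseases modelled
#' (ischaemic heart disease, hypertensive heart disease, ischemic stroke,
#' diabetes, colorectal cancer, kidney cancer, breast cancer, endometrial
#' cancer, osteoarthritis) and each (sex, age) stratum: annual incidence,
#' point prevalence, annual case fatality, remission (zero by default — the
#' diseases are treated as chronic), the relative risk per +1 BMI unit applied
#' to incidence, plus a disease-level disability weight and annual health-care
#' cost per prevalent case (2010 AUD). Sex-specific cancers have zero
#' incidence in males. Relative risks taper towards 1 in old age.
#'
#' @inheritParams generate_population
#' @return A tibble with one row per (disease, sex, age).
#' @export
generate_disease_bundle <- function(seed = 1L, max_age = 100L) {
  stopifnot_scalar_number(seed, "seed")
  pars <- disease_params()

  withr_seed(seed + 1L, {
    purrr::pmap_dfr(pars, function(disease, inc_max, inc_mid, inc_slope, cf,
                                    duration, dw, cost, rr0, male_mult,
                                    female_only) {
      jitter <- exp(stats::rnorm(1, 0, 0.05))
      purrr::map_dfr(c("male", "female"), function(sex) {
        ages <- 2:max_age
        mult <- if (female_only) {
          if (sex == "male") 0 else 1
        } else if (sex == "male") male_mult else 1
        inc <- inc_max * mult * jitter * stats::plogis((ages - inc_mid) / inc_slope)
        inc <- pmin(inc, 0.099)
        prev <- pmin(inc * duration / (1 + inc * duration), 0.45)
        # RR attenuates with age, as BMI relative risks typically do
        taper <- ifelse(ages <= 70, 1, pmax(0.3, 1 - (ages - 70) / 60))
        rr <- 1 + (rr0 - 1) * taper * (mult > 0)
        tibble::tibble(
          disease = disease,
          sex = sex,
          age = ages,
          incidence = inc,
          prevalence = prev,
          case_fatality = cf,
          remission = 0,
          rr_per_bmi_unit = rr,
          disability_weight = dw,
          annual_cost_per_case = cost
        )
      })
    })
  })
}

# Table of band-level mean intakes the calibrated generator reproduces:
# baseline daily energy and SSB energy (kJ/day/person) by sex and age band.
calibrated_intakes <- function() {
  tibble::tribble(
    ~sex, ~age_band, ~total_energy, ~ssb_energy,
    "male", "2-12", 8140.3, 466.6,
    "female", "2-12", 7137.4, 426.9,
    "male", "13-19", 10771.7, 687.0,
    "female", "13-19", 8260.6, 600.8,
    "male", "20+", 10308.0, 684.8,
    "female", "20+", 7841.2, 557.6
  )
}

# Mean SSB intake across the whole population and its capped counterpart,
# used to pin down the calibrated package-size mix: a 375 mL single-serve cap
# removes 14.4 of 564.4 kJ/day on average.
CALIBRATION_TARGETS <- list(
  single_serve_share = 0.27,
  over_cap_within_single_serve = 0.59,
  excess_fraction = 14.4 / 564.4,
  cap = 375,
  energy_density = 1.6 # kJ/mL; 600 kJ in a 375 mL can
)

calibrated_package_shares <- function() {
  tg <- CALIBRATION_TARGETS
  sizes <- c(250, 375, 400, 450, 500, 600, 1250, 2000)
  single <- sizes <= 600
  over <- single & sizes > tg$cap
  s_over <- tg$single_serve_share * tg$over_cap_within_single_serve
  ratio <- (sizes - tg$cap) / sizes
  # place mass on the >cap sizes so the share-weighted excess volume matches
  # the calibration target: equal shares on {450,500,600}, remainder at 400
  big3 <- sizes %in% c(450, 500, 600)
  b <- (tg$excess_fraction - ratio[sizes == 400] * s_over) /
    (sum(ratio[big3]) - 3 * ratio[sizes == 400])
  share <- numeric(length(sizes))
  share[big3] <- b
  share[sizes == 400] <- s_over - 3 * b
  share[sizes == 250] <- (tg$single_serve_share - s_over) / 2
  share[sizes == 375] <- (tg$single_serve_share - s_over) / 2
  share[sizes == 1250] <- (1 - tg$single_serve_share) * 0.41
  share[sizes == 2000] <- (1 - tg$single_serve_share) * 0.59
  tibble::tibble(
    package_size = sizes,
    single_serve = single,
    volume_share = share
  )
}

#' Generate SSB consumption and package-size sales-share tables
#'
#' Returns per-stratum mean daily SSB intake (three age bands by sex, the
#' resolution at which consumption inputs are reported) and the volume share
#' of SSB sales by package size with single-serve flags. With
#' `calibrate = TRUE` (the default) the tables are pinned to the
#' published marginals: band-level baseline intakes, a 27% single-serve volume
#' share of which 59% sits in sizes above 375 mL, with the mass above the cap
#' placed so that the share-weighted excess volume fraction equals the
#' published population-mean energy reduction under the cap. With
#' `calibrate = FALSE` both tables are randomly perturbed around
#' those values.
#'
#' @inheritParams generate_population
#' @param calibrate Reproduce the published marginals exactly?
#' @return A list with elements `consumption` (tibble: `sex`, `age_band`,
#'   `total_energy`, `ssb_energy`, `ssb_volume`, `energy_density`) and
#'   `package_shares` (tibble: `package_size`, `single_serve`,
#'   `volume_share`).
#' @export
generate_consumption <- function(seed = 1L, calibrate = TRUE) {
  stopifnot_scalar_number(seed, "seed")
  dens <- CALIBRATION_TARGETS$energy_density
  base <- calibrated_intakes()
  shares <- calibrated_package_shares()

  if (!calibrate) {
    withr_seed(seed + 2L, {
      base <- base |>
        dplyr::mutate(
          total_energy = .data$total_energy * stats::runif(dplyr::n(), 0.85, 1.15),
          ssb_energy = pmin(
            .data$ssb_energy * stats::runif(dplyr::n(), 0.7, 1.3),
            .data$total_energy
          )
        )
      w <- stats::rgamma(nrow(shares), shape = 4, rate = 1)
      shares$volume_share <- w / sum(w)
    })
  }

  consumption <- base |>
    dplyr::mutate(
      ssb_volume = .data$ssb_energy / dens,
      energy_density = dens
    )
  list(consumption = consumption, package_shares = shares)
}

#' Generate a complete synthetic input bundle
#'
#' Convenience wrapper producing all four input tables (population, diseases,
#' consumption, package shares) from one master seed, together with a manifest
#' recording the seed and calibration flag.
#'
#' @inheritParams generate_population
#' @inheritParams generate_consumption
#' @return A list of class `ssb_bundle` with elements `population`,
#'   `diseases`, `consumption`, `package_shares`, `manifest`.
#' @export
#' @examples
#' bundle <- synthetic_bundle(seed = 7)
#' names(bundle)
synthetic_bundle <- function(seed = 1L, calibrate = TRUE,
                             max_age = 100L) {
  cons <- generate_consumption(seed, calibrate)
  out <- list(
    population = generate_population(seed, max_age),
    diseases = generate_disease_bundle(seed, max_age),
    consumption = cons$consumption,
    package_shares = cons$package_shares,
    manifest = list(
      seed = as.integer(seed),
      calibrate = calibrate,
      max_age = as.integer(max_age)
    )
  )
  class(out) <- "ssb_bundle"
  out
}

#' @export
print.ssb_bundle <- function(x, ...) {
  cat("<ssb_bundle>\n")
  cat("  seed:", x$manifest$seed,
      " calibrated:", x$manifest$calibrate, "\n")
  cat("  population:", nrow(x$population), "strata;",
      "diseases:", dplyr::n_distinct(x$diseases$disease), "\n")
  invisible(x)
}

#' Write / read an input bundle as CSV + JSON manifest
#'
#' `write_bundle()` writes `population.csv`, `diseases.csv`,
#' `consumption.csv`, `package_shares.csv` (RFC-4180, header row, UTF-8) and
#' `manifest.json` into `dir`; `read_bundle()` reads them back.
#'
#' @param bundle An `ssb_bundle`.
#' @param dir Directory path; created if missing.
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()` an
#'   `ssb_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$population, file.path(dir, "population.csv"))
  readr::write_csv(bundle$diseases, file.path(dir, "diseases.csv"))
  readr::write_csv(bundle$consumption, file.path(dir, "consumption.csv"))
  readr::write_csv(bundle$package_shares, file.path(dir, "package_shares.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  need <- c("population.csv", "diseases.csv", "consumption.csv",
            "package_shares.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("Bundle directory '%s' is missing: %s",
                  dir, paste(missing, collapse = ", ")))
  }
  out <- list(
    population = readr::read_csv(file.path(dir, "population.csv"),
                                 show_col_types = FALSE),
    diseases = readr::read_csv(file.path(dir, "diseases.csv"),
                               show_col_types = FALSE),
    consumption = readr::read_csv(file.path(dir, "consumption.csv"),
                                  show_col_types = FALSE),
    package_shares = readr::read_csv(file.path(dir, "package_shares.csv"),
                                     show_col_types = FALSE),
    manifest = if (file.exists(file.path(dir, "manifest.json"))) {
      jsonlite::read_json(file.path(dir, "manifest.json"))
    } else {
      list()
    }
  )
  class(out) <- "ssb_bundle"
  out
}

# run code under a temporary RNG state so generators never disturb the
# caller's random stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% 2147483647L)
  force(code)
}
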