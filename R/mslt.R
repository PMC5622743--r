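#' Potential impact fraction of a BMI shift on disease incidence
#'
#' Computes the proportional change in disease incidence produced by shifting
#' the population BMI distribution, given a log-linear relative risk per +1
#' kg/m^2. Two estimators are available:
#'
#' * `mean_shift`: the closed form `1 - rr^delta_bmi`, which is exact when
#'   risk is log-linear in BMI and the whole distribution translates.
#' * `integral`: numerical integration of `rr^x` over a lognormal BMI
#'   distribution before and after the shift (`pif = 1 - I*/I`), where the
#'   shifted distribution is a lognormal with mean `bmi_mean + delta_bmi` and
#'   unchanged standard deviation. Integration is truncated at the 1e-10 and
#'   1-1e-10 quantiles of each density (the integrand has no finite integral
#'   over an unbounded lognormal support).
#'
#' A negative shift with `rr > 1` yields a positive fraction (incidence
#' falls).
#'
#' @param rr Relative risk per +1 kg/m^2, positive; vectorised.
#' @param delta_bmi BMI shift in kg/m^2; vectorised.
#' @param method `"mean_shift"` (default) or `"integral"`.
#' @param bmi_mean,bmi_sd Mean and SD of the pre-shift BMI distribution;
#'   required for the integral method.
#' @return Potential impact fraction(s) in (-1, 1).
#' @export
#' @examples
#' potential_impact_fraction(1.2, -1) # 1 - 1.2^-1 = 0.1667
potential_impact_fraction <- function(rr, delta_bmi,
                                      method = c("mean_shift", "integral"),
                                      bmi_mean = NULL, bmi_sd = NULL) {
  method <- match.arg(method)
  if (any(rr <= 0)) abort("`rr` must be positive.")
  if (method == "mean_shift") {
    return(1 - rr^delta_bmi)
  }
  if (is.null(bmi_mean) || is.null(bmi_sd)) {
    abort("The integral method needs `bmi_mean` and `bmi_sd`.")
  }
  n <- max(length(rr), length(delta_bmi), length(bmi_mean), length(bmi_sd))
  rr <- rep_len(rr, n)
  delta_bmi <- rep_len(delta_bmi, n)
  bmi_mean <- rep_len(bmi_mean, n)
  bmi_sd <- rep_len(bmi_sd, n)
  purrr::map_dbl(seq_len(n), function(i) {
    if (delta_bmi[i] == 0 || rr[i] == 1) return(0)
    num <- rr_lognormal_moment(rr[i], bmi_mean[i], bmi_sd[i])
    num_star <- rr_lognormal_moment(rr[i], bmi_mean[i] + delta_bmi[i], bmi_sd[i])
    1 - num_star / num
  })
}

# E[rr^X] for X ~ lognormal with given arithmetic mean and sd, truncated at
# extreme quantiles (the untruncated integral diverges)
rr_lognormal_moment <- function(rr, mean, sd) {
  if (mean <= 0) abort("BMI distribution mean must be positive.")
  sdlog2 <- log(1 + (sd / mean)^2)
  sdlog <- sqrt(sdlog2)
  meanlog <- log(mean) - sdlog2 / 2
  lo <- qlnorm(1e-10, meanlog, sdlog)
  hi <- qlnorm(1 - 1e-10, meanlog, sdlog)
  integrate(function(x) rr^x * dlnorm(x, meanlog, sdlog),
            lower = lo, upper = hi, rel.tol = 1e-10)$value
}

#' Apply a potential impact fraction to an incidence rate
#'
#' @param incidence Non-negative incidence rate(s).
#' @param pif Potential impact fraction(s), strictly below 1.
#' @return `incidence * (1 - pif)`.
#' @export
adjust_incidence <- function(incidence, pif) {
  if (any(incidence < 0)) abort("`incidence` must be non-negative.")
  if (any(pif >= 1)) abort("`pif` must be below 1.")
  incidence * (1 - pif)
}

#' Per-stratum potential impact fractions for every disease
#'
#' Joins a body-shift table to the disease bundle and evaluates the PIF for
#' each (disease, sex, age) stratum.
#'
#' @param diseases Disease bundle tibble (see [generate_disease_bundle()]).
#' @param bshift Body-shift tibble from [body_shift()].
#' @param population Population tibble; required for the integral method
#'   (supplies `bmi_mean`, `bmi_sd`).
#' @inheritParams potential_impact_fraction
#' @return A tibble `disease`, `sex`, `age`, `pif`.
#' @export
pif_table <- function(diseases, bshift,
                      method = c("mean_shift", "integral"),
                      population = NULL) {
  method <- match.arg(method)
  joined <- diseases |>
    dplyr::select("disease", "sex", "age", "rr_per_bmi_unit") |>
    dplyr::left_join(dplyr::select(bshift, "sex", "age", "delta_bmi"),
                     by = c("sex", "age")) |>
    dplyr::mutate(delta_bmi = dplyr::coalesce(.data$delta_bmi, 0))
  if (method == "integral") {
    if (is.null(population)) {
      abort("The integral method needs `population` for the BMI distribution.")
    }
    joined <- joined |>
      dplyr::left_join(
        dplyr::select(population, "sex", "age", "bmi_mean", "bmi_sd"),
        by = c("sex", "age")
      )
    joined$pif <- potential_impact_fraction(
      joined$rr_per_bmi_unit, joined$delta_bmi, method = "integral",
      bmi_mean = joined$bmi_mean, bmi_sd = joined$bmi_sd
    )
  } else {
    joined$pif <- potential_impact_fraction(joined$rr_per_bmi_unit,
                                            joined$delta_bmi)
  }
  dplyr::select(joined, "disease", "sex", "age", "pif")
}

#' Present value of an annual stream
#'
#' @param values Annual amounts.
#' @param rate Annual discount rate, non-negative.
#' @param years Year of each amount; defaults to `0, 1, 2, ...`.
#' @param reference_year Year whose value is not discounted.
#' @return The discounted sum.
#' @export
#' @examples
#' discount(c(100, 100), 0.03) # 197.087
discount <- function(values, rate, years = seq_along(values) - 1,
                     reference_year = 0) {
  if (rate < 0) abort("`rate` must be non-negative.")
  if (length(years) != length(values)) {
    abort("`years` must match `values` in length.")
  }
  sum(values / (1 + rate)^(years - reference_year))
}

# --- disease-process engine -------------------------------------------------

# cohort indexing assumes single-year contiguous ages per sex
check_contiguous_ages <- function(ages) {
  if (length(ages) == 0 || (length(ages) > 1 && !all(diff(ages) == 1))) {
    abort("Population ages must be contiguous single years within each sex.")
  }
  invisible(ages)
}

# One disease, one sex: annual susceptible/prevalent/dead-of-disease
# proportions for every cohort. Cohort j enters at age ages[j]; at simulation
# year t its age index is j + t. Returns K x K matrices (cohort x year):
#   C  - prevalent proportion at the start of year t
#   dd - probability of dying of the disease during year t
# Conservation S + C + cumulative dd = 1 holds exactly; other-cause attrition
# lives in the main life table (the processes are proportional).
disease_state_matrices <- function(prev0, inc, cf, rem) {
  K <- length(prev0)
  if (any(inc < 0) || any(cf < 0) || any(rem < 0)) {
    abort("Disease rates must be non-negative.")
  }
  p_i <- 1 - exp(-inc)
  p_f <- 1 - exp(-cf)
  p_r <- 1 - exp(-rem)
  C_mat <- matrix(0, K, K)
  dd_mat <- matrix(0, K, K)
  S <- 1 - prev0
  C <- prev0
  for (t in 0:(K - 1)) {
    jj <- seq_len(K - t)
    ai <- jj + t
    Cj <- C[jj]
    Sj <- S[jj]
    C_mat[jj, t + 1] <- Cj
    new_cases <- Sj * p_i[ai]
    deaths <- Cj * p_f[ai]
    remits <- Cj * p_r[ai]
    dd_mat[jj, t + 1] <- deaths
    S[jj] <- Sj - new_cases + remits
    C[jj] <- Cj + new_cases - deaths - remits
  }
  list(C = C_mat, dd = dd_mat)
}

#' Simulate one disease process over all cohorts
#'
#' Runs the three-state (susceptible, prevalent, dead-of-disease) annual
#' process for a single disease across every cohort of the population, with
#' incidence optionally reduced by a potential impact fraction. Counts are
#' proportions of each entering cohort scaled to its size; other-cause
#' mortality is handled by the main life table, so within the process
#' `susceptible + prevalent + cumulative dead` equals the entering cohort.
#'
#' @param disease Disease-bundle rows for a single disease.
#' @param population Population tibble.
#' @param pif Optional PIF tibble (from [pif_table()]) filtered to the same
#'   disease; incidence is multiplied by `1 - pif`.
#' @return A tibble `sex`, `cohort_age`, `year`, `age`, `susceptible`,
#'   `prevalent`, `dead`.
#' @export
run_disease_process <- function(disease, population, pif = NULL) {
  if (dplyr::n_distinct(disease$disease) != 1) {
    abort("`disease` must contain rows for exactly one disease.")
  }
  purrr::map_dfr(c("male", "female"), function(sx) {
    d <- dplyr::arrange(dplyr::filter(disease, .data$sex == sx), .data$age)
    p <- dplyr::arrange(dplyr::filter(population, .data$sex == sx), .data$age)
    if (nrow(d) != nrow(p) || !all(d$age == p$age)) {
      abort("Disease and population strata do not match.")
    }
    check_contiguous_ages(p$age)
    inc <- d$incidence
    if (!is.null(pif)) {
      pf <- dplyr::arrange(dplyr::filter(pif, .data$sex == sx), .data$age)
      inc <- adjust_incidence(inc, pf$pif)
    }
    st <- disease_state_matrices(d$prevalence, inc, d$case_fatality,
                                 d$remission)
    K <- nrow(p)
    dead <- t(apply(st$dd, 1, cumsum))
    idx <- which(row(st$C) + col(st$C) - 1 <= K, arr.ind = TRUE)
    tibble::tibble(
      sex = sx,
      cohort_age = p$age[idx[, 1]],
      year = idx[, 2] - 1L,
      age = p$age[idx[, 1]] + idx[, 2] - 1L,
      susceptible = (1 - st$C[idx] - dead[idx]) * p$count[idx[, 1]],
      prevalent = st$C[idx] * p$count[idx[, 1]],
      dead = dead[idx] * p$count[idx[, 1]]
    )
  })
}

# --- main life table --------------------------------------------------------

#' Run the proportional multi-state life table
#'
#' Simulates all cohorts of the population to the maximum age in annual
#' cycles. Each of the nine disease processes runs in parallel (proportional
#' to the cohort, linked through all-cause mortality); when a body-shift is
#' supplied, disease incidence is reduced by the potential impact fraction of
#' the BMI change and the resulting change in disease deaths perturbs
#' all-cause mortality relative to the unshifted reference. Person-years use
#' a half-cycle correction; health-adjusted person-years weight each year by
#' `1 - background morbidity - sum(prevalence x disability weight)`; health
#' costs accrue per prevalent person-year.
#'
#' @param population Population tibble.
#' @param diseases Disease bundle tibble.
#' @param bshift Optional body-shift tibble from [body_shift()]; `NULL`
#'   simulates the reference population.
#' @param pif_method PIF estimator, see [potential_impact_fraction()].
#' @param discount_rate Annual discount rate for the summary present values.
#' @return An object of class `mslt_output`: annual totals (`by_year`),
#'   deaths by disease and year (`deaths_by_disease`), and a one-row
#'   `summary` tibble with discounted and undiscounted life years, HALYs and
#'   health costs.
#' @export
#' @examples
#' b <- synthetic_bundle(1)
#' ref <- run_mslt(b$population, b$diseases)
#' glance(ref)
run_mslt <- function(population, diseases, bshift = NULL,
                     pif_method = c("mean_shift", "integral"),
                     discount_rate = 0.03) {
  pif_method <- match.arg(pif_method)
  disease_names <- unique(diseases$disease)
  pif <- if (!is.null(bshift)) {
    pif_table(diseases, bshift, method = pif_method, population = population)
  } else {
    NULL
  }

  totals <- NULL
  deaths <- NULL
  for (sx in c("male", "female")) {
    p <- dplyr::arrange(dplyr::filter(population, .data$sex == sx), .data$age)
    check_contiguous_ages(p$age)
    K <- nrow(p)
    dlist <- purrr::map(disease_names, function(nm) {
      d <- diseases |>
        dplyr::filter(.data$disease == nm, .data$sex == sx) |>
        dplyr::arrange(.data$age)
      if (nrow(d) != K || !all(d$age == p$age)) {
        abort("Disease and population strata do not match.")
      }
      ref <- disease_state_matrices(d$prevalence, d$incidence,
                                    d$case_fatality, d$remission)
      run <- ref
      if (!is.null(pif)) {
        pf <- pif |>
          dplyr::filter(.data$disease == nm, .data$sex == sx) |>
          dplyr::arrange(.data$age)
        run <- disease_state_matrices(
          d$prevalence, adjust_incidence(d$incidence, pf$pif),
          d$case_fatality, d$remission
        )
      }
      list(name = nm, dw = d$disability_weight[1],
           cost = d$annual_cost_per_case[1], ref = ref, run = run)
    })

    l <- p$count
    ly <- haly <- cost <- numeric(K)
    dth <- matrix(0, length(dlist), K,
                  dimnames = list(disease_names, NULL))
    for (t in 0:(K - 1)) {
      jj <- seq_len(K - t)
      ai <- jj + t
      q <- p$mortality_rate[ai]
      if (!is.null(pif)) {
        for (d in dlist) {
          # grouped difference so an identical run perturbs q by exactly zero
          q <- q + (d$run$dd[jj, t + 1] - d$ref$dd[jj, t + 1])
        }
      }
      if (any(q < -1e-9) || any(q > 1 + 1e-9)) {
        abort("Adjusted all-cause mortality left [0, 1].")
      }
      q <- pmin(pmax(q, 0), 1)
      lj <- l[jj]
      l_next <- lj * (1 - q)
      L <- (lj + l_next) / 2
      w <- 1 - p$morbidity_rate[ai]
      yc <- 0
      for (i in seq_along(dlist)) {
        d <- dlist[[i]]
        prev <- d$run$C[jj, t + 1]
        w <- w - prev * d$dw
        yc <- yc + sum(L * prev * d$cost)
        dth[i, t + 1] <- dth[i, t + 1] + sum(lj * d$run$dd[jj, t + 1])
      }
      if (any(w < -1e-9) || any(w > 1 + 1e-9)) {
        abort("Health-state weight left [0, 1].")
      }
      w <- pmin(pmax(w, 0), 1)
      ly[t + 1] <- ly[t + 1] + sum(L)
      haly[t + 1] <- haly[t + 1] + sum(L * w)
      cost[t + 1] <- cost[t + 1] + yc
      l[jj] <- l_next
    }
    sx_totals <- tibble::tibble(year = 0:(K - 1), life_years = ly,
                                halys = haly, health_costs = cost)
    totals <- if (is.null(totals)) sx_totals else {
      dplyr::mutate(totals,
                    life_years = .data$life_years + sx_totals$life_years,
                    halys = .data$halys + sx_totals$halys,
                    health_costs = .data$health_costs + sx_totals$health_costs)
    }
    sx_deaths <- if (length(disease_names) > 0) {
      tibble::as_tibble(t(dth)) |>
        dplyr::mutate(year = 0:(K - 1)) |>
        tidyr::pivot_longer(-"year", names_to = "disease",
                            values_to = "deaths")
    } else {
      tibble::tibble(year = integer(), disease = character(),
                     deaths = numeric())
    }
    deaths <- dplyr::bind_rows(deaths, sx_deaths)
  }

  deaths <- deaths |>
    dplyr::group_by(.data$disease, .data$year) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop")

  yrs <- totals$year
  summary <- tibble::tibble(
    life_years = sum(totals$life_years),
    halys = sum(totals$halys),
    life_years_disc = discount(totals$life_years, discount_rate, yrs),
    halys_disc = discount(totals$halys, discount_rate, yrs),
    health_costs_disc = discount(totals$health_costs, discount_rate, yrs)
  )
  structure(
    list(by_year = totals, deaths_by_disease = deaths, summary = summary,
         discount_rate = discount_rate,
         strata = dplyr::count(population, .data$sex)),
    class = "mslt_output"
  )
}

#' @export
print.mslt_output <- function(x, ...) {
  cat("<mslt_output>\n")
  cat(sprintf("  life years: %.0f  HALYs: %.0f (undiscounted)\n",
              x$summary$life_years, x$summary$halys))
  cat(sprintf("  HALYs: %.0f  health costs: %.0f AUD (discounted at %g%%)\n",
              x$summary$halys_disc, x$summary$health_costs_disc,
              100 * x$discount_rate))
  invisible(x)
}

#' @rdname run_mslt
#' @param x An `mslt_output`.
#' @param ... Unused.
#' @method tidy mslt_output
#' @export
tidy.mslt_output <- function(x, ...) x$by_year

#' @rdname run_mslt
#' @method glance mslt_output
#' @export
glance.mslt_output <- function(x, ...) x$summary

#' @rdname run_mslt
#' @param object An `mslt_output`.
#' @method autoplot mslt_output
#' @export
autoplot.mslt_output <- function(object, ...) {
  ggplot2::ggplot(object$by_year, ggplot2::aes(.data$year, .data$halys)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Simulation year", y = "Health-adjusted life years",
                  title = "Annual HALYs over the simulated lifetime")
}

#' Compare intervention and reference life-table outputs
#'
#' Differences the annual streams of two [run_mslt()] outputs and discounts
#' them: HALYs gained, health-care cost offsets (negative when the
#' intervention saves money) and deaths averted by disease. Identical inputs
#' give exact zeros.
#'
#' @param reference,intervention `mslt_output` objects on identical strata.
#' @param discount_rate Annual discount rate applied to the differenced
#'   streams.
#' @return A one-row tibble: `halys_gained`, `halys_gained_undisc`,
#'   `life_years_gained`, `cost_offsets`, plus a `deaths_averted` list-column
#'   holding a per-disease tibble.
#' @export
compare_populations <- function(reference, intervention, discount_rate = 0.03) {
  if (!identical(reference$strata, intervention$strata) ||
      nrow(reference$by_year) != nrow(intervention$by_year)) {
    abort("Reference and intervention outputs are on different strata.")
  }
  yrs <- reference$by_year$year
  d_haly <- intervention$by_year$halys - reference$by_year$halys
  d_ly <- intervention$by_year$life_years - reference$by_year$life_years
  d_cost <- intervention$by_year$health_costs - reference$by_year$health_costs
  averted <- reference$deaths_by_disease |>
    dplyr::rename(ref_deaths = "deaths") |>
    dplyr::left_join(intervention$deaths_by_disease,
                     by = c("disease", "year")) |>
    dplyr::group_by(.data$disease) |>
    dplyr::summarise(deaths_averted = sum(.data$ref_deaths - .data$deaths),
                     .groups = "drop")
  tibble::tibble(
    halys_gained = discount(d_haly, discount_rate, yrs),
    halys_gained_undisc = sum(d_haly),
    life_years_gained = discount(d_ly, discount_rate, yrs),
    cost_offsets = discount(d_cost, discount_rate, yrs),
    deaths_averted = list(averted)
  )
}
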