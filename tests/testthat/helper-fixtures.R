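# Small fixture builders and an individual-level microsimulation oracle used
# to cross-check the deterministic life table.

toy_population <- function(ages = 60:62, count = 1000, mortality = 0.02,
                           morbidity = 0.05) {
  tidyr::expand_grid(sex = c("male", "female"), age = ages) |>
    dplyr::mutate(
      count = count,
      mortality_rate = mortality,
      morbidity_rate = morbidity,
      mean_height = ifelse(sex == "male", 1.755, 1.616),
      mean_weight = 80,
      bmi_mean = 27,
      bmi_sd = 4
    )
}

toy_diseases <- function(ages = 60:62,
                         names = c("ischaemic heart disease", "diabetes"),
                         incidence = c(0.02, 0.01),
                         case_fatality = c(0.05, 0.01),
                         prevalence = c(0.05, 0.08),
                         dw = c(0.35, 0.2),
                         cost = c(9000, 5000),
                         rr = c(1.15, 1.25)) {
  purrr::map_dfr(seq_along(names), function(i) {
    tidyr::expand_grid(sex = c("male", "female"), age = ages) |>
      dplyr::mutate(
        disease = names[i],
        incidence = incidence[i],
        prevalence = prevalence[i],
        case_fatality = case_fatality[i],
        remission = 0,
        rr_per_bmi_unit = rr[i],
        disability_weight = dw[i],
        annual_cost_per_case = cost[i]
      )
  })
}

# Individual-level simulation with the same annual transition semantics as
# the deterministic engine: death during a year contributes half a
# person-year; health-state weights use start-of-year disease states; disease
# processes run in parallel, independent of other-cause death. Returns totals
# and standard errors from the per-individual distribution.
microsim_oracle <- function(population, diseases, n_per_cohort = 5000,
                            seed = 42) {
  set.seed(seed)
  disease_names <- unique(diseases$disease)
  total_ly <- total_haly <- 0
  var_ly <- var_haly <- 0
  prev_end <- setNames(numeric(length(disease_names)), disease_names)
  prev_end_var <- setNames(numeric(length(disease_names)), disease_names)

  for (sx in c("male", "female")) {
    p <- dplyr::arrange(dplyr::filter(population, sex == sx), age)
    K <- nrow(p)
    dis <- purrr::map(disease_names, function(nm) {
      dplyr::arrange(dplyr::filter(diseases, disease == nm, sex == sx), age)
    })
    for (j in seq_len(K)) {
      n <- n_per_cohort
      scale <- p$count[j] / n
      alive <- rep(TRUE, n)
      ly <- haly <- numeric(n)
      state <- purrr::map(seq_along(dis), function(i) {
        prev <- stats::rbinom(n, 1, dis[[i]]$prevalence[j]) == 1
        list(C = prev, D = rep(FALSE, n))
      })
      for (t in 0:(K - j)) {
        ai <- j + t
        if (t == K - j) {
          # start-of-year states in the cohort's final simulated year, the
          # last point the deterministic trajectory records
          for (i in seq_along(dis)) {
            x <- as.numeric(state[[i]]$C)
            prev_end[i] <- prev_end[i] + scale * sum(x)
            prev_end_var[i] <- prev_end_var[i] + scale^2 * n * stats::var(x)
          }
        }
        w <- 1 - p$morbidity_rate[ai]
        for (i in seq_along(dis)) {
          w_i <- dis[[i]]$disability_weight[1]
          w <- w - w_i * (state[[i]]$C & TRUE)
        }
        dies <- alive & (stats::runif(n) < p$mortality_rate[ai])
        py <- ifelse(alive, ifelse(dies, 0.5, 1), 0)
        ly <- ly + py
        haly <- haly + py * w
        alive <- alive & !dies
        for (i in seq_along(dis)) {
          d <- dis[[i]]
          p_i <- 1 - exp(-d$incidence[ai])
          p_f <- 1 - exp(-d$case_fatality[ai])
          S <- !state[[i]]$C & !state[[i]]$D
          new_case <- S & (stats::runif(n) < p_i)
          die_d <- state[[i]]$C & (stats::runif(n) < p_f)
          state[[i]]$C <- (state[[i]]$C | new_case) & !die_d
          state[[i]]$D <- state[[i]]$D | die_d
        }
      }
      total_ly <- total_ly + scale * sum(ly)
      total_haly <- total_haly + scale * sum(haly)
      var_ly <- var_ly + scale^2 * n * stats::var(ly)
      var_haly <- var_haly + scale^2 * n * stats::var(haly)
    }
  }
  list(
    life_years = total_ly, life_years_se = sqrt(var_ly),
    halys = total_haly, halys_se = sqrt(var_haly),
    prevalent_end = prev_end, prevalent_end_se = sqrt(prev_end_var)
  )
}
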