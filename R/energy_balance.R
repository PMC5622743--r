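#' Steady-state energy-balance parameters
#'
#' The model converts a sustained change in daily energy intake to an eventual
#' change in body weight with a linear steady-state rule: one kilogram of body
#' weight per `rho` kJ/day of sustained intake change. Adults (age >=
#' `adult_age_threshold`) use 100 kJ/day per kg, the steady-state rule of
#' thumb of the standard adult weight-change model. Children use sex- and
#' band-specific coefficients consistent with child energy-balance models, in
#' which the same intake change moves weight less in young children.
#'
#' @param rho_adult kJ/day of sustained intake change per kg of steady-state
#'   weight change, adults.
#' @param rho_child Named list of child coefficients by sex and age band.
#' @param adult_age_threshold First adult age (years).
#' @return A list of class `energy_balance_params`.
#' @export
energy_balance_params <- function(rho_adult = 100,
                                  rho_child = list(
                                    male = c("2-12" = 195, "13-19" = 120),
                                    female = c("2-12" = 180, "13-19" = 103)
                                  ),
                                  adult_age_threshold = 20) {
  if (rho_adult <= 0 || any(unlist(rho_child) <= 0)) {
    abort("All energy-balance coefficients must be positive.")
  }
  structure(
    list(rho_adult = rho_adult, rho_child = rho_child,
         adult_age_threshold = adult_age_threshold),
    class = "energy_balance_params"
  )
}

#' Steady-state weight change from a sustained energy-intake change
#'
#' @param delta_kj Change in daily energy intake (kJ/day); vectorised.
#' @param sex `"male"` or `"female"`; recycled against `delta_kj`.
#' @param age Age in years; recycled.
#' @param params An [energy_balance_params()] object.
#' @return Weight change in kg, same sign as `delta_kj`.
#' @export
#' @examples
#' weight_change(-17.5, "male", 40) # adult: -0.175 kg
weight_change <- function(delta_kj, sex, age,
                          params = energy_balance_params()) {
  n <- max(length(delta_kj), length(sex), length(age))
  delta_kj <- rep_len(delta_kj, n)
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  rho <- purrr::map2_dbl(sex, age, function(s, a) {
    if (a >= params$adult_age_threshold) {
      params$rho_adult
    } else {
      params$rho_child[[s]][[age_to_band(a)]]
    }
  })
  delta_kj / rho
}

#' BMI change from a weight change at a given height
#'
#' @param delta_weight Weight change in kg.
#' @param height Height in metres, positive.
#' @return BMI change in kg/m^2.
#' @export
bmi_change <- function(delta_weight, height) {
  if (any(height <= 0)) abort("`height` must be positive.")
  delta_weight / height^2
}

#' Shift the BMI distribution of population strata
#'
#' Applies a location shift to each stratum's BMI distribution: the mean moves
#' by `delta_bmi`, the standard deviation is unchanged.
#'
#' @param population Population tibble (see [generate_population()]).
#' @param delta_bmi BMI shift in kg/m^2, length 1 or `nrow(population)`.
#' @return The population tibble with shifted `bmi_mean`.
#' @export
shift_bmi <- function(population, delta_bmi) {
  shifted <- population$bmi_mean + rep_len(delta_bmi, nrow(population))
  if (any(shifted <= 0)) {
    abort("BMI shift would produce a non-positive mean BMI.")
  }
  population$bmi_mean <- shifted
  population
}

#' Per-age body-weight and BMI shifts from an energy-change table
#'
#' Broadcasts band-level energy-intake changes to single-year ages, converts
#' them to steady-state weight changes with the energy-balance rule, and to
#' BMI changes using each stratum's mean height.
#'
#' @param population Population tibble.
#' @param energy_change Effect tibble from [scenario_effect()] (per sex and
#'   age band).
#' @param params An [energy_balance_params()] object.
#' @return A tibble `sex`, `age`, `delta_kj`, `delta_weight`, `delta_bmi`.
#' @export
#' @examples
#' b <- synthetic_bundle(1)
#' eff <- scenario_effect(b$consumption, b$package_shares, scenario("A1"))
#' body_shift(b$population, eff)
body_shift <- function(population, energy_change,
                       params = energy_balance_params()) {
  population |>
    dplyr::mutate(age_band = age_to_band(.data$age)) |>
    dplyr::left_join(
      dplyr::select(energy_change, "sex", "age_band", "delta_kj"),
      by = c("sex", "age_band")
    ) |>
    dplyr::mutate(
      delta_kj = dplyr::coalesce(.data$delta_kj, 0),
      delta_weight = weight_change(.data$delta_kj, .data$sex, .data$age,
                                   params = params),
      delta_bmi = bmi_change(.data$delta_weight, .data$mean_height)
    ) |>
    dplyr::select("sex", "age", "delta_kj", "delta_weight", "delta_bmi")
}
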