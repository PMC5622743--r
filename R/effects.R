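#' Load the intervention scenario registry
#'
#' Reads the packaged YAML registry of the ten default scenarios (A1–A6 for
#' the single-serve package-size cap, B1–B4 for energy-density reformulation)
#' or a user-supplied registry with the same schema, and validates every
#' entry. Mandatory scenarios carry 100% industry adherence; voluntary ones
#' 20%. Compensation (re-consumption of part of the capped excess) and
#' substitution (a fraction of consumers swapping to 0 kJ alternatives) are
#' mutually exclusive.
#'
#' @param path Optional path to a YAML registry; defaults to the packaged one.
#' @return A tibble with one row per scenario: `id`, `intervention`, `cap`,
#'   `kj_reduction`, `mandatory`, `adherence`, `compensation`,
#'   `substitution`, `description`.
#' @export
#' @examples
#' default_scenarios()
default_scenarios <- function(path = NULL) {
  path <- path %||% system.file("extdata", "scenarios.yaml", package = "ssbcea")
  raw <- yaml::read_yaml(path)$scenarios
  sc <- purrr::map_dfr(raw, function(s) {
    tibble::tibble(
      id = s$id,
      intervention = s$intervention,
      cap = s$cap %||% NA_real_,
      kj_reduction = s$kj_reduction %||% NA_real_,
      mandatory = isTRUE(s$mandatory),
      adherence = s$adherence %||% 1,
      compensation = s$compensation %||% 0,
      substitution = s$substitution %||% 0,
      description = s$description %||% ""
    )
  })
  validate_scenarios(sc)
  sc
}

#' Look up a single scenario by id
#' @param id Scenario id, e.g. `"A1"`.
#' @inheritParams default_scenarios
#' @return A one-row scenario tibble.
#' @export
scenario <- function(id, path = NULL) {
  sc <- default_scenarios(path)
  hit <- sc[sc$id == id, ]
  if (nrow(hit) != 1) {
    abort(sprintf("Unknown scenario id '%s'. Known ids: %s.",
                  id, paste(sc$id, collapse = ", ")))
  }
  hit
}

validate_scenarios <- function(sc) {
  ok_int <- sc$intervention %in% c("package_cap", "energy_reduction")
  if (!all(ok_int)) abort("Unknown intervention type in scenario registry.")
  if (any(sc$compensation > 0 & sc$substitution > 0)) {
    abort("Compensation and substitution are mutually exclusive in a scenario.")
  }
  if (any(sc$adherence <= 0 | sc$adherence > 1)) {
    abort("Scenario adherence must be in (0, 1].")
  }
  bad_kj <- sc$intervention == "energy_reduction" &
    (is.na(sc$kj_reduction) | sc$kj_reduction < 0 | sc$kj_reduction > 1)
  if (any(bad_kj)) abort("`kj_reduction` must be in [0, 1] for reformulation scenarios.")
  bad_cap <- sc$intervention == "package_cap" & (is.na(sc$cap) | sc$cap <= 0)
  if (any(bad_cap)) abort("`cap` must be a positive volume for package-cap scenarios.")
  invisible(sc)
}

check_shares <- function(shares) {
  need <- c("package_size", "single_serve", "volume_share")
  if (!all(need %in% names(shares))) {
    abort("`shares` needs columns package_size, single_serve, volume_share.")
  }
  if (abs(sum(shares$volume_share) - 1) > 1e-6) {
    abort("Package-size volume shares must sum to 1.")
  }
  invisible(shares)
}

#' Volume fraction removed by a single-serve package-size cap
#'
#' For every single-serve package size above the cap, the volume in excess of
#' the cap is expressed as a fraction of that package and weighted by the
#' package's share of all SSB volume sold: the result is the fraction of total
#' SSB volume (equivalently energy, at a common energy density) that the cap
#' removes if consumers move to the capped size without compensating.
#'
#' @param shares Package-size share tibble (see
#'   [generate_consumption()]); volume shares must sum to 1.
#' @param cap Cap volume in mL (default 375).
#' @return A single fraction in \[0, 1\].
#' @export
#' @examples
#' shares <- synthetic_bundle(1)$package_shares
#' excess_volume_fraction(shares)
excess_volume_fraction <- function(shares, cap = 375) {
  check_shares(shares)
  stopifnot_scalar_number(cap, "cap")
  if (cap <= 0) abort("`cap` must be positive.")
  hit <- shares$single_serve & shares$package_size > cap
  sum(shares$volume_share[hit] *
        (shares$package_size[hit] - cap) / shares$package_size[hit])
}

#' Share of SSB volume sold in products affected by the cap
#'
#' The total volume share of single-serve packages above the cap — the reach
#' of the intervention, as opposed to the (smaller) fraction of volume it
#' actually removes.
#'
#' @inheritParams excess_volume_fraction
#' @return A single fraction in \[0, 1\].
#' @export
affected_volume_share <- function(shares, cap = 375) {
  check_shares(shares)
  stopifnot_scalar_number(cap, "cap")
  if (cap <= 0) abort("`cap` must be positive.")
  sum(shares$volume_share[shares$single_serve & shares$package_size > cap])
}

#' Per-stratum energy-intake change under a package-size cap
#'
#' Applies the cap's proportional volume reduction uniformly across age–sex
#' strata (all groups are assumed to consume single-serve sizes in the same
#' proportions), scaled by each stratum's SSB energy intake. Compensation
#' removes part of the excess reduction; substituting consumers (fraction
#' `substitution`) swap to a 0 kJ alternative — by default for all their SSBs
#' (`substitution_scope = "all_ssb"`), optionally only for the affected
#' above-cap products (`"affected_only"`). Voluntary adherence scales the
#' whole effect.
#'
#' @param consumption Consumption profile tibble (per sex and age band).
#' @param shares Package-size share tibble.
#' @param scenario One-row scenario tibble with `intervention = "package_cap"`.
#' @param substitution_scope Scope of the 0 kJ substitution, see Details.
#' @return A tibble `sex`, `age_band`, `ssb_energy`, `delta_kj` with
#'   `delta_kj <= 0`.
#' @export
#' @examples
#' b <- synthetic_bundle(1)
#' package_cap_effect(b$consumption, b$package_shares, scenario("A1"))
package_cap_effect <- function(consumption, shares, scenario,
                               substitution_scope = c("all_ssb", "affected_only")) {
  substitution_scope <- match.arg(substitution_scope)
  if (!identical(scenario$intervention, "package_cap")) {
    abort("`package_cap_effect()` requires a package_cap scenario.")
  }
  excess <- excess_volume_fraction(shares, scenario$cap)
  sub_reach <- switch(substitution_scope,
    all_ssb = 1,
    affected_only = affected_volume_share(shares, scenario$cap)
  )
  frac <- excess * (1 - scenario$compensation) * (1 - scenario$substitution) +
    scenario$substitution * sub_reach
  consumption |>
    dplyr::transmute(
      .data$sex, .data$age_band, .data$ssb_energy,
      delta_kj = -.data$ssb_energy * frac * scenario$adherence
    )
}

#' Per-stratum energy-intake change under reformulation
#'
#' A uniform percentage cut of SSB energy density applies to all SSBs in every
#' stratum, with no compensatory drinking; voluntary adherence scales the
#' effect by the fraction of products reformulated.
#'
#' @inheritParams package_cap_effect
#' @param scenario One-row scenario tibble with
#'   `intervention = "energy_reduction"`.
#' @return A tibble `sex`, `age_band`, `ssb_energy`, `delta_kj`.
#' @export
energy_reduction_effect <- function(consumption, scenario) {
  if (!identical(scenario$intervention, "energy_reduction")) {
    abort("`energy_reduction_effect()` requires an energy_reduction scenario.")
  }
  if (is.na(scenario$kj_reduction) || scenario$kj_reduction < 0 ||
      scenario$kj_reduction > 1) {
    abort("`kj_reduction` must be in [0, 1].")
  }
  consumption |>
    dplyr::transmute(
      .data$sex, .data$age_band, .data$ssb_energy,
      delta_kj = -.data$ssb_energy * scenario$kj_reduction * scenario$adherence
    )
}

#' Dispatch a scenario to its effect-size calculation
#'
#' @inheritParams package_cap_effect
#' @return A tibble `sex`, `age_band`, `ssb_energy`, `delta_kj`.
#' @export
scenario_effect <- function(consumption, shares, scenario,
                            substitution_scope = c("all_ssb", "affected_only")) {
  switch(scenario$intervention,
    package_cap = package_cap_effect(consumption, shares, scenario,
                                     substitution_scope),
    energy_reduction = energy_reduction_effect(consumption, scenario),
    abort("Unknown intervention type.")
  )
}
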