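#' Classify a cost-effectiveness result
#'
#' Applies the usual decision rules on the incremental cost-effectiveness
#' plane: an intervention that saves money and gains health is *dominant* (no
#' ICER reported); one that costs money and gains health is *cost-effective*
#' when its ICER is at or below the willingness-to-pay threshold; one that
#' costs money and loses (or gains no) health is *dominated*. Degenerate
#' cases are classified, never raised: the ICER is undefined when no HALYs
#' are gained.
#'
#' @param net_cost Net cost in AUD (intervention cost plus cost offsets;
#'   offsets are negative when the intervention saves money).
#' @param halys_gained Incremental HALYs.
#' @param wtp Willingness-to-pay threshold in AUD per HALY (default 50,000).
#' @return A tibble `classification`, `icer` (NA when undefined); vectorised.
#' @export
#' @examples
#' classify(-540.9e6, 73883) # dominant
classify <- function(net_cost, halys_gained, wtp = 50000) {
  if (wtp <= 0) abort("`wtp` must be positive.")
  n <- max(length(net_cost), length(halys_gained))
  net_cost <- rep_len(net_cost, n)
  halys_gained <- rep_len(halys_gained, n)
  icer <- ifelse(halys_gained > 0 & net_cost >= 0,
                 net_cost / halys_gained, NA_real_)
  classification <- dplyr::case_when(
    halys_gained > 0 & net_cost < 0 ~ "dominant",
    halys_gained > 0 & icer <= wtp ~ "cost_effective",
    halys_gained > 0 ~ "not_cost_effective",
    net_cost > 0 ~ "dominated",
    TRUE ~ "not_cost_effective"
  )
  tibble::tibble(classification = classification, icer = icer)
}

# discounted cost aggregation from pre-drawn component amounts (AUD millions)
aggregate_cost <- function(scenario, components, amounts, discount_rate) {
  total <- 0
  for (i in seq_len(nrow(components))) {
    comp <- components[i, ]
    if (comp$mandatory_only && !scenario$mandatory) next
    amount <- amounts[i]
    if (comp$scales_with_adherence && scenario$mandatory) amount <- amount * 5
    yrs <- comp$years_active[[1]]
    total <- total + discount(rep(amount / length(yrs), length(yrs)),
                              discount_rate, years = yrs, reference_year = 1)
  }
  total
}

pct_ui <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)

#' Run the full cost-effectiveness analysis with Monte Carlo uncertainty
#'
#' Chains the whole pipeline for each scenario — intervention effect size,
#' energy-balance conversion, multi-state life table, intervention costing —
#' and propagates parameter uncertainty by Monte Carlo simulation. Each
#' iteration draws every cost component from its uncertainty distribution
#' (and, when `vary` includes `"effects"`, a PERT ±20% multiplier on the
#' energy-intake change, rerunning the life table). Uncertainty intervals are
#' 2.5th/97.5th percentiles. One master seed expands to per-iteration
#' substreams, so increasing `n_iterations` never changes earlier draws and
#' identical seeds give identical results.
#'
#' @param bundle An `ssb_bundle` (see [synthetic_bundle()], [read_bundle()]).
#' @param scenarios Scenario tibble; defaults to all ten registry scenarios.
#' @param n_iterations Monte Carlo iterations (default 2000).
#' @param seed Master seed.
#' @param wtp Willingness-to-pay threshold, AUD per HALY.
#' @param discount_rate Annual discount rate for costs and benefits.
#' @param pif_method PIF estimator, see [potential_impact_fraction()].
#' @param vary Character vector of parameter groups sampled per iteration:
#'   `"costs"` (always available) and/or `"effects"`.
#' @param substitution_scope See [package_cap_effect()].
#' @param eb_params Energy-balance parameters.
#' @param components Cost-component tibble.
#' @return An object of class `cea_result` with per-scenario means, 95%
#'   uncertainty intervals, dominance classification and ICERs, plus the
#'   per-iteration draws for the cost-effectiveness plane.
#' @export
#' @examples
#' b <- synthetic_bundle(1)
#' res <- run_cea(b, scenarios = scenario("A1"), n_iterations = 50, seed = 1)
#' tidy(res)
run_cea <- function(bundle, scenarios = default_scenarios(),
                    n_iterations = 2000, seed = 1L, wtp = 50000,
                    discount_rate = 0.03,
                    pif_method = c("mean_shift", "integral"),
                    vary = "costs",
                    substitution_scope = c("all_ssb", "affected_only"),
                    eb_params = energy_balance_params(),
                    components = default_cost_components()) {
  pif_method <- match.arg(pif_method)
  substitution_scope <- match.arg(substitution_scope)
  validate_scenarios(scenarios)
  if (n_iterations < 1) abort("`n_iterations` must be at least 1.")
  bad_vary <- setdiff(vary, c("costs", "effects"))
  if (length(bad_vary) > 0) {
    abort(sprintf("Unknown `vary` group(s): %s.",
                  paste(bad_vary, collapse = ", ")))
  }

  reference <- run_mslt(bundle$population, bundle$diseases,
                        pif_method = pif_method,
                        discount_rate = discount_rate)

  deterministic <- purrr::map(seq_len(nrow(scenarios)), function(k) {
    sc <- scenarios[k, ]
    eff <- scenario_effect(bundle$consumption, bundle$package_shares, sc,
                           substitution_scope)
    bs <- body_shift(bundle$population, eff, params = eb_params)
    out <- run_mslt(bundle$population, bundle$diseases, bshift = bs,
                    pif_method = pif_method, discount_rate = discount_rate)
    cmp <- compare_populations(reference, out, discount_rate)
    list(scenario = sc, effect = eff, comparison = cmp)
  })

  draw_effects <- "effects" %in% vary
  iter <- purrr::map_dfr(seq_len(n_iterations), function(i) {
    set.seed(substream_seed(seed, i))
    amounts <- purrr::map_dbl(seq_len(nrow(components)),
                              function(j) draw_component(components[j, ], 1))
    eff_mult <- if (draw_effects) rpert(1, 0.8, 1, 1.2) else 1
    purrr::map_dfr(seq_along(deterministic), function(k) {
      det <- deterministic[[k]]
      cost <- 1e6 * aggregate_cost(det$scenario, components, amounts,
                                   discount_rate)
      if (draw_effects && eff_mult != 1) {
        eff <- dplyr::mutate(det$effect, delta_kj = .data$delta_kj * eff_mult)
        bs <- body_shift(bundle$population, eff, params = eb_params)
        out <- run_mslt(bundle$population, bundle$diseases, bshift = bs,
                        pif_method = pif_method,
                        discount_rate = discount_rate)
        cmp <- compare_populations(reference, out, discount_rate)
      } else {
        cmp <- det$comparison
      }
      tibble::tibble(
        iteration = i,
        id = det$scenario$id,
        halys_gained = cmp$halys_gained,
        intervention_cost = cost,
        cost_offsets = cmp$cost_offsets,
        net_cost = cost + cmp$cost_offsets
      )
    })
  })

  results <- iter |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      halys_lo = pct_ui(.data$halys_gained)[1],
      halys_hi = pct_ui(.data$halys_gained)[2],
      halys_gained = mean(.data$halys_gained),
      cost_lo = pct_ui(.data$intervention_cost)[1],
      cost_hi = pct_ui(.data$intervention_cost)[2],
      intervention_cost = mean(.data$intervention_cost),
      offsets_lo = pct_ui(.data$cost_offsets)[1],
      offsets_hi = pct_ui(.data$cost_offsets)[2],
      cost_offsets = mean(.data$cost_offsets),
      net_lo = pct_ui(.data$net_cost)[1],
      net_hi = pct_ui(.data$net_cost)[2],
      net_cost = mean(.data$net_cost),
      .groups = "drop"
    ) |>
    dplyr::select("id", "halys_gained", "halys_lo", "halys_hi",
                  "intervention_cost", "cost_lo", "cost_hi",
                  "cost_offsets", "offsets_lo", "offsets_hi",
                  "net_cost", "net_lo", "net_hi")
  cls <- classify(results$net_cost, results$halys_gained, wtp)
  results <- dplyr::bind_cols(results, cls) |>
    dplyr::left_join(
      purrr::map_dfr(deterministic, function(det) {
        dplyr::mutate(det$comparison$deaths_averted[[1]],
                      id = det$scenario$id) |>
          tidyr::nest(deaths_averted = -"id")
      }),
      by = "id"
    ) |>
    dplyr::arrange(match(.data$id, scenarios$id))

  structure(
    list(results = results, draws = iter, wtp = wtp,
         n_iterations = n_iterations, seed = as.integer(seed),
         discount_rate = discount_rate, vary = vary),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %d scenario(s), %d Monte Carlo iteration(s)\n",
              nrow(x$results), x$n_iterations))
  df <- x$results
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %-3s HALYs %10.0f (%0.0f; %0.0f)  net cost %12.1f M AUD  %s\n",
      df$id[i], df$halys_gained[i], df$halys_lo[i], df$halys_hi[i],
      df$net_cost[i] / 1e6, df$classification[i]
    ))
  }
  invisible(x)
}

#' @rdname run_cea
#' @param x,object A `cea_result`.
#' @param ... Unused.
#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) x$results

#' @rdname run_cea
#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x$results),
    n_iterations = x$n_iterations,
    wtp = x$wtp,
    discount_rate = x$discount_rate,
    n_dominant = sum(x$results$classification == "dominant"),
    seed = x$seed
  )
}

#' Cost-effectiveness plane points and quadrant summary
#'
#' One point per Monte Carlo iteration and scenario (incremental HALYs
#' against incremental net cost), with the fraction of draws falling in the
#' dominant quadrant (health gained, money saved) per scenario.
#'
#' @param x A `cea_result`.
#' @return A list with `points` (tibble: `id`, `iteration`, `inc_halys`,
#'   `inc_cost`) and `quadrants` (tibble: `id`, `dominant_fraction`).
#' @export
ce_plane <- function(x) {
  if (!inherits(x, "cea_result")) abort("`x` must be a cea_result.")
  points <- x$draws |>
    dplyr::transmute(.data$id, .data$iteration,
                     inc_halys = .data$halys_gained,
                     inc_cost = .data$net_cost)
  quadrants <- points |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      dominant_fraction = mean(.data$inc_halys > 0 & .data$inc_cost < 0),
      .groups = "drop"
    )
  list(points = points, quadrants = quadrants)
}

#' @rdname run_cea
#' @method autoplot cea_result
#' @export
autoplot.cea_result <- function(object, ...) {
  pts <- ce_plane(object)$points
  ggplot2::ggplot(pts,
                  ggplot2::aes(.data$inc_halys, .data$inc_cost / 1e6,
                               colour = .data$id)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Incremental HALYs", y = "Incremental cost (AUD M)",
                  colour = "Scenario",
                  title = "Cost-effectiveness plane")
}

#' @rdname ce_plane
#' @param ... Passed on.
#' @export
plot_ce_plane <- function(x, ...) autoplot(x, ...)
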