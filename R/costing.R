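#' Default intervention cost components
#'
#' The four implementation cost components (2010 AUD millions), their payers,
#' uncertainty distributions and time profiles:
#'
#' * passing legislation (government): 1.0 M, gamma with 95% CI 0.9–1.2,
#'   incurred once in year 1, mandatory scenarios only;
#' * administration, enforcement, promotion and monitoring (government):
#'   12.3 M, PERT ±50%, spread over years 1–5, mandatory only;
#' * packaging and reformulation changes (industry): 36.9 M, PERT ±50%,
#'   years 1–2; stated at the 20%-adherence level and scaled fivefold for
#'   mandatory scenarios;
#' * advocacy, marketing and promotion (NGOs): 5.5 M, PERT ±50%, years 1–2,
#'   applied to every scenario.
#'
#' Stated means are totals spread evenly across active years.
#'
#' @return A tibble with one row per component: `name`, `payer`, `mean`,
#'   `dist`, `params` (list), `years_active` (list), `mandatory_only`,
#'   `scales_with_adherence`.
#' @export
default_cost_components <- function() {
  tibble::tibble(
    name = c("legislation", "administration_monitoring",
             "industry_packaging_reformulation", "ngo_advocacy"),
    payer = c("government", "government", "industry", "ngo"),
    mean = c(1.0, 12.3, 36.9, 5.5),
    dist = c("gamma_mean_ci", "pert_pct_range", "pert_pct_range",
             "pert_pct_range"),
    params = list(
      list(mean = 1.0, ci_lower = 0.9, ci_upper = 1.2),
      list(mode = 12.3, pct_range = 0.5),
      list(mode = 36.9, pct_range = 0.5),
      list(mode = 5.5, pct_range = 0.5)
    ),
    years_active = list(1L, 1:5, 1:2, 1:2),
    mandatory_only = c(TRUE, TRUE, FALSE, FALSE),
    scales_with_adherence = c(FALSE, FALSE, TRUE, FALSE)
  )
}

#' Sample a PERT distribution
#'
#' The (modified) PERT distribution on `[min, max]` with the given mode: a
#' scaled Beta with `alpha = 1 + shape (mode - min)/(max - min)` and
#' `beta = 1 + shape (max - mode)/(max - min)`.
#'
#' @param n Number of draws.
#' @param min,mode,max Bounds and mode, `min <= mode <= max`.
#' @param shape PERT shape parameter (4 = classic).
#' @return `n` draws in `[min, max]`.
#' @export
rpert <- function(n, min, mode, max, shape = 4) {
  if (!(min <= mode && mode <= max)) abort("Need min <= mode <= max.")
  if (min == max) return(rep(min, n))
  a <- 1 + shape * (mode - min) / (max - min)
  b <- 1 + shape * (max - mode) / (max - min)
  min + (max - min) * rbeta(n, a, b)
}

# gamma (shape, rate) with the stated mean whose 2.5/97.5 percentiles best
# match the stated CI, fitted by least squares on the log-shape
fit_gamma_mean_ci <- function(mean, ci_lower, ci_upper) {
  if (!(ci_lower < mean && mean < ci_upper)) {
    abort("Gamma CI bounds must bracket the mean.")
  }
  obj <- function(log_shape) {
    shape <- exp(log_shape)
    q <- qgamma(c(0.025, 0.975), shape = shape, rate = shape / mean)
    sum((q - c(ci_lower, ci_upper))^2)
  }
  shape <- exp(optimize(obj, c(-2, 15))$minimum)
  c(shape = shape, rate = shape / mean)
}

#' Draw from a cost component's uncertainty distribution
#'
#' Uses the caller's RNG stream (set a seed outside for reproducibility).
#' `gamma_mean_ci` draws from a gamma with the stated mean whose 2.5/97.5
#' percentiles approximate the stated CI; `pert_pct_range` from a PERT on
#' `mode * (1 ± range)`; `point` returns the mean.
#'
#' @param component One row of [default_cost_components()].
#' @param n Number of draws.
#' @return `n` draws in AUD millions.
#' @export
draw_component <- function(component, n = 1) {
  p <- component$params[[1]]
  switch(component$dist,
    point = rep(component$mean, n),
    gamma_mean_ci = {
      fit <- fit_gamma_mean_ci(p$mean, p$ci_lower, p$ci_upper)
      rgamma(n, shape = fit[["shape"]], rate = fit[["rate"]])
    },
    pert_pct_range = rpert(n, p$mode * (1 - p$pct_range), p$mode,
                           p$mode * (1 + p$pct_range)),
    abort(sprintf("Unknown distribution family '%s'.", component$dist))
  )
}

#' Total discounted intervention cost for a scenario
#'
#' Aggregates the cost components under the scenario's implementation mode:
#' mandatory scenarios include the government components and scale
#' adherence-dependent components fivefold (their stated means correspond to
#' 20% adherence); voluntary scenarios exclude mandatory-only government
#' components and take adherence-dependent components at their stated level.
#' Each component's amount is spread evenly over its active years and
#' discounted with year 1 as the reference year.
#'
#' @param scenario One-row scenario tibble.
#' @param components Cost-component tibble, see [default_cost_components()].
#' @param discount_rate Annual discount rate.
#' @param draw Draw each component from its uncertainty distribution
#'   (`TRUE`) or use the stated means (`FALSE`).
#' @return Total discounted cost in AUD millions.
#' @export
#' @examples
#' scenario_cost(scenario("A1"), default_cost_components())
scenario_cost <- function(scenario, components = default_cost_components(),
                          discount_rate = 0.03, draw = FALSE) {
  total <- 0
  for (i in seq_len(nrow(components))) {
    comp <- components[i, ]
    if (comp$mandatory_only && !scenario$mandatory) next
    amount <- if (draw) draw_component(comp, 1) else comp$mean
    if (comp$scales_with_adherence && scenario$mandatory) {
      amount <- amount * 5
    }
    yrs <- comp$years_active[[1]]
    total <- total + discount(rep(amount / length(yrs), length(yrs)),
                              discount_rate, years = yrs, reference_year = 1)
  }
  total
}
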