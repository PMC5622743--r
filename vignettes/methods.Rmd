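---
title: "Modelling portion-size interventions on sugar-sweetened beverages: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling portion-size interventions on sugar-sweetened beverages: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbcea)
```

## The model in one paragraph

`ssbcea` estimates the lifetime health and economic consequences of two
interventions on sugar-sweetened beverages (SSBs) — a 375 mL cap on
single-serve package sizes and reformulation to a lower energy density — for
a closed population of single-year age–sex cohorts aged 2–100. A scenario is
translated into a per-stratum change in mean daily energy intake; a
steady-state energy-balance rule converts that into body-weight and BMI
changes; a potential impact fraction converts the BMI shift into reduced
incidence of nine obesity-related diseases; a proportional multi-state life
table propagates the changed disease epidemiology into health-adjusted life
years (HALYs) and health-care costs; and a costing and Monte Carlo layer
produces net costs, dominance classifications and ICERs with 95%
uncertainty intervals.

## Effect sizes

For the package cap with cap volume $c$ and package-size volume shares
$w_s$, the proportional volume (equivalently energy, at a common energy
density) removed is

$$ e(c) = \sum_{s > c,\ \text{single-serve}} w_s \frac{s - c}{s}, $$

applied uniformly to every stratum's SSB energy intake — all age and sex
groups are assumed to buy package sizes in the same proportions, an
assumption forced by the absence of stratified sales data. Scenario
modifiers enter as

$$ \Delta E = -E_{\text{SSB}} \left[ e(c)(1 - \kappa)(1 - \sigma) + \sigma \right] \alpha, $$

with compensation $\kappa$ (a fraction of the removed excess re-consumed in
other formats), substitution $\sigma$ (a fraction of consumers swapping to
0 kJ alternatives) and adherence $\alpha$ (1 for legislated scenarios, 0.2
for voluntary pledges). Reformulation is simpler:
$\Delta E = -E_{\text{SSB}} \, r \, \alpha$ for a fractional energy cut
$r$ (0.05 or 0.30), with no compensatory drinking.

**Substitution scope.** Whether the 10% of substituting consumers drop all
of their SSB energy or only the above-cap single-serve products is genuinely
open. We default to the broader reading (`substitution_scope = "all_ssb"`):
substituters move wholesale to 0 kJ alternatives, and the remaining 90%
receive the cap's excess reduction. The narrow reading
(`"affected_only"`, in which substituters only drop the affected products)
is implemented behind the same switch. The broad reading is the default
because substitution scenarios are reported to yield several-fold larger
health gains than the base cap, which only wholesale substitution can
produce; under the narrow reading the substitution scenarios barely differ
from the base case.

## Energy balance

A sustained intake change $\Delta E$ (kJ/day) maps to a steady-state weight
change $\Delta w = \Delta E / \rho$. For adults (age ≥ 20) we use
$\rho = 100$ kJ/day per kg, the steady-state rule of thumb of the standard
adult weight-change model; it reproduces the published adult
energy-to-weight pairs at two-decimal rounding (−17.5 kJ/day → −0.17 kg,
−27.9 → −0.28). Child models imply larger $\rho$ (a given intake change
moves weight less); we back-fit band- and sex-specific defaults from the
published child rows: 195 (boys 2–12), 180 (girls 2–12), 120 (boys 13–19)
and 103 (girls 13–19) kJ/day per kg. These are exposed in
`energy_balance_params()` and should be treated as approximations: the
underlying child equations are not reproducible from published band-level
means, and the female 2–12 back-fit (≈180) differs from the male one.

The weight change is applied as a location shift of the stratum BMI
distribution ($\Delta \text{BMI} = \Delta w / h^2$ at the stratum mean
height; standard deviation unchanged), constant from the first simulated
year for life — both interventions alter the food supply itself, so the
intake change is treated as permanent.

## Potential impact fractions

Disease incidence responds to a BMI shift through a log-linear relative
risk $RR$ per +1 kg/m²:

$$ \text{PIF} = 1 - RR^{\Delta \text{BMI}} \quad (\texttt{mean\_shift}), $$

the exact result when the whole distribution translates and risk is
log-linear. The alternative `integral` method evaluates
$1 - \int RR^x f^*(x)\,dx / \int RR^x f(x)\,dx$ with $f$ a lognormal
matched to the stratum's BMI mean and SD and $f^*$ the same lognormal with
the shifted mean. Because $RR^x$ grows exponentially while the lognormal
tail decays sub-exponentially, that integral has no finite value on an
unbounded support; we truncate at the $10^{-10}$ and $1-10^{-10}$ quantiles
of each density. The two methods agree to $10^{-6}$ as the BMI spread
vanishes (a test enforces this) and differ by a few percent at realistic
spreads. `mean_shift` is the default: it is cheap, closed-form, and makes
no distributional assumption beyond log-linearity. Relative risks apply to
incidence only, not to case fatality.

## The proportional multi-state life table

Each disease runs as an independent three-state annual process
(susceptible → prevalent at incidence adjusted by the PIF; prevalent → dead
at case fatality; prevalent → susceptible at remission, zero by default)
within each cohort, *proportionally* — disease-state proportions are
tracked conditionally on surviving other causes, so the processes do not
interact except through the main table. Rates convert to annual
probabilities as $p = 1 - e^{-\text{rate}}$; any derived transition
probability outside $[0,1]$ aborts the run. Within a process,
susceptible + prevalent + cumulative disease deaths is conserved exactly (a
property test requires $10^{-9}$ relative).

The main table ages each cohort with all-cause mortality; for the
intervention population the mortality probability is perturbed by the
grouped difference in disease-death probabilities between intervention and
reference processes (grouped so that a null intervention perturbs mortality
by *exactly* zero, giving exact zero HALY gains — another enforced
invariant). Person-years use a half-cycle correction,
$L_t = (l_t + l_{t+1})/2$, since deaths occur throughout a year. HALYs
weight person-years by
$1 - \text{background morbidity} - \sum_d \text{prev}_d \cdot dw_d$, where
the background morbidity rate excludes the nine modelled diseases (their
disability is added explicitly, which keeps the decomposition exact and
avoids double counting). Health costs accrue per prevalent person-year;
cost offsets are the discounted difference in those streams and are
negative when the intervention saves money.

Simulation year 0 is the reference year for discounting benefits (default
rate 3%/yr); intervention effects start in the first simulated year and the
model runs every cohort to age 100.

The deterministic engine is cross-checked against a seeded individual-level
microsimulation with identical transition semantics on a three-cohort,
two-disease configuration; totals and final state counts must agree within
three standard errors of the microsimulation.

## Intervention costs

Four components (2010 AUD millions): legislation (1.0; gamma with 95% CI
0.9–1.2; year 1; mandatory scenarios only), government administration and
monitoring (12.3; PERT ±50%; years 1–5; mandatory only), industry packaging
and reformulation (36.9; PERT ±50%; years 1–2), and NGO advocacy (5.5;
PERT ±50%; years 1–2; all scenarios). The gamma is parameterised by fixing
its mean and least-squares matching its 2.5/97.5 percentiles to the stated
CI; the PERT is the classic shape-4 Beta rescaled to mode × (1 ± 0.5).

The published totals (≈210 M mandatory, ≈44.5 M voluntary) are not exactly
reconstructible from the component table alone, so an explicit aggregation
rule is fixed and validated only against the published 95% intervals:
industry costs are stated at the 20%-adherence level and scaled fivefold
for mandatory scenarios; government components appear only in mandatory
scenarios; NGO costs always at the stated level; each stated mean is a
total spread evenly over its active years; the stream is discounted at 3%
with year 1 as the reference. Under this rule the mandatory total is
≈200 M and the voluntary ≈42 M, inside the published intervals. The rule
lives in `default_cost_components()`/`scenario_cost()` and can be
overridden per run.

## Uncertainty analysis

Monte Carlo simulation (default 2000 iterations) draws every cost component
per iteration; 95% uncertainty intervals are non-parametric 2.5/97.5
percentiles. A master seed expands into per-iteration substreams, so
results are bit-reproducible and extending the iteration count never
changes earlier draws. By default only cost parameters are sampled — the
published account does not enumerate which effect parameters were varied —
so HALY intervals are degenerate unless `vary = c("costs", "effects")` is
set, which adds a PERT ±20% multiplier on the energy-intake change and
reruns the life table per iteration. Classification uses the conventional
quadrants: dominant (saves money, gains health), cost-effective (ICER at or
below AUD 50,000/HALY), not cost-effective, dominated.

## The synthetic-data generator

The generator replaces four proprietary inputs with seeded, validated
tables:

* **Population**: single-year cohorts 2–100 by sex, with a plausible
  population pyramid, Gompertz-type mortality (forced non-decreasing beyond
  age 40), slowly rising background morbidity, growth-curve heights and an
  adult BMI plateau in the high 20s.
* **Diseases**: the nine obesity-related diseases (ischaemic heart disease,
  hypertensive heart disease, ischemic stroke, diabetes, colorectal cancer,
  kidney cancer, breast cancer, endometrial cancer, osteoarthritis) with
  logistic age ramps for incidence, disease-typical case fatality,
  disability weights and annual costs, and BMI relative risks that taper in
  old age. The defaults deliberately give ischaemic heart disease the
  largest RR × burden so the leading cause of averted deaths matches what
  such models consistently find.
* **Consumption**: mean daily SSB energy by sex and age band
  (2–12, 13–19, ≥20 — the resolution at which intake data are reported),
  broadcast flat to single-year ages; a single energy density of
  1.6 kJ/mL (600 kJ per 375 mL serve) converts volume and energy.
* **Package-size shares**: volume shares on a size grid
  {250, 375, 400, 450, 500, 600, 1250, 2000} mL with single-serve flags on
  sizes ≤ 600 mL.

With `calibrate = TRUE` the consumption table reproduces the
published band-level baseline intakes exactly, and the share table is
pinned to three marginals: 27% of SSB volume is single-serve, 59% of
single-serve volume exceeds 375 mL, and the allocation across the
above-cap sizes is solved so the share-weighted excess-volume fraction
equals the published population-mean energy reduction (14.4 of
564.4 kJ/day). That last constraint requires an excess ratio of ≈0.160,
below the minimum attainable on a {450, 500, 600} grid (0.1667), which is
why the grid includes a 400 mL size; the solved allocation then reproduces
every published per-band energy change for the cap at printed precision.

What the generator does **not** emulate: survey weighting and sampling
error; within-band age gradients of SSB intake (the flat broadcast is a
declared simplification — the true single-year profile is unknown);
real disease epidemiology, costs per prevalent case, or cohort sizes.
Consequently absolute HALY and cost-offset magnitudes are not comparable to
published totals, and the tests treat them as such: the acceptance checks
pin down the desk-verifiable arithmetic (effect sizes, energy balance,
sales-mix marginals, cost distributions) and replace the headline totals
with structural properties — exact null-intervention zeros, conservation,
microsimulation agreement, scenario ordering (30% cut > 5% cut,
mandatory > voluntary) and local linearity of HALY gains in the BMI shift.
Passing them shows the machinery is right, not that the synthetic inputs
are Australia.

## Numerical choices and problem sizes

* Annual cycles with half-cycle correction; no within-year interpolation.
* Rates → probabilities via $1 - e^{-\text{rate}}$; guards abort on
  probabilities outside $[0,1]$ after mortality adjustment (tolerance
  $10^{-9}$ before clamping).
* Degenerate inputs are classified, not raised, in the economics layer
  (zero HALYs → ICER undefined, dominated when costly); generator and
  life-table inputs are validated up front by `validate_bundle()`.
* The test suite runs full-size life tables (2 × 99 cohorts, 9 diseases)
  where the check needs them and small toys (3 cohorts, ≤ 2 diseases)
  elsewhere; the microsimulation cross-check uses 4,000 individuals per
  cohort in the unit test and 50,000 in the acceptance test. The default
  uncertainty analysis (cost-only sampling) reuses the deterministic life
  table across iterations, so 2000 iterations over all ten scenarios run
  in well under a minute.

## Known limitations

* Steady-state energy balance, applied from year 1: no dynamic weight
  trajectory, so early-year HALY gains are slightly front-loaded relative
  to a dynamic model.
* Proportional disease processes ignore co-morbidity interactions.
* The BMI-independent effect of obesity on quality of life is not
  modelled (no published parameters to implement it against).
* No trend projection of future incidence; no price/elasticity or revenue
  redistribution modelling; no equity or subgroup analysis.
* The voluntary-adherence figure (20%) and the compensation/substitution
  fractions are scenario assumptions, not estimates; the scenario registry
  exists precisely so they can be varied.
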