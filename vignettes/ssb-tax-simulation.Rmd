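---
title: "Simulating beverage-tax effects on energy intake, weight and obesity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating beverage-tax effects on energy intake, weight and obesity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbtax)
```

## The model

ssbtax is an ex-ante micro-simulation of an ad-valorem tax on
sugar-sweetened beverages (SSBs) in an adult population. The causal chain
is the standard one used in beverage-tax health-impact models:

1. **Price.** A tax at rate $t$ with pass-through $\rho$ raises the
   retail price of every taxed category by $\Delta p = 100\,t\rho$
   percent; untaxed categories are unaffected
   (`price_change()`).
2. **Demand.** With own- and cross-price elasticities $\varepsilon_{ji}$
   (the % change in demand for beverage $j$ per 1% price change of
   beverage $i$), the demand response is, to first order,
   $$\%\Delta q_j = \sum_i \varepsilon_{ji}\, \%\Delta p_i,$$
   applied multiplicatively to each individual's baseline daily volume
   and floored at zero (`consumption_shift()`). The same percentage
   change applies to every individual; heterogeneity in the absolute
   effect comes entirely from baseline consumption levels.
3. **Energy.** The daily energy-intake change of person $k$ is
   $\Delta E_k = \sum_j \Delta q_{kj}\, d_j$ with $d_j$ the category
   energy density in kcal/mL (`energy_change()`). Because cross-price
   terms shift volume into untaxed caloric beverages, $\Delta E_k$ can be
   positive.
4. **Weight.** A simplified steady-state energy-balance rule converts a
   sustained intake change into weight change: 100 kJ/day per kg of
   steady-state weight, $\Delta w_{ss} = \Delta E \cdot 4.184 / 100$,
   with an exponential approach to the new steady state that attains 95%
   of $\Delta w_{ss}$ at the 3-year evaluation horizon
   (`steady_state_weight_change()`, `weight_change_at_horizon()`).
   Height is constant, so $\Delta \mathrm{BMI} = \Delta w / h^2$
   (`apply_weight_change()`).
5. **Prevalence.** BMI is classified with the adult cut-offs
   (overweight $25 \le \mathrm{BMI} < 30$, obesity
   $\mathrm{BMI} \ge 30$), and survey-weighted prevalences are compared
   pre/post tax per sex and age stratum, reported as relative changes in
   percent with percentile-bootstrap confidence intervals
   (`prevalence_change()`, `bootstrap_ci()`, `run_scenario()`).

Assumptions worth keeping in view: no energy-expenditure or
physical-activity feedback; one elasticity matrix for the whole
population (no differentiation by sex, age or income); a linear
intake–weight relationship with a single new steady state; and
self-report-style anthropometry at baseline.

### Two model-form choices that were genuinely open

**Elasticity application.** "A 1% price change moves demand by
$\varepsilon$%" can be read linearly
($\%\Delta q = \varepsilon \cdot \%\Delta p$) or as a
constant-elasticity (log) response
($q' = q \prod_i (1+\Delta p_i/100)^{\varepsilon_{ji}}$). The package
defaults to the linear first-order reading and exposes the log form via
`consumption_shift(form = "log")`. Under the linear form the
pass-through sensitivity is exactly proportional: every individual's
$\Delta E$ at 80% pass-through is $0.8\times$ the 100% value — a
property the test suite asserts to machine precision. (Published
sensitivity ratios in this literature are often slightly above the
pass-through ratio, which hints at nonlinear application; with the log
form here the ratio at a 20% tax is $\approx 0.84$ rather than 0.80.)

**Time course.** The two commonly quoted anchors of the simplified
energy-balance rule — half the change within about a year, 95% within
about three — are mutually inconsistent for a single exponential (50% at
1 y implies 89%, not 95%, at 3 y). The applied contrafactual here uses
only the 3-year/95% anchor: `weight_model_params()` calibrates the time
constant $\tau$ so that $1-e^{-3/\tau} = 0.95$ exactly, and the horizon
evaluation is therefore exactly $0.95\,\Delta w_{ss}$ at 3 years.

### Prevalence accounting

The whole population is classified before and after the tax, so
individuals can enter overweight from below just as they can progress to
obesity; the alternative reading (only those already overweight/obese at
baseline are followed, entry barred) is available via
`prevalence_change(..., restrict_to_baseline_excess = TRUE)`. The open
accounting is the default because barred entry makes a rise in
overweight prevalence impossible, while rising overweight under
substitution-driven calorie gains is exactly the behaviour such models
report. Note one consequence for interpretation: the *overweight-only*
band can move non-monotonically, because a growing obese class drains
the top of the overweight band while new entrants arrive at the bottom;
the combined $\mathrm{BMI} \ge 25$ measure is the monotone one.

## The synthetic population

Real consumption (household-budget survey recall) and anthropometry
(health-survey) microdata are not shipped; `generate_population()`
creates a seeded stand-in whose *stratum structure* matches the printed
adult baselines of the Brazilian population the model targets:

* overall SSB volume 176 mL/person/day carrying 67 kcal/day;
* soft drinks 65% of SSB volume, other sugary drinks 20%, sweetened milk
  drinks 10%, sports/energy drinks 5% (the last three are package
  assumptions within the printed total);
* a monotone age gradient from 268.6 mL/day (20–29) to 105.5 mL/day
  (70+), interpolated with a power curve whose exponent is solved at
  configuration time so the age-share-weighted mean is exactly 176;
* male/female means 208/153 mL/day, applied as sex factors normalised
  within each age band;
* non-sweetened caloric beverages (milk, fruit juice, coffee/tea —
  water excluded) 576 mL/day and 153 kcal/day, with fruit juice plus
  coffee/tea at 94% of that volume, and an *increasing* age ramp
  (450→720 mL/day before rescaling) reflecting higher milk and coffee
  intake at older ages — the feature that drives the substitution-led
  calorie gain in older strata;
* energy densities (kcal/mL): soda 0.37, sweetened milk drinks 0.60,
  sports/energy 0.35, other SSBs 0.32, milk 0.61, juice 0.45, coffee/tea
  0.15, water 0. These are defaults solved so the volume mix lands the
  two printed volume↔energy pairs within 1%; all overridable per
  catalogue.

Per-category daily volumes are zero-inflated gamma: a category-specific
probability of zero intake on the recall day (e.g. 0.45 for soda, 0.15
for coffee/tea, defaults chosen to mimic one-day dietary recalls) and a
gamma with shape 0.8 (consumer-level CV ≈ 1.1) for the rest, with the
stratum mean matched exactly in expectation. BMI is lognormal per sex
with parameters solved in closed form from two exceedance targets,
defaults $P(\mathrm{BMI}\ge25)$ = 0.57 (men) / 0.62 (women) and
$P(\mathrm{BMI}\ge30)$ = 0.22 / 0.30 — assumptions consistent with
roughly 60% excess weight and 27% obesity overall. Heights are normal
per sex (1.73/1.61 m, SD 0.07/0.065); weight is $\mathrm{BMI}\cdot h^2$.
Survey weights are mildly heterogeneous (gamma, shape 4) and normalised
to an expansion total of 152 million adults, so weighted-estimator code
paths are genuinely exercised. Consumption and BMI are independent by
default, matching a model that applies the same percentage consumption
change at every BMI.

What the generator does **not** emulate: the complex survey design
(strata/PSU clustering — weights here are independent), within-person
day-to-day intake correlation, consumption–BMI correlation, and any
income dimension. Passing calibration tests therefore show that the
pipeline's estimators recover the intended stratum structure, not that
the package reproduces the original microdata results; those depend on
the unpublished estimated elasticity matrix, which users must supply for
replication.

## The illustrative elasticity matrix

`default_elasticities()` is labelled illustrative, not estimated:
own-price −1.0 for the four SSB classes, −0.7 for untaxed categories
(inert unless you tax them), a total cross-price response of +0.7 from
the taxed group spread evenly over the three untaxed caloric beverages,
and +0.05 toward water. With the baseline means above, a 20% fully
passed-through tax gives an overall energy change of roughly
$0.2\times(-67 + 0.7\times153) \approx +8$ kcal/day — taxed intake
falls, substitution overshoots in energy terms — and the age profile
flips sign between 20–29 (heavy SSB, light substitutes) and the older
bands, the qualitative pattern such simulations report. Because the
cross terms act on the *volume* of untaxed beverages, whose energy
density is higher on average at older ages' consumption mix, the only
net calorie-reducing stratum is 20–29.

## Numerical and reproducibility choices

* One master seed per `run_config()`; stage seeds by fixed offsets
  (population +1000, bootstrap +2000). All randomness flows through a
  seed-scoped RNG helper that restores the caller's stream.
* Shifted consumption is floored at 0; floored entries are counted and
  logged. Post-tax weight is floored at 30 kg, binding only for
  individuals at/above the floor at baseline (the floor never raises
  anyone); clamped counts are reported with a warning.
* Bootstrap: nonparametric percentile over individuals, 2.5/97.5
  percentiles; default 1000 replicates for `bootstrap_ci()` and 500 for
  the full report tables in `run_scenario()` (three tables × 21 strata
  recomputed per replicate). The test suite uses 50–400 replicates and
  populations of 300–50,000; calibration checks use 50,000, the size at
  which the 5% calibration tolerance is comfortably met.
* Degenerate inputs: zero-target configurations produce exact-zero
  consumption; zero baseline prevalence reports `NA` relative change
  with a warning rather than dividing by zero; empty strata are omitted.

## Known limitations

* The default elasticity matrix is illustrative; every quantitative
  output at default settings is a property of that matrix plus the
  synthetic baselines, not an estimate for any real population.
* No elasticity uncertainty is propagated; bootstrap CIs reflect
  sampling of individuals only.
* The energy-balance rule is the simplified steady-state one: no
  fat/lean partitioning, no adaptive thermogenesis, no sex-specific
  equations.
* Survey-design variance (clustering, stratification) is not modelled;
  CIs are i.i.d.-bootstrap CIs.

## A complete run

```{r, eval = FALSE}
cfg <- run_config(
  population = population_config(),   # 50,000 synthetic adults
  scenarios = list(tax_scenario(0.20), tax_scenario(0.25), tax_scenario(0.30)),
  seed = 1
)
results <- lapply(cfg$scenarios, function(s) run_scenario(cfg, s))
render_reports(results, "reports")
sens <- run_sensitivity(cfg, pass_through_values = c(1, 0.8))
sens$comparison
```
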