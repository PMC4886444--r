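---
title: "Model and methods: a beverage tax and the burden of stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a beverage tax and the burden of stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbstroke)
```

## Overview

`ssbstroke` estimates the effect of a price increase on sugar-sweetened
beverages (SSBs) on the population burden of stroke, using a proportional
multi-state life table. The causal chain is:

1. **Tax → price.** A tax rate $\tau$ with pass-on rate $\rho$ raises
   consumer prices by $\Delta p = \tau\rho$.
2. **Price → consumption.** Own- and cross-price elasticities translate
   the price change into millilitre changes for four beverage classes
   (SSBs, fruit juice, milk, artificially sweetened beverages).
3. **Consumption → energy.** Energy densities (kJ/l) convert millilitre
   changes to a net change in daily energy intake per stratum.
4. **Energy → weight → BMI.** An equilibrium energy-balance constant
   ($k$ kJ/day per kg) gives the steady-state weight change, divided by
   height squared to give a BMI change.
5. **BMI → risk.** The BMI distribution of each age–sex stratum is modelled
   as log-normal; shifting it and integrating a relative-risk curve over
   both densities yields a potential impact fraction (PIF) for stroke
   incidence.
6. **Risk → burden.** The PIF scales stroke incidence in the intervention
   arm of a multi-state life table that follows all cohorts to age 100,
   tracking cases, deaths, (health-adjusted) life years and costs.

Outcomes are differences between a reference arm (no tax) and an
intervention arm that are otherwise identical, so all structural
assumptions cancel except the incidence reduction itself.

## Demand model

For beverage $b$ with baseline intake $Q_b$ (ml/day) and price elasticity
$\varepsilon_b$ (own-price for SSBs, cross-price for the others), the
default linear first-order response is

$$\Delta Q_b = s \, Q_b \, \varepsilon_b \, \Delta p,$$

where $s$ is an optional portion-size scaling (ratio of the assumed serving
volume to the 330 ml reference). An iso-elastic alternative,
$\Delta Q_b = Q_b\left[(1+\Delta p)^{\varepsilon_b} - 1\right]$, is
available via `tax_scenario(demand_form = "isoelastic")`; for a 20% price
change the two differ by roughly 10% in magnitude. The net energy change is
$\Delta E = \sum_b \Delta Q_b \, d_b / 1000$ with $d_b$ in kJ/l
(defaults: SSB 1800, juice 1340, milk 2540, diet 0). Substitution toward
juice and milk partially offsets the SSB energy reduction; the diet class
carries no energy.

## Energy balance and the BMI distribution

Weight change at the new steady state is $\Delta w = \Delta E / k$ with
$k = 94$ kJ/day per kg (SD 2.96 in the uncertainty analysis), and
$\Delta \mathrm{BMI} = \Delta w / h^2$ with $h$ the mean height of the sex
group. Stratum BMI is log-normal with parameters fitted by the method of
moments:

$$\sigma^2 = \ln\!\left(1 + \mathrm{sd}^2/\mathrm{mean}^2\right), \qquad
  \mu = \ln(\mathrm{mean}) - \sigma^2/2.$$

Shifts are additive on the natural scale. Because dispersion co-varies with
the mean, the standard deviation moves with the mean via a slope estimated
from two synthetic survey waves by regression through the origin
(`estimate_sd_slope()`). An optional secular BMI trend (kg/m² per year)
applies to **both** arms, so it widens the PIF over time without itself
creating a treatment effect.

## Potential impact fraction

The relative risk of stroke at BMI $x$ is
$RR(x) = r^{(x - x_0)/5}$ for $x > x_0$ and $1$ otherwise, with threshold
$x_0 = 21$ and $r$ the per-5-unit risk ratio for the age–sex stratum. The
PIF is

$$\mathrm{PIF} = \frac{E_{\mathrm{ref}}[RR] - E_{\mathrm{int}}[RR]}
                       {E_{\mathrm{ref}}[RR]},$$

with expectations over the reference and shifted BMI densities. The
integral is evaluated in standard-normal $z$-space: the sub-threshold mass
contributes exactly $\Phi(z_0)$, and the remainder is integrated with
adaptive quadrature (`stats::integrate`, relative tolerance $10^{-8}$) or,
for the many evaluations inside Monte Carlo loops, a cached 96-node
Gauss–Legendre rule; the two routes agree to $10^{-8}$ and the fast route
is the default. The integrand is truncated at BMI 80 and $|z| \le 10$,
which discards mass far below double precision at any realistic dispersion.
Identical reference and intervention distributions give a PIF of exactly
zero by construction, not merely to rounding — a property the test suite
asserts bitwise.

The PIF is applied to stroke incidence **by current age band as cohorts
age** (cross-sectionally), so a cohort entering at 15–19 picks up the
40–44 PIF when it reaches that age.

## Life table

Each of the 34 age–sex cohorts (5-year bands 15–19 to 95–99, entering at
the band midpoint) is simulated by single year of age to 100. Annual rates
become probabilities via $p = 1 - e^{-\text{rate}}$. Within a cycle, the
ordering is:

1. incident cases leave the susceptible pool (incidence scaled by
   $1-\mathrm{PIF}$ in the intervention arm);
2. a fraction $d_{28}$ of new cases dies within 28 days and never enters
   the prevalent pool;
3. case fatality applies to the prevalent pool;
4. other-cause mortality applies proportionally to all survivors.

Persons are conserved exactly: start = end + deaths, enforced to
$10^{-9}$ in tests over randomised rate sets. Life years and prevalent
cases use mid-year conventions. Health-adjusted life years subtract both a
background disability rate (the stratum per-capita YLD rate net of the
stroke contribution, floored at zero) and the stroke disability weight
(0.28) applied to mid-year prevalence. Costs are mid-year prevalent cases
times an annual cost per case, weighted across sectors: 18% private at the
full tariff and 82% public at 70% of it. Discounting (first model year
undiscounted) applies to life years, HALYs and costs only — never to case
or death counts.

## Uncertainty and sensitivity

`run_monte_carlo()` redraws elasticities (normal), consumption means
(normal, truncated at zero by rejection), the energy-balance constant
(normal, truncated positive) and relative risks (log-normal) per draw,
re-runs the pipeline, and reports 2.5th/97.5th percentile intervals. Draws
are reproducible per (seed, index), so any single draw can be recomputed in
isolation. `sensitivity_grid()` varies one assumption at a time — tax rate,
discount rate, portion size, cost level, disability scaling, BMI trend,
pass-on rate, and a conservative own-price elasticity — and reruns the
deterministic pipeline for each row.

## Synthetic inputs

`generate_bundle()` fabricates a complete, internally consistent input set
from one seed: consumption declining with age and scaled to a weighted
mean SSB intake of 184 ml/day; mortality and stroke incidence log-linear
in age; prevalence at the quasi-steady state implied by incidence, case
fatality and mortality; relative risks attenuating with age; BMI summary
statistics with two noisy survey waves for the dispersion slope; heights,
costs and populations. It emulates the *structure* of survey,
burden-of-disease and claims data, not any particular country's values, so
absolute outcome magnitudes are illustrative; relative behaviour
(monotonicity in tax, discounting leaving counts unchanged, and so on) is
the substantive output. Randomness is confined to the BMI waves and
optional individual-level samples; everything else is deterministic given
the configuration, which is what makes bitwise reproducibility across runs
and machines possible.

## Worked example

```{r example, eval = FALSE}
bundle <- generate_bundle(synthetic_config(seed = 1))
run <- run_pipeline(bundle, tax_scenario(tax_rate = 0.20,
                                         horizon_years = 20))
run$totals
```

The numbered scripts under `analysis/` chain these steps into the full
workflow: input generation and validation, the base case, the sensitivity
grid, and the Monte Carlo uncertainty intervals, each writing its tables
under `results/`.
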