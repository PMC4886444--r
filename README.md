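# ssbstroke

A proportional multi-state life table model of the effect of a
sugar-sweetened beverage (SSB) tax on the population burden of stroke.

## The problem

Fiscal policies on SSBs are a standard lever against diet-related disease,
but their health effects are indirect: a tax changes prices, prices change
consumption, consumption changes energy intake, energy intake shifts the
body-mass-index (BMI) distribution, and only then does disease risk move.
This package implements that full chain for stroke:

```
tax τ ──ρ──▶ Δp ──ε──▶ ΔQ (ml/day) ──d──▶ ΔE (kJ/day)
        ──k──▶ Δw (kg) ──1/h²──▶ ΔBMI ──▶ PIF ──▶ life table
```

- **Demand:** ΔQ_b = Q_b · ε_b · τρ per beverage class (SSB, juice, milk,
  diet), with energy densities d_b converting to kJ/day.
- **Energy balance:** Δw = ΔE / k with k = 94 kJ/day per kg at the new
  steady state; ΔBMI = Δw / h².
- **Risk:** stratum BMI is log-normal; RR(x) = r^((x−21)/5) above a
  threshold of 21. The potential impact fraction
  PIF = (E_ref[RR] − E_int[RR]) / E_ref[RR] is computed by quadrature over
  both densities.
- **Burden:** 34 age–sex cohorts (bands 15–19 … 95–99) are followed by
  single year of age to 100 in a reference and an intervention arm.
  The PIF scales stroke incidence in the intervention arm only. The model
  tracks incident and prevalent cases, 28-day and long-run case fatality,
  other-cause mortality, (health-adjusted) life years, and stroke
  health-care costs, with exact person conservation each cycle.

All inputs come from a seeded synthetic-data generator that emulates the
structure of survey, burden-of-disease and claims data, so every number in
the repository is reproducible from a single integer.

## Worked example

```r
library(ssbstroke)

bundle <- generate_bundle(synthetic_config(seed = 1))
run <- run_pipeline(bundle, tax_scenario(tax_rate = 0.20,
                                         pass_on_rate = 1,
                                         horizon_years = 20))
run
#> <ssb_run> tax 20% over 20 years
#>   incident cases averted :          790
#>   stroke deaths averted  :          615
#>   prevalent cases, final :          138
#>   DALYs averted          :         4963
#>   costs saved (ZAR)      :     57439254
```

Uncertainty intervals and one-way sensitivity:

```r
ui <- run_monte_carlo(bundle, tax_scenario(), mc_config(n_draws = 2000))
ui$table          # 95% intervals for each headline outcome

grid <- sensitivity_grid(bundle)   # 27 scenarios, one assumption at a time
```

## Repository layout

- `R/` — the package: `synthetic_data.R` (input generator and validation),
  `demand.R` (price → consumption → energy), `bmi_model.R` (energy →
  weight → BMI distribution), `pif.R` (risk integration), `lifetable.R`
  (cohort simulation), `pipeline.R` (orchestration and artifacts),
  `uncertainty.R` (Monte Carlo and sensitivity grid).
- `analysis/` — numbered scripts chaining the workflow: generate inputs,
  base case, sensitivity grid, uncertainty. Each writes tables under
  `results/`.
- `vignettes/methods.Rmd` — model equations, numerical choices and design
  decisions.
- `tests/testthat/` — unit tests per module plus `test-acceptance.R`,
  which checks the model's defining properties against independent
  oracles (hand-unrolled life tables, brute-force Monte Carlo
  integration, conservation laws, interval calibration).

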