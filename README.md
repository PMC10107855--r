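# hfspanel

Panel-econometric tools for studying **health financing transitions**: how
a country's move from out-of-pocket (OOP) dominated health spending toward
social health insurance (SHI) or non-contributory government financing
affects health system outcomes.

Who it is for: health economists and epidemiologists working with long
country-year panels of health expenditure shares (e.g. national health
accounts extracts), outcomes (life expectancy, under-5 and maternal
mortality, catastrophic health expenditure incidence, immunization, total
health expenditure per capita) and macro controls.

## What it does

1. **Classification.** Each country-year is assigned a predominant health
   financing system (HFS) — `OOP`, `GOV` or `SHI` — by pooled k-means on
   the raw shares of total health expenditure (THE) channelled via
   government, SHI and OOP arrangements (`fit_kmeans()`, with
   `classify_argmax()` / `classify_threshold()` as alternative rules and
   `kselect_diagnostics()` for choosing the number of clusters). Durable
   switches (lasting at least two years) are detected by
   `detect_transitions()`.

2. **Estimation.** The main model is a generalized difference-in-differences
   two-way fixed-effects regression

   y_it = α + ρ₁ SHI_it + ρ₂ GOV_it + γ′x_it + τ_t + c_i + ε_it

   with OOP predominance as the reference category, estimated by
   within-transformation (`fit_twfe()`), with CR1 cluster-robust standard
   errors at the country level and t(G−1) inference. ρ₁ and ρ₂ are the
   within-country effects of transitioning out of OOP predominance.
   Coefficients on logged outcomes translate into percent changes as
   Δy% = (e^ρ − 1)·100 (`pct_effect()`). Variants: country-specific linear
   trends (`fit_random_trend()`), treatment-by-year differential trends
   (`fit_difftrend()` with `mean_impact()`), contextual-factor interactions
   (`fit_interaction()` / `marginal_effect()`), continuous shares as
   treatments (`fit_shares_treatment()`), and `event_study()` curves.

3. **Specification tests.** `clogg_test()` compares coefficients across
   models with and without country trends; `pta_ratio_test()` tests the
   nonlinear parallel-trend restriction Σρ_t / Σβ_t = 0 in the
   differential-trend model by a delta-method Wald statistic;
   `lead_test()` adds one-year treatment leads (Granger-style reverse
   causality check); `coef_diff_test()` tests ρ₁ = ρ₂; `bacon_weights()`
   computes the Goodman-Bacon timing decomposition and the weight carried
   by "already-treated as control" comparisons.

4. **Synthetic panels.** `simulate_panel()` generates balanced country-year
   panels with logistic-normal financing shares around three regime
   centroids, planted absorbing transitions, fixed-effects outcome models
   with known treatment effects, and optional violations (country trends,
   anticipation, outcome-dependent switching) — the basis for all recovery
   and size/power experiments.

## Worked example

```r
library(hfspanel)
cfg <- run_config(
  sim_cfg = sim_config(n_countries = 60, n_gov_switchers = 15,
                       n_shi_switchers = 4, seed = 42),
  controls = c("log_gdp_pc", "urban_pct"), seed = 42)
rep <- run_full_analysis(cfg)
print(rep)
```

```
<hfspanel report> seed 42

Transitions:
  from_label to_label n_countries
1        OOP      GOV          15
2        OOP      SHI           4

Main two-way FE estimates:
      outcome treatment estimate    se p_value stars pct_effect
1  log_the_pc       GOV    0.042 0.011   0.000   ***        4.3
2  log_the_pc       SHI    0.172 0.012   0.000   ***       18.8
5          le       GOV    1.113 0.152   0.000   ***         NA
6          le       SHI    0.072 0.376   0.849               NA
7     log_u5m       GOV   -0.079 0.012   0.000   ***       -7.6
...
PTA tests: 24, share p<0.05 = 0.04; lead tests: 12, share p<0.05 = 0.08
```

Reading it: the pipeline simulated a 60-country panel with 15 planted
government-financing and 4 SHI transitions, recovered them from the
k-means labels, and estimated — for example — that a transition to
government-predominant financing raises life expectancy by about 1.1
years (planted effect 1.341, within the cluster-robust CI) and lowers
under-5 mortality by 7.6% (planted −8.0%). The parallel-trend battery (24
tests) rejects at roughly its nominal rate, as it should when the
parallel-trend assumption holds by construction.

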