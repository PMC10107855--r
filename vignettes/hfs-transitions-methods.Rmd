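---
title: "Health financing transitions: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Health financing transitions: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfspanel)
```

## The problem

Countries trying to reach universal health coverage typically move away
from out-of-pocket (OOP) payment toward pooled, pre-paid public financing
— either contributory social health insurance (SHI) or non-contributory
government financing. Whether those two destinations differ in their
effects on health system outcomes is an empirical question that has to be
answered from observational country-year panels, with all the usual
hazards: the "treatment" (a country's predominant financing system) is
not assigned at random, transitions are staggered over time, and only a
handful of countries make any given transition.

`hfspanel` packages the full analysis chain for this question —
classification of country-years into financing systems, two-way
fixed-effects difference-in-differences estimation, and a battery of
specification tests — together with a synthetic-panel generator that
plants known truth, so every step can be validated by recovery
experiments rather than by faith.

## Classifying country-years

A country's financing mix is summarized by the shares of total health
expenditure (THE) channelled via government, SHI and OOP arrangements
(the three together typically account for ~90% of THE; the remainder is
mostly voluntary insurance). `fit_kmeans()` pools all country-years into
one k-means clustering on the raw three shares:

* **No standardization.** All inputs are percentages on a common scale;
  rescaling would distort the geometry the classification is meant to
  capture.
* **One pooled clustering** rather than per-year clusterings, so that
  labels are comparable over time and a "transition" is meaningful.
* **k-means++ seeding, best of `n_init = 50` restarts, Lloyd iterations
  capped at 300**, deterministic given `seed`. Within-cluster sum of
  squares is asserted nonincreasing across Lloyd iterations; empty
  clusters are repaired by relocating their center to the worst-fit point
  (which cannot increase the objective).
* **Labelling** takes the argmax coordinate of each centroid; if two
  centroids share an argmax the solution is ambiguous and the function
  refuses rather than guesses.

`kselect_diagnostics()` reports WSS, log WSS, the explained-variance
share η² and the proportional reduction in error PRE for k = 1..k_max,
and defines the elbow as the k after which PRE drops the most. On
generated three-regime data the elbow lands at k = 3 in well over 90% of
replicates.

Alternative rules — the largest share (`classify_argmax()`) and an
OOP-threshold rule (`classify_threshold()`) — are provided for robustness
analyses. Argmax ties break in the order OOP > GOV > SHI, conservatively
toward the reference category. Note a geometric subtlety: argmax regions
are bounded by share-tie planes, not by Voronoi boundaries of the
centroids, so argmax and k-means labels provably agree only close to a
centroid; the tests assert exact agreement within a third of the minimum
inter-centroid distance and ≥95% agreement overall.

A **transition** is a change of predominant label that persists at least
`min_duration = 2` consecutive observed years. One-year blips emit no
event, and the return from a blip to the previously established label is
not an event either; a gap in the observed years breaks a persistence
run. Raw yearly labels feed the regressions by default;
`smooth_labels()` offers the blip-reverting variant for sensitivity
analysis, since whether blips should be smoothed before regression is a
genuinely open choice.

## The estimators

The main specification is a generalized difference-in-differences with
two reversible treatments and staggered timing:

$$y_{it} = \alpha + \rho_1\,SHI_{it} + \rho_2\,GOV_{it} + \gamma'x_{it}
  + \tau_t + c_i + \varepsilon_{it}$$

`fit_twfe()` absorbs country effects by within-demeaning and enters year
effects as dummies (the window is short, so explicit dummies are cheaper
and unambiguous compared with iterative demeaning on unbalanced data);
coefficients are identical to full dummy-variable OLS to 1e-8, which the
test suite asserts against `lm()` directly. Missing data are handled by
listwise deletion per fitted model — no imputation — so sample sizes vary
across outcome columns, as they do in real panels of this kind.

**Inference.** Standard errors use the CR1 cluster-robust sandwich with
small-sample factor [G/(G−1)]·[(N−1)/(N−K)], clusters = countries, and
K counting the absorbed fixed effects; coefficient tests use t with G−1
degrees of freedom. Stata-style conventions differ across commands, so
one convention is fixed and documented; the tests cross-check against
`sandwich::vcovCL(type = "HC1")` on the equivalent dummy-OLS fit.
Reported adjusted R² is within-R²-based and not comparable across
software conventions.

**Collinearity.** Rank-deficient designs drop columns greedily by column
position (first-come-first-kept) and record what was dropped; a treatment
with no within-country variation is a hard error, because the design
then cannot identify its effect at all.

Variants:

* `fit_random_trend()` adds a linear trend per country, absorbed jointly
  with the country effect by per-country detrending (partitioned
  regression). Countries need ≥3 observed years. One identification
  caveat: a *common* linear drift in the year effects is annihilated by
  country detrending, so it reappears in the fitted country slopes — the
  slopes are interpretable relative to the common trend, not absolutely.
* `fit_difftrend()` interacts each treatment with the year dummies
  (first observed year as reference), allowing each treatment group its
  own nonlinear time profile. Empty treatment-year cells drop out and are
  recorded. `mean_impact()` summarizes the transition effect as
  ρ + (Σ_{t≥2} ρ_t)/(T−1) — the interaction sum divided by T−1 with the
  reference year excluded from the sum but counted in T. The alternative
  "average of the T per-year total effects" is exposed via
  `average = "per_year"` but is not the default; the two differ by a
  factor (T−1)/T on the interaction average, and the window-sum form is
  the one used in this literature.
* `fit_interaction()` adds a contextual factor and its treatment
  interactions; `marginal_effect()` evaluates the transition effect at
  chosen factor values with exact linear-form SEs. Factors are not
  centered; effects are evaluated at explicit values instead, which is
  equivalent and more transparent.
* `fit_shares_treatment()` swaps the regime dummies for continuous
  government and SHI shares (OOP omitted: the shares are collinear).
* `event_study()` regresses on relative-time dummies around each
  country's single transition (reference: the year before the switch),
  with endpoint bins at ±H. Countries with multiple or reversed
  transitions stay in the dummy-based fits (the design tolerates
  reversible treatments) but are excluded from event studies, where
  relative time would be ill-defined.

For logged outcomes a coefficient ρ converts to a percent change
(e^ρ − 1)·100 via `pct_effect()`, reported to one decimal. A coefficient
of 0.117 is +12.4%; −0.083 is −8.0% (headline roundings computed from
unrounded coefficients can differ in the last digit).

## The specification-test battery

* **Clogg-style comparison** (`clogg_test()`):
  Z = (ρ̂_trend − ρ̂_plain)/√(SE²_trend + SE²_plain), two-sided normal
  reference (the normal is the reference in the construction this test
  follows; both SEs are cluster-robust). Its null hypothesis is that
  country trends are *uncorrelated with the treatment* — not that trends
  are absent. That matters for validation: in a world with literally no
  country trends the two estimates are nearly identical and the statistic
  is degenerate (measured size ≈ 0% at nominal 5%), so the size
  experiments exercise this test in its intended null world, with country
  trend slopes of sd 0.2·σ_ε per year drawn independently of switching
  (for life expectancy that is a ±3 year differential drift over an
  18-year window — realistic for secular health trends). There the
  empirical size is within the nominal range.
* **Nonlinear parallel-trend ratio** (`pta_ratio_test()`): under a
  group-specific loading on an unobserved common trend, the restriction
  (Σ_{t≥2} ρ_t)/(Σ_{t≥2} β_t) = 0 holds iff the treated groups load like
  the reference group. The ratio's variance comes from the delta method
  on the joint cluster-robust covariance (verified against a
  finite-difference Jacobian to 1e-6) and the Wald statistic is referred
  to χ²(1). The testing machinery behind this restriction is not pinned
  down in the literature that uses it (delta method vs bootstrap); the
  delta-method Wald form was chosen and is documented here. When the
  year-effect sum is indistinguishable from zero the ratio is undefined
  and a labelled numerator-only Wald test is returned instead — which is
  why the generator's year effects include a nonzero drift by default:
  a visible common time profile is what makes the ratio well-posed.
* **Lead tests** (`lead_test()`): one-year treatment leads added to any
  of the three specifications; a significant lead means the "effect"
  precedes the transition — reverse causality in the Granger sense.
  Leads shift strictly within country and respect gaps.
* **Effect difference** (`coef_diff_test()`): t-test of ρ₁ = ρ₂ from the
  joint covariance; for differential-trend fits the comparison is between
  mean impacts.
* **Timing decomposition** (`bacon_weights()`): on the sub-design of
  never-treated countries plus absorbing switchers (balanced window, no
  controls), the two-way FE coefficient is decomposed exactly into
  weighted 2×2 comparisons; the share of weight on
  later-vs-earlier-treated comparisons quantifies exposure to the
  negative-weights problem. The decomposition is implemented only for
  this absorbing sub-design; there is no accepted formulation for
  reversible treatments, which are therefore out of scope.

`pvalue_histogram()` summarizes any battery of p-values as bin counts and
shares below 5%/10% — the reporting style used for these test batteries.
No multiple-testing adjustment is applied across the battery, by design:
the batteries are descriptive.

## The synthetic-panel generator

`simulate_panel()` emulates the data structure the estimators assume, at
the study's scale: 124 countries over 2000–2017, financing-share regimes
centred at (gov, shi, oop, other) = (62.6, 2.7, 21.4, 13.3) for
government-predominant, (28.6, 7.3, 51.6, 12.5) for OOP-predominant and
(11.0, 59.3, 23.6, 6.1) for SHI-predominant country-years, initial regime
proportions ≈ (48.5%, 32%, 19.5%) OOP/GOV/SHI, and 30 OOP-origin
countries switching to government financing plus 7 to SHI at uniformly
drawn interior years. Planted treatment effects default to the magnitudes
a two-way FE analysis of such a panel reports (e.g. +1.341 years of life
expectancy and −0.083 log points of under-5 mortality for a government
transition; +0.117 log points of THE per capita for an SHI transition),
so recovery experiments double as a plausibility bridge to real-world
effect sizes. All defaults are overridable but are treated as *the* study
conditions: validation experiments do not move them.

Design choices worth knowing:

* **Shares** are additive-logistic-normal draws: softmax of the
  log-centroid plus iid Gaussian noise (σ_s = 0.25 on the log-ratio
  scale), times 100. This keeps every draw exactly on the simplex and
  preserves the centroid's ordering; zero centroid components are floored
  at 1e-6 before the log. Within-regime shares are iid around the
  centroid — real share series are serially dependent, so the generator
  understates within-regime persistence; classification accuracy results
  should be read as per-observation, not per-run-length.
* **Outcomes** follow the two-way FE model exactly: country effects
  (sd per outcome, e.g. 7 years for life expectancy), a common year
  drift (e.g. +0.25 years/yr) plus small common shocks, an idiosyncratic
  error (sd 1.0 year for life expectancy), and a log-GDP loading; logged
  outcomes are generated on the log scale and exponentiated, so the
  natural-scale columns are exactly log-normal. Index-type outcomes are
  clipped to their domains, which can shave tails for the immunization
  index near 100.
* **Controls** are AR(1) processes around country-level means;
  contextual factors get regime-dependent means (informal sector smaller
  under SHI, payroll financing larger, and so on). By default the
  controls are independent of switching (`confound_strength = 0`), so
  omitting them costs precision, not consistency.
* **Violations** are explicit switches: `country_trend_sd` plants random
  country trends (uncorrelated with treatment — a parallel-trends-
  consistent world); `switcher_trend` gives switchers an extra slope
  (a treatment-correlated differential trend, the violation the PTA
  tests must catch); `anticipation_frac` applies a fraction of the
  treatment effect one year early; `endog_slope` makes the switch year
  selection load on the previous year's standardized idiosyncratic shock
  (at slope 0 this reduces *exactly* to the uniform draw, so the
  exogenous mode is the degenerate case). Endogenous selection operates
  on the shock of one configured outcome (default life expectancy).
* **Reversibility**: switches are absorbing by default (the dominant
  real-world pattern); `n_reverters` exercises the reversible-treatment
  design.
* One integer seed drives everything through a single RNG stream, with
  caller RNG state restored afterwards.

What passing tests on these panels do *not* show: robustness to serial
dependence in shares and errors (the generator's errors are iid within
country), to measurement error in OOP shares (a known data-quality issue
in real national health accounts), or to the multivariate outlier
structure of real panels. They validate the estimators and tests under
the model they assume, plus the planted violations.

## Validation results and problem sizes

The validation suite (and `scripts/acceptance.R`) uses: 20 panels of
50×18 for the dummy-OLS equivalence (tolerance 1e-8); 200 panels at the
full 124×18 scale for recovery of the planted life-expectancy effect
(mean within ±0.1, 95% CI coverage required in [91%, 98%]); 500
replicates per specification test for size (required within [2%, 9%] at
nominal 5%) and power (ratio test ≥80% against a 0.5·σ differential
trend; lead test above twice nominal under outcome-dependent switching);
50 replicates for the k-selection elbow; 10 panels for the
Goodman-Bacon identity (weights sum to 1 within 1e-9, weighted 2×2 sum
equals the sub-panel TWFE within 1e-8).

Two measured properties deserve flagging rather than hiding:

* The ρ₁−ρ₂ difference test runs slightly hot: its true size is ≈8–9% at
  nominal 5% under the study's 30/7 switcher design, so a 500-replicate
  size check against a 9% ceiling can land on either side of the line. The cause is the
  few-treated-clusters bias of cluster-robust SEs — only 7 countries
  identify the SHI arm, whose own CI coverage is ≈90% rather than 95%.
  This is a property of CR1+t(G−1) inference at this design, not a bug;
  analyses with very few switchers should read the SHI-arm SEs (and this
  contrast) with that in mind.
* The Clogg comparison is severely conservative when country trends are
  literally absent (size ≈0%); see above for why its size is evaluated
  in the uncorrelated-trends null world instead.

## Limitations

* The package analyses long-format country-year CSVs only; it does not
  fetch or parse the upstream national-accounts databases, and share
  sums are validated to 100 ± 0.5 percentage points (real accounting
  data rarely sums exactly; how raw-data discrepancies were handled
  upstream is the data provider's affair).
* Classification boundaries on real data depend on k-means seeding and
  restart counts; with the deterministic seeding here, results are
  reproducible but may differ at the margin from other software.
* No IV/GMM, spatial or Driscoll-Kraay inference; no
  honest/staggered-DiD estimators beyond the diagnostic decomposition;
  no mediation analysis.
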