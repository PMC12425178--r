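---
title: "Parameter discretisation for compartmental models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter discretisation for compartmental models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixdistill)
```

## The problem

Compartmental models run at a coarse stratification (the *model partition*
`A = {a_j}`), while inputs such as an infection-fatality ratio IFR(x) and
outputs such as ages at death live on a fine axis (the *output partition*
`B = {b_i}`). This package treats the two resolution changes as one object:
the **mixing table** over the union partition `C = A ∪ B`. All intervals are
half-open `[c_i, c_{i+1})`, with the terminal interval closed, so the
partition tiles its support exactly; containment tests use this convention
throughout, including the tie-break for "all deaths at the mean age"
(a mean landing exactly on a boundary goes to the upper interval).

Per mixing interval the table stores the weighted parameter integral
`weight_i = ∫ parameter(x) ρ(x) dx` and the population mass
`population_i = ∫ ρ(x) dx`. Aggregation (`blend()`) is then the
density-weighted group mean, which always lies between the parameter's
infimum and supremum over the group. Disaggregation (`distill()`) applies
row-stochastic Bayes weights `ω_ji`, proportional within each model group to
the parameter-times-density mass of the intersection with each output group —
so outcome totals are conserved by construction, a property the test suite
asserts to 1e-12 relative on randomized partitions.

Both partitions must span the same support; mismatched supports raise an
error rather than silently clipping, because clipping hides population mass.
The stratifying feature is scalar (age in the demonstration, but any
one-dimensional stratification works); joint multi-dimensional features are
out of scope.

## Interpolation and normalisation

Tabular inputs become functions as follows:

* **Parameters**: a monotonicity-preserving cubic Hermite spline
  (Fritsch–Carlson, `splinefun(method = "monoH.FC")`). A natural cubic spline
  can overshoot below zero between the tiny values typical of IFR tables;
  shape-preserving interpolation cannot. Users may pass any function instead.
* **Densities**: piecewise-linear interpolation (`approxfun`), then
  renormalised to integrate to 1 over the support. The blend and distill
  formulas are ratios and hence scale-invariant, so normalisation is always
  safe; enforcing it makes population conservation (`Σ population_i = 1`)
  directly testable. Single-year demography tables have a dedicated
  piecewise-constant density (`demography_density()`): row `age = x` is the
  interval `[x, x+1)`, so density integrals agree exactly with table sums and
  with the SEIR group populations.
* **Extrapolation** is constant beyond the tabulated range for both kinds of
  input, avoiding spline excursions at open-ended groups.

Integrals are computed by adaptive quadrature (`stats::integrate`, absolute
tolerance 1e-9, configurable) on each smooth piece — the integration range is
split at every interpolation knot — with a composite-Simpson fallback on a
0.01-unit grid if the adaptive rule fails. Against a brute-force midpoint
Riemann oracle at step 1e-3, blended values agree to better than 1e-6
relative on smooth random inputs (asserted in the suite).

Degenerate inputs are handled explicitly: a model group over which the
parameter is identically zero has no parameter information to apportion by,
so its `ω` row falls back to population-proportional shares with a warning
(mass is conserved, nothing is invented); zero-mass mixing intervals are an
error.

## The alternative approaches

For comparison the package implements the naive rules commonly used in
practice, sharing one registry of approach names used by the summaries and
the CLI:

| direction | approach | rule |
|---|---|---|
| aggregation | `midpoint` | parameter at `(a+b)/2` |
| aggregation | `mean_age` | parameter at `E[x | group] = ∫ x ρ / ∫ ρ` |
| aggregation | `blend` | density-weighted mean `∫ parameter·ρ / ∫ ρ` |
| disaggregation | `uniform` | mass ∝ interval length |
| disaggregation | `mean_age` | all mass at `E[x | group]` |
| disaggregation | `density` | mass ∝ `∫ ρ` |
| disaggregation | `distill` | mass ∝ `∫ parameter·ρ` |

The mean-age aggregation rule is sometimes written loosely as the parameter
of the bare density integral; the quantity actually intended — and
implemented here — is the parameter evaluated at the density-weighted mean
feature value. For affine parameters it coincides with `blend` exactly (a
test property); for convex parameters Jensen's inequality puts it below.
Open-ended terminal groups take an explicit upper bound in the partition
(101 years by default in the demonstration) so midpoints and means are
well defined.

## The demonstration model

An age-stratified SEIR model with force of infection
`λ_i = β Σ_j c_ij I_j / N_j`, where `c_ij` is the daily number of contacts an
individual of group `i` has with group `j`. Two parameterisations:

| parameter | flu-like | COVID-like |
|---|---|---|
| transmissibility β (per contact-day) | 0.15 | 0.1 |
| latent period 1/τ (days) | 1 | 3 |
| infectious period 1/γ (days) | 2 | 5 |
| IFR(x) | ∝ all-cause mortality m(x) | `10^(−3.27 + 0.0524x)/100` |

Assumptions: no ageing, births or background deaths (group totals are
conserved, checked to 1e-6 relative); fatalities remain in R and do not feed
back into transmission, equivalent to survivors proportionally reducing
contacts; vaccination is all-or-nothing at 50% efficacy, applied by moving
the protected fraction of the target group from S to R before the run;
the epidemic is seeded with 0.001% of every group in E. The ODE system is
integrated with `deSolve::lsoda` (relative tolerance 1e-8, absolute 1e-10) on
a daily output grid; cumulative infections are tracked as an auxiliary
integrated state `∫ λ S dt` rather than by differencing S, avoiding
cancellation error. Deaths are post-processing, `deaths_j = IFR_j × cumI_j`,
so trajectories are bit-identical across IFR choices — the suite asserts this
and the implied linear scaling of deaths.

The default horizon is 365 days, chosen (and checked in the tests) so the
epidemic has effectively ended, i.e. remaining infectious mass is below the
seed size. The single-group solver is validated against the final-size
equation `z = 1 − exp(−R₀ z)` to 0.1%.

**Scenarios.** Model groups 0–4, 5–19, 20–64 and 65+ (terminal bound 101).
A fixed dose stock equal to 75% of the 65+ population is allocated entirely
to one target group per scenario (so larger target groups get lower
coverage, capped at 1), alongside a no-vaccination baseline.

**High-resolution benchmark.** The same model at single-year resolution
(101 groups). Seeding at a common fraction is automatically
population-proportional within the coarse bounds; doses are shared
population-proportionally across the single-year groups inside the target
range. The coarse contact matrix expands as
`c_fine[i, j] = c[I, J] · pop_j / pop_J`, which preserves each individual's
total contacts with every coarse block; under block-uniform prevalence the
fine force of infection aggregates exactly to the coarse one, and the suite
verifies that coarse and fine runs then agree per model group to solver
tolerance. Single-year IFRs use the value at the interval's lower bound,
`IFR(x)` for `[x, x+1)`; the same lower-bound convention gives the
representative age for life-expectancy lookup in the YLL step. Both are
conventions, not derived facts — midpoint or integral variants would be
equally defensible and differ only within the practical margin of the
decision; the lower-bound pair keeps deaths and YLLs consistent.

**YLLs.** `YLL = Σ_i deaths_i · e(age_i)` with `e(x)` linearly interpolated
from the life table; undiscounted and without age weights. In the
comparison report the YLL rows hold the model-group deaths fixed at the
blend-based estimates and vary only the disaggregation approach, mirroring
the common situation where per-group death counts are handed to a
health-economics team; the benchmark YLLs come from the high-resolution
deaths directly.

**Flu-like IFR calibration.** The flu-like IFR is `scale × m(x)` (clipped to
[0, 1]). The scale is set so total deaths match the COVID-like pathogen in a
reference setting — by convention the no-vaccination, HIC-like,
high-resolution run. Because trajectories are IFR-independent, deaths are
linear in the scale and the calibration is an exact ratio; the clip is
checked post hoc and warned about. The mortality curve comes from the
HIC-like life table in both populations, so the two populations share one
age-specific IFR.

## Synthetic fixtures

The generators stand in for demographic data a study would normally download:

* `make_demography()`: parametric single-year pyramids — `"rectangular"`
  (near-flat with a logistic taper centred at 70% of the maximum age; CV of
  counts below 5% before the taper) and `"young"` (exponential decay at 4%
  per year of age). Deterministic; an optional seeded log-normal jitter
  roughens the pyramid without changing the total and without touching the
  global RNG stream.
* `make_life_table()`: mortality as infant-decay plus Gompertz terms — hence
  U-shaped in age, which is what makes the flu-like IFR non-monotone — with
  `e(x)` derived numerically from the implied survival curve. The HIC-like
  parameters give higher life expectancy at birth than the LMIC-like ones.
* `make_contact_matrix()`: a convex combination of proportional mixing and
  the identity, scaled to 8 daily contacts per person by default, satisfying
  contact reciprocity. With the default assortativity of 0.4 and the flu-like
  parameters this puts the basic reproduction number near 2.4
  (`β·contacts·infectious period`), a plausible pandemic-influenza range.

The demonstration uses a total population of 5e7 and these defaults
throughout the tests and the acceptance script. What the synthetic fixtures
emulate is the *shape* contrast between rectangular and young populations and
between monotone and U-shaped IFRs; they do not reproduce any specific
country's pyramid, contact structure or mortality schedule. Consequently the
qualitative results — conservation, the ordering of approaches, blend/distill
being closest to the high-resolution benchmark in deaths and YLLs for every
scenario (asserted in the suite across both populations and both pathogens) —
transfer to real data, while the magnitudes (deaths averted, percentage
overestimates) are fixture-specific and should not be read as estimates for
any real population. Difference metrics such as *averted* deaths or YLLs are
additionally sensitive to near-cancellation: two approaches can bracket the
benchmark closely on totals yet order differently on differences,
particularly for the U-shaped flu-like IFR where errors in the youngest and
oldest groups partially offset.

## Known limitations

* Scalar stratifying feature only; no joint age × risk discretisation.
* No uncertainty propagation on blended parameters or redistributed outcomes.
* The SEIR demonstration omits waning immunity, leaky vaccines, demography
  and stochasticity by design; with strong within-group depletion (deaths
  concentrated at the oldest ages shifting a group's composition over time)
  any fixed-parameter coarse model, including this one, will drift from the
  high-resolution benchmark.
* YLLs are undiscounted and unweighted; DALYs, morbidity and costing are out
  of scope.
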