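# mixdistill

Compartmental epidemic models stratify a population into broad groups — say
ages 0–4, 5–19, 20–64 and 65+ — while the quantities that drive disease burden,
such as the infection-fatality ratio (IFR), vary continuously across each
group. Modellers face two mirror-image discretisation problems:

* **Aggregation**: turning a continuous parameter curve `parameter(x)` and a
  population density `ρ(x)` into one value per model compartment. Naive choices
  (the value at the group midpoint, or at the group's mean age) ignore how the
  parameter and the population co-vary inside the group.
* **Disaggregation**: spreading compartment-level outcomes (e.g. deaths) back
  onto a fine partition — needed, for instance, to compute years of life lost
  (YLL), where every death is weighted by the remaining life expectancy at the
  age of death. Spreading deaths proportionally to population alone
  systematically assigns them too young and inflates YLLs.

`mixdistill` implements the matched pair of transformations. A **mixing
table** over the union `C = A ∪ B` of the model partition `A` and the output
partition `B` stores, per mixing interval `c_i`,

```
weight_i     = ∫_{c_i} parameter(x) ρ(x) dx
population_i = ∫_{c_i} ρ(x) dx            with ∫ ρ(x) dx = 1
```

Aggregation (**blend**) gives each model group the density-weighted mean

```
parameter_j = Σ_{c_k ∈ a_j} weight_k / Σ_{c_k ∈ a_j} population_k
```

and disaggregation (**distill**) redistributes outcomes `X_j` to output groups
by the Bayes-rule weights

```
ω_ji = Σ_{c_k ∈ b_i ∩ a_j} weight_k / Σ_{c_k ∈ a_j} weight_k ,   Y_i = Σ_j ω_ji X_j .
```

Every `ω` row sums to 1, so outcome totals are conserved exactly.

The package also ships the naive alternatives for comparison (midpoint and
mean-age aggregation; uniform, mean-age and density-proportional
disaggregation), an age-stratified SEIR demonstration model with
all-or-nothing vaccination scenarios at low (4-group) and high (single-year,
101-group) resolution, YLL computation from a life table, and synthetic
demography/life-table/contact-matrix generators so everything runs without
external data.

## Worked example

Aggregate a COVID-like IFR, `IFR(x) = 10^(−3.27 + 0.0524·x) / 100`, onto the
four broad age groups of a synthetic high-income-style population, then
disaggregate model deaths to single years of age and compute YLLs:

```r
library(mixdistill)

demo <- make_demography("rectangular", total_population = 5e7)
ages <- make_partition(c(0, 5, 20, 65, 101))
mx   <- build_mixing_table(covid_ifr, demography_density(demo),
                           model = ages, output = seq(0, 101))

parameter_summary(covid_ifr, demography_density(demo), ages)
#>     group_lo group_hi approach        value
#>  1:        0        5 midpoint 7.261060e-06
#>  ...
#>  4:       65      101 midpoint 1.200052e-01
#>  8:       65      101 mean_age 4.081525e-02
#> 12:       65      101    blend 6.908995e-02
```

For the 65+ group the midpoint rule (IFR at age 83) gives 12.0%, the mean-age
rule 4.1%, and the blended density-weighted mean 6.9% — a three-fold spread
from the same inputs, because the IFR grows ~12.8% per year of age while the
population thins out across the open-ended group.

```r
deaths  <- c(12, 160, 3000, 45000)   # per model group, e.g. from an SEIR run
by_year <- distill(mx, deaths)
by_year[66:70, ]
#>    output_group group_lo group_hi     value
#> 1:           66       65       66  770.3605
#> 2:           67       66       67  830.0205
#> ...
sum(by_year$value)                            # 48172 — totals are conserved
compute_ylls(by_year, make_life_table("rectangular"))
#> [1] 484443.7
```

The full demonstration — SEIR runs under vaccination scenarios, deaths and
YLLs averted under every aggregation/disaggregation approach, benchmarked
against the 101-group high-resolution model — is one call:

```r
rep <- compare_approaches(demo, make_life_table("rectangular"),
                          covid_params(),
                          make_contact_matrix(ages,
                            populations = group_populations(demo, ages)))
```

See the methods vignette (`vignettes/parameter-discretisation.Rmd`) for the
model details, and `exec/mixdistill` for the command-line interface
(`fixtures`, `blend`, `distill`, `compare` subcommands over plain CSV files).

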