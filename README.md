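# icdshift

Quantify year-on-year shifts in the diagnostic mix of ICD-10-coded
primary-care visit registries.

When a health system is disrupted — the COVID-19 switch from face-to-face
care to telemedicine being the canonical case — the reasons patients are
seen for change along with the care model. `icdshift` is for
health-services researchers and planners who have visit-level records
(one row per visit, zero or more ICD-10 diagnostic codes per visit) and
want to know **which diagnoses surged, which collapsed, and which account
for most of the overall disruption**, at several resolutions of the ICD-10
hierarchy and within strata such as modality, specialty, age group or sex.

## The statistics

For code grouping *c* and periods *t₀* (baseline) and *t₁*, with n(c, t)
the number of code occurrences (a visit with *k* codes contributes *k*),
and Δc = n(c, t₁) − n(c, t₀):

- **Interannual variation**: iav_c = 100 · Δc / n(c, t₀), the per-group
  relative change in percent (undefined, reported `NA`, on a zero
  baseline);
- **Variation index**: VI_c = |Δc| / Σ_c′ |Δc′|, each group's share of the
  total absolute disruption; VI ∈ [0, 1] and sums to 1 over the table in
  which it is computed.

Counts are accumulated in a term-frequency matrix (periods × code
groupings) at three aggregation levels: ICD-10 **chapters** (C00-D49,
...), **blocks** (I10-I16, ...), and three-character **categories** (E11,
...), with exact rollup conservation between levels.

The package also ships a **seeded synthetic visit-cohort generator**
calibrated to the published margins of a two-year Catalan primary-care
registry (volumes, coding completeness, modality/specialty/sex/age
mixtures, per-year chapter weights, codes-per-visit law), so the full
pipeline is testable without access to restricted registry data, plus the
published tables themselves (`reference_table()`) as machine-checkable
inputs.

## Worked example

```r
library(icdshift)
library(dplyr)

fm <- as_freq_matrix(
  reference_table("chapters"),                  # published 21 x 2 chapter counts
  periods = c(Y2019 = "n_2019", Y2020 = "n_2020")
)
vt <- variation_table(fm, sort = "by_index")
tidy(vt, rounded = TRUE) |>
  select(group, n_early, n_late, iav_pct, vi) |>
  head(5)
#> # A tibble: 5 × 5
#>   group                                             n_early n_late iav_pct    vi
#>   <chr>                                               <int>  <int>   <dbl> <dbl>
#> 1 Factors influencing health status and contact wi…  186604 296764    59.0  0.22
#> 2 Diseases of the circulatory system (I00-I99)       252555 187701   -25.7  0.13
#> 3 Endocrine, nutritional, and metabolic diseases (…  261076 202933   -22.3  0.11
#> 4 Diseases of the respiratory system (J00-J99)       176405 120669   -31.6  0.11
#> 5 Certain infectious and parasitic diseases (A00-B…   52220  99779    91.1  0.09

glance(vt)
#> # A tibble: 1 × 6
#>   n_groups total_codes sum_abs_delta mean_abs_iav_pct top_vi_group         level
#>      <int>       <int>         <int>            <dbl> <chr>                <dbl>
#> 1       21     3921974        512346             23.9 Factors influencing…     1
```

Reading: health-services contact codes (Z00-Z99) grew 59% year-on-year
and alone carry 22% of the total absolute shift in the diagnostic mix;
circulatory-disease codes (I00-I99) fell 25.7% and carry another 13%.
Across all 21 chapters, 3,921,974 code occurrences moved by 512,346 in
absolute sum.

A full synthetic run, end to end:

```r
cfg <- run_config(
  simulate = list(n_visits = c(Y2019 = 50000, Y2020 = 50000)),
  seed = 7
)
bundle <- run_pipeline(cfg)        # simulate -> filter -> count -> variation
emit_tables(bundle, "out/")        # deterministic TSVs + manifest.yaml
autoplot(bundle$results$L1_all$variation)   # before-vs-during log-log scatter
```

A thin command-line wrapper with `simulate` / `summarize` / `variation` /
`report` subcommands lives at `inst/scripts/icdshift-cli.R`, driven by the
same YAML configuration as `run_config_from_yaml()`.

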