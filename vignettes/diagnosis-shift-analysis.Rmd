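---
title: "Quantifying shifts in the primary-care diagnostic mix with icdshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shifts in the primary-care diagnostic mix with icdshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdshift)
library(dplyr)
```

## The problem

Primary-care registries record, for every visit, zero or more ICD-10
diagnostic codes that serve as a proxy for the reason the patient was seen.
When the care model is disrupted — most dramatically by the COVID-19
pandemic, which replaced most face-to-face contact with telemedicine —
the *mix* of diagnoses shifts: some reasons for consultation surge, others
collapse. Health planners need to know which diagnoses were most displaced,
at several resolutions of the ICD-10 hierarchy, and within strata such as
visit modality or patient age group.

`icdshift` implements this analysis end to end: visit-level records are
filtered to coded visits, each code is rolled up through the ICD-10
hierarchy, counts are accumulated into a period-by-group term-frequency
matrix, and two complementary statistics summarise the change of each code
grouping between a baseline and a comparison period.

## The model

Let $n(c, t)$ be the number of occurrences of code grouping $c$ among the
visits of period $t$. A visit carrying $k$ codes contributes $k$
occurrences — cells count codes, not visits. For two periods $t_0$
(baseline) and $t_1$, write $\Delta_c = n(c, t_1) - n(c, t_0)$.

Two statistics are computed per grouping:

* **Interannual variation**, the relative change in percent:
  $$\mathrm{iav}_c = 100 \cdot \frac{\Delta_c}{n(c, t_0)}.$$
  It is undefined when the baseline count is zero; such groups are kept in
  the table with an `NA` sentinel rather than a fabricated 0 or infinity.

* **Variation index**, the grouping's share of the total absolute
  disruption:
  $$\mathrm{VI}_c = \frac{|\Delta_c|}{\sum_{c'} |\Delta_{c'}|},$$
  which lies in $[0, 1]$ and sums to 1 over the groupings of the table.
  A grouping with a zero baseline still contributes its $|\Delta_c|$ to the
  denominator, so the normalization identity holds even when some iav
  values are undefined. When *every* $\Delta_c$ is zero the index is
  undefined for all groups (never $0/0$).

The two statistics are deliberately complementary: iav is scale-free per
group (a rare code can show a huge percentage change), while VI weights
each change by its absolute size, so it highlights the groupings that
account for most of the system-level shock. Both are invariant to
multiplying all counts by a positive constant.

**Denominator scope.** The variation index is always normalized within the
table being reported — the groupings of one aggregation level, inside one
stratum. Restricting a table to its top-$k$ rows after normalization does
not renormalize the index; consequently per-row indices quoted from a
published top-$k$ excerpt cannot be reproduced from the excerpt's rows
alone. `variation_table()` therefore always computes the index over the
full matrix it is given.

## ICD-10 aggregation levels

Codes are analysed at three levels:

1. **Chapters** (e.g. "Neoplasms (C00-D49)") — the shipped table follows
   the ICD-10-CM tabular layout (21 chapters, with the C00-D49 / D50-D89
   split), plus the special-purpose chapter U00-U85 so that pandemic-era
   codes such as U07 roll up instead of landing in the unmapped bucket.
   The special chapter can be dropped with `include_special = FALSE`.
2. **Blocks** (e.g. "Hypertensive diseases (I10-I16)") — the public block
   structure nested within chapters. A handful of single-category blocks
   are merged into neighbouring ranges to keep the table a set of disjoint
   intervals; no block range used in published diagnosis-mix reports is
   affected.
3. **Categories** — the three-character stem itself (e.g. "E11"); any
   dot suffix ("E11.9") is stripped first, so level 3 is the category
   rollup, not the raw code.

Ranges are ordered positionally with digits before letters in positions
2–3, so "O9A" sorts after "O99" and ranges such as O00-O9A and X92-Y09 are
proper intervals. Codes whose stem falls outside every range are routed to
an explicit `UNMAPPED` bucket by default (counted and reported), keeping
the rollup conservation identity exact: category counts sum to block
counts sum to chapter counts, unmapped mass included.

## Cohort handling choices

* **Coded-visit filter.** Diagnosis coding is optional in primary-care
  records, so the analysis set is restricted to visits with at least one
  code; `coding_summary()` reports the per-period fraction dropped, which
  is itself a quantity of interest (coding completeness fell during the
  pandemic).
* **Age groups.** Six bins partition the non-negative ages: 0–5, 6–11,
  12–18, 19–26, 27–59, and 60+. Published bin definitions sometimes
  overlap in their footnotes (adolescence "12–18" vs youth "14–26") even
  though the corresponding shares sum to 100%; the package uses the
  disjoint 12–18 / 19–26 reading, and resolves the 60-year boundary into
  the older-adult bin so there is neither gap nor overlap.
* **Distinct patients** are counted as distinct patient identifiers per
  period.
* **Difference percentages** in the cohort summary are
  $100 (n_{t_1} - n_{t_0}) / n_{t_0}$, the same form as iav. Empty
  partitions yield flagged `NA` descriptors, never zeros.
* **Duplicate codes on one visit** count as separate occurrences by
  default (term-frequency semantics); `dedupe = TRUE` switches to
  per-visit presence counting.
* **Partitions** are user-specified named closed-open date intervals;
  the shipped default is the two calendar years of a before/during
  comparison. Visits outside every partition are excluded and counted,
  never silently absorbed.

## The synthetic cohort generator

The registry data such analyses run on cannot be redistributed, so the
package includes a seeded generator whose defaults are calibrated to the
published margins of a two-year Catalan primary-care registry
(`reference_table()`): per-year visit volumes (1,421,779 / 1,402,406),
uncoded fractions (18.46% / 22.50%), modality mixtures (85.30% vs 45.20%
face-to-face), specialty and sex mixtures, age-group shares (uniform ages
within each bin, capped at 95), and per-year chapter weights taken from
the published chapter counts.

**Codes per coded visit** follow $1 + N$ with $N$ negative binomial. The
two parameters are solved at configuration time so the law reproduces the
published mean (1.38) and tail ($P(>3\ \text{codes}) = 3.5\%$): a shifted
geometric can match the mean but tops out near a 2.1% tail at that mean,
so the tail target requires genuine overdispersion (the fitted dispersion
is about 0.38). The tail probability is not monotone in the dispersion
parameter, so the solver works on the branch between the tail's maximum
and the Poisson limit.

**Within a chapter**, a code's category is drawn uniformly over the
categories covered by the chapter's blocks; real registries concentrate
mass on a few categories (I10, E11, Z20...), so level-2/3 *shares* of the
synthetic data are deliberately diffuse even though level-1 shares are
realistic. Patients are drawn uniformly from a fixed pool (default
376,486, the registry's reference population); no per-patient visit law
is published, so distinct-patient counts are exercised but not calibrated.
The generator also does not model disease co-occurrence within a visit,
calendar seasonality, or modality-dependent coding intensity. Passing
tests on synthetic cohorts therefore validate the *pipeline arithmetic*
(counting, rollup, normalization, stratification, determinism and
parameter recovery), not clinical realism.

`expected_counts()` gives the closed-form expectation
$E[n(c,t)] = n_t (1 - m_t)\, \bar{k}\, p(c,t)$ (visits × coded fraction ×
mean codes × group probability), which is the oracle for parameter
recovery: as the cohort grows, the empirical variation table converges to
the variation table of the expected matrix. Tests check per-chapter shares
within three binomial standard errors at roughly $10^5$ code occurrences
per period, and variation indices within the count noise propagated
through the index ($\mathrm{sd}(\Delta_c) \approx
\sqrt{E[n(c,t_0)] + E[n(c,t_1)]}$ against the fixed expected denominator).

## Numerical and reporting conventions

* Internal computation is full precision; emitted tables round derived
  columns (shares, iav, VI) to 2 decimal places by default, matching how
  such tables are printed. A value that rounds differently only in the
  last printed digit of a published table is treated as a print-rounding
  ambiguity, not a defect.
* Sorting is by descending total (or descending index), with ties broken
  lexicographically by label so outputs are bit-stable.
* Undefined values are emitted as the literal `NA`, never as 0.
* `run_pipeline()` + `emit_tables()` are deterministic under a fixed seed
  and configuration: reruns produce byte-identical files; the manifest
  records the package version, seed and a configuration hash.

## Problem sizes

The bundled test-suite runs generate cohorts of $10^3$–$10^5$ visits
(about $2 \times 10^5$ code occurrences at the top end), sizes at which
every statistical tolerance above is meaningful while a full suite run
completes in well under a minute; the full pipeline benchmark uses
$10^5$ visits across all three levels and three strata. All defaults scale
unchanged to registry-sized inputs (millions of visits), since every step
is a vectorized count or join.

## Worked example

```{r example}
# published chapter counts as a two-period matrix
fm <- as_freq_matrix(
  reference_table("chapters"),
  periods = c(Y2019 = "n_2019", Y2020 = "n_2020")
)
vt <- variation_table(fm, sort = "by_index")
tidy(vt, rounded = TRUE) |>
  select(group, n_early, n_late, iav_pct, vi) |>
  head(5)
glance(vt)
```

```{r synthetic}
# a small synthetic cohort through the same pipeline
cfg <- synthetic_config(n_visits = c(Y2019 = 5000, Y2020 = 5000))
visits <- generate_visits(cfg, seed = 1)
visits |>
  filter_coded() |>
  build_matrix(1, year_partitions(c(2019, 2020))) |>
  variation_table() |>
  glance()
```

## Known limitations

* The hierarchy ships one dialect (the ICD-10-CM chapter/block layout);
  WHO-dialect block boundaries differ in places. A user CSV can override
  the table wholesale.
* The two compared periods are calendar years by default; a pandemic that
  starts mid-period dilutes the contrast, and no within-period
  decomposition is attempted.
* No inferential statistics are attached to the variations: with millions
  of codes the sampling error of the printed percentages is negligible
  relative to the systematic questions (coding practice changes) that
  dominate interpretation.
* The variation index depends on the grouping resolution and stratum in
  which it is computed; indices from different tables are not comparable.
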