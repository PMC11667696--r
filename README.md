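# stilsort

Hierarchical rank-sort case prioritization for sTILs annotation studies.

## The problem

Validation datasets for AI models that assess stromal tumor-infiltrating
lymphocytes (sTILs) in triple negative breast cancer are built by having
pathologists annotate regions of interest (ROIs) on whole slide images
(WSIs). Clinical cohorts are dominated by low sTILs densities and by the
majority demographic groups of the contributing sites, so annotating cases
in arrival order produces a dataset that under-samples exactly the
subgroups where model generalizability is most in question. `stilsort`
implements a hierarchical rank-sort that enriches annotation batches for
underrepresented density bins, demographics, disease stages and assessment
pitfalls, together with the metadata harmonization and diversity
diagnostics needed to audit the result.

## The method

Each WSI receives a four-component score tuple:

1. **Normalized density count score** ∈ [0, 2]:
   `Σ_b w_b · n_b / N`, where `n_b` counts the WSI's evaluable ROIs in
   density bin *b* (low: x ≤ 10%, medium: 10% < x ≤ 40%, high: x > 40%),
   `N` is the WSI's total ROI count, and weights are
   `w = (high 2, medium 1, low 0)`.
2. **Race and ethnicity score** ∈ {0, 2, 4}: 2 points if race is present
   and ≠ White, plus 2 if ethnicity is present and Hispanic or Latino.
3. **Stage, age and sex score** ∈ [0, 6]: stage III/IV 2, I/II 1; age
   ≤ 50 or 81+ 2, 51–60 or 71–80 1, 61–70 0 (whole years); sex present
   and ≠ F 2.
4. **Pitfall score** ≥ 0: each pitfall occurrence across the WSI's ROIs
   scores its rarity tier (rare 2, semi-rare 1, common 0).

Missing data always contributes 0 points. Cases are sorted by descending
lexicographic comparison of the tuple — a later component is consulted
only to break a tie in all earlier ones, residual ties fall back to the
WSI identifier — then deduplicated to one WSI per patient (keeping the
best-ranked section) and the top `batch_size × n_batches` cases are dealt
round-robin (1, 2, …, n, 1, 2, …) into batches. Diversity is audited with
the Shannon entropy of the density-bin counts and the Fisher–Pearson
skewness of the densities, before vs. after selection.

## Worked example

```r
library(stilsort)

coh <- generate_cohort(two_site_preset(seed = 1))
coh
#> <cohort> 105 patients at 2 site(s), 121 WSIs, 1210 ROIs (954 evaluable)

plan <- prioritize_cases(coh)
plan
#> <batch_plan> 121 WSIs ranked, 16 duplicate section(s) excluded
#>   5 batches of 8 cases (top 40 of 105 unique patients)

head(as.data.frame(plan), 3)
#>   rank         wsi_id  patient_id density_score race_ethnicity_score
#> 1    1 site_b-P006-W1 site_b-P006           0.8                    2
#> 2    2 site_b-P012-W1 site_b-P012           0.8                    2
#> 3    3 site_a-P004-W1 site_a-P004           0.8                    0
#>   bcs_age_sex_score pitfall_score batch
#> 1                 2             2     1
#> 2                 0             0     2
#> 3                 2             1     3

diversity_report(coh, plan)
#> <diversity_report> unit: evaluable ROI
#>   entropy  (base 2.718): 0.8480 -> 1.0310
#>   skewness (g1): 2.0581 -> 1.2895
#>   bin counts before: low 636, medium 213, high 105
#>   bin counts after:  low 163, medium 90, high 69
```

The synthetic two-site cohort starts strongly low-skewed (67% of
evaluable ROIs in the low bin, skewness 2.06). The rank-sort's top 40
cases carry a much more even bin distribution — entropy rises from 0.85
to 1.03 nats and skewness falls to 1.29 — while the score tuples show the
selection favoring non-White patients, higher stages and rare pitfalls at
equal density profiles.

The same workflow is available from a shell via `inst/exec/stilsort`
(subcommands `simulate`, `harmonize`, `score`, `rank`, `batch`,
`report`); every run writes a `run_manifest.json` with the resolved
configuration, input digests and seed.

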