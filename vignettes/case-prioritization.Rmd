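---
title: "Prioritizing histopathology cases into annotation batches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing histopathology cases into annotation batches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stilsort)
```

## The task and its assumptions

A reader study for validating sTILs-assessment models needs pathologist
annotations on batches of whole slide images (WSIs). Two facts shape the
design of `stilsort`. First, clinical TNBC cohorts are dominated by low
sTILs densities and by each site's majority demographics, so uniform
sampling yields a validation set that barely covers the subgroups where
model performance is least certain. Second, annotation capacity is the
scarce resource — a batch of 8 cases with ~10 ROIs each is roughly an
hour of expert time — so the order in which cases enter the study
matters more than any post-hoc reweighting.

The method is deliberately simple: a *hierarchical rank-sort*. Each WSI
gets a tuple of four scores and cases are ordered by descending
lexicographic comparison — the sTILs density profile dominates, then
race/ethnicity, then stage/age/sex, then assessment pitfalls, each later
component acting only as a tie-break for the earlier ones. The method
assumes first-pass ROI densities are informative enough to rank on
(they are preliminary estimates, not ground truth) and that per-patient
deduplication (keeping the best-ranked of several sequential sections)
is acceptable because sections of one biopsy are nearly interchangeable.

## Scores and their parameters

All score tables live in `prioritization_config()` and are plain data;
nothing is learned.

* **Normalized density count score** ∈ [0, 2]. Bin fractions of the
  WSI's ROIs times weights (high 2, medium 1, low 0), with bins
  low ≤ 10% < medium ≤ 40% < high (boundaries inclusive on the left
  bin). The denominator is configurable: the default `"all"` counts
  every ROI annotated on the WSI, so not-evaluable ROIs dilute the
  score; `"evaluable"` restricts to binnable ROIs. Both readings are
  defensible for a score described as a fraction of "total ROIs in the
  WSI" when only evaluable ROIs carry densities; we default to the
  literal total and surface the switch.
* **Race and ethnicity score** ∈ {0, 2, 4}: two points each for
  race present and ≠ White, and ethnicity present and Hispanic or
  Latino.
* **Stage, age, sex score** ∈ [0, 6]: stage III/IV → 2, I/II → 1;
  age brackets in whole years (≤ 40, 41–50, 81–90 → 2; 51–60,
  71–80 → 1; 61–70 → 0); sex present and not female → 2. The published
  bracket table stops at 90; we score ages above 90 with 2 points —
  they are the rarest of all — and expose the bracket table in the
  config. Non-integer ages are floored.
* **Pitfall score** ≥ 0: every pitfall occurrence on the WSI's ROIs is
  worth its rarity tier (rare 2, semi-rare 1, common 0). The default
  tier map is fixed; `derive_rarity_map()` recomputes tiers from a new
  cohort using distinct-WSI counts with thresholds ≤ 2 (rare) and
  ≤ 10 (semi-rare). Labels missing from the map are a hard error by
  default — silent zeros would hide vocabulary drift — with a lenient
  warn-and-zero mode.

Missing values contribute 0 points everywhere, never "not-F" or
"not-White" credit: enrichment should reward documented membership in an
underrepresented group, not absence of documentation, and the
missing-never-raises-a-score property is enforced by tests.

Residual ties after all four components are broken by ascending
`wsi_id` in byte order. Any deterministic content-based key would do;
identifier order makes the ranking reproducible regardless of how the
input tables were sorted on disk.

## Harmonization choices

Raw site exports are mapped to a controlled vocabulary by a data
dictionary (column aliases, value aliases, types). Every value coded as
unknown (`Unknown`, `NA`, `N/A`, empty, case variants) becomes the
single missing sentinel — R's `NA`, an empty field on disk — because
downstream logic treats unknown and absent identically. Unresolvable
categorical values also become missing, but each substitution is logged,
so vocabulary drift is visible without aborting a load. Structural
violations (duplicate identifiers, dangling references, a density on a
not-evaluable ROI) do abort, listing the offending identifiers.

TNM triples are collapsed to aggregated anatomic stages I–IV through a
shipped lookup table following the anatomic stage groups of the current
staging edition; the table is an exported data frame
(`anatomic_stage_table()`) and can be replaced. Stage 0 disease
(Tis N0 M0) has no aggregated stage in I–IV and maps to missing, as does
the undefined T0 N0 M0; distant metastasis (M1) yields IV even when T or
N is unknown, since no T/N combination changes that grouping.

## Diversity diagnostics

`diversity_report()` compares the cohort with the selected batches on
the unit of the evaluable ROI: Shannon entropy of the three density-bin
counts, Fisher–Pearson skewness (`g1`; bias-corrected `G1` by flag) of
the raw densities, per-batch bin counts, and per-subgroup retention.
Entropy uses the natural logarithm over the three evaluable bins by
default; both the base and the option to include Not Evaluable as a
fourth category are exposed, because reported entropies of such studies
depend on exactly these two conventions and are otherwise not
comparable. With three bins the natural-log entropy is bounded by
ln 3 ≈ 1.0986; published figures above that bound must have used a
different base or category set, so we document ours in the report
object rather than matching any particular printed value.

## The synthetic cohort generator

`generate_cohort()` draws cohorts for testing and calibration;
`two_site_preset()` fixes the study conditions we target: 105 patients
in two sites (49/56), site-specific race mixes (87.8% vs. 36.4% White),
truncated-normal ages (means 64.98 / 62.09, SDs 14.95 / 13.80, truncated
to [18, 100] — an adult oncology cohort), all female, site-specific
stage missingness (83.7% / 23.2%, ≈ 51% pooled), ~1.35 WSIs per patient
at the first site, 10 ROIs per WSI with 79% evaluable, and densities
drawn by sampling a bin (low 0.68, medium 0.22, high 0.10) then
uniformly within it. The within-bin uniform is the simplest
distribution consistent with marginal bin frequencies, which is all a
bin-count summary pins down. Pitfall labels occur independently per ROI
with tiered rates (0.003 / 0.01 / 0.05) chosen so the rare / semi-rare /
common case-count classes emerge at a ~50-WSI cohort. Demographics and
densities are drawn independently; any real correlation between, say,
stage and density is not emulated, so passing tests demonstrate the
mechanics of enrichment, not its clinical effect size. Generation uses
one seeded generator and restores the caller's random state.

Densities are rounded to one decimal so cohorts round-trip byte-exactly
through CSV; rounding can move a draw onto a bin edge (probability
≈ 4 × 10⁻⁴), which is negligible against the ±0.02 generator-fidelity
tolerance the tests enforce at 10,000 ROIs.

## Numerical and degenerate-input conventions

* Density bins use half-open intervals with inclusive upper bounds
  (10 is low, 40 is medium); densities outside [0, 100] are errors.
* A WSI with no evaluable ROIs scores 0 density points (with a warning
  under the `"evaluable"` denominator, where the fraction is undefined);
  a WSI with no ROIs at all is an error.
* Entropy requires a positive total count; skewness requires ≥ 3 values
  and positive variance, and the diversity report records `NA` where a
  degenerate selection makes skewness undefined.
* Batching requires `batch_size × n_batches` retained cases and reports
  the shortfall otherwise; no partial batches are produced.
* Percentages in summary tables are rounded to one decimal; age decade
  bins are closed ranges 1–10, 11–20, ….

## Problem sizes used in the test suite

The suite exercises: the ranking against a brute-force pairwise-
comparison oracle on 1,000 random cohorts of ≤ 8 WSIs; the enrichment
direction (entropy up, skewness down after top-40 selection) on 100
seeded two-site cohorts of 105 patients; and generator fidelity at
10,000 ROIs. These sizes give the properties enough room to fail while
keeping the default run fast on one CPU.

## Known limitations

* The rank-sort optimizes nothing jointly: it is a greedy ordering, and
  batch-to-batch balance of density bins is whatever round-robin dealing
  yields. Integer-programming style balanced batching is out of scope.
* Point tables are fixed inputs; there is no weighting-scheme learning.
* The generator's independence assumptions (see above) mean synthetic
  results quantify the machinery, not real-world enrichment magnitudes.
* Only one site pair and one disease context are presently modeled by
  the preset; other study designs need their own `synthetic_config()`.
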