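---
title: "Quantifying drug response in organotypic tumor slice cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug response in organotypic tumor slice cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicequant)
```

## The measurement model

Organotypic slice cultures of pancreatic ductal adenocarcinoma develop a
cancerous cell outgrowth on the cut surface of each slice. Its morphology
carries the drug-response signal: flat, cubic, cylindrical and clear
outgrowths indicate viable tumor, while swollen and necro-apoptotic
outgrowths indicate severe damage. A pathologist annotates these classes and
the slice perimeter on whole-slide images; the annotation software exports
lengths in µm and areas in µm². `slicequant` consumes those tables (or
GeoJSON geometry with a µm-per-pixel scale) and computes, per slice:

- per-class outgrowth length as a percentage of the slice perimeter;
- `viable_len_pct` and `damaged_len_pct`, the group sums;
- `outgrowth_pct = viable_len_pct + damaged_len_pct`;
- `viability_pct = 100 · viable/(viable + damaged)` — of outgrowth lengths
  for surface-growing tumors, of annotated tumor areas for cultures
  quantified within the slice (poorly differentiated or insidiously growing
  tumors that form no outgrowth);
- the tumor viability index
  `TVI = 3 · viable_len_pct + 1 · damaged_len_pct`, in [0, 300].

The viability denominator is viable + damaged only: the six morphologies are
exhaustive, so this is the viable share of all measured tumor. The TVI
weights (3, 1) are the field's published values; they are configurable
through `morphology_grouping()` because no derivation fixes them, but the
defaults are never changed by the pipeline itself. A slice with a perimeter
but no outgrowth records gets `outgrowth_pct = 0` and `tvi = 0` (the index
is length-weighted, so zero outgrowth forces zero) while `viability_pct` is
left missing — a ratio over nothing is undefined, and the slice is flagged
with a warning rather than silently counted as 0% or 100% viable.

Values are averaged over the duplicate slices of each culture × condition
(arithmetic mean, missing values skipped with the count recorded), then
assembled into culture × condition matrices. "All selenite concentrations
together" medians pool the duplicate-averaged condition summaries, not raw
slices, so each culture × condition contributes one value regardless of how
many slice pieces were cut. Damage (100 − viability) maps to Evans tumor
regression grades: below 10% grade I, 10–50% IIa, above 50 up to 90% IIb,
above 90% III, and 100% (no viable tumor) IV. Only the >90% ⇒ III–IV anchor
is fixed by the response definition used here; the intermediate cuts follow
the standard Evans scheme.

## Inference

Cohorts of 6–8 cultures rule out parametric tests (a Shapiro–Wilk screen is
reported descriptively via `normality_screen()`, but nothing branches on
it). The package's tests are:

**Exact paired Wilcoxon signed-rank** (`wilcoxon_signed_rank_exact()`):
differences control − treatment per culture; zero differences are discarded
before ranking (Wilcoxon's original convention; Pratt's zero-rank variant is
available via `zero_method = "pratt"`); |d| are ranked with midranks for
ties; W is the sum of ranks of positive differences. For up to 12 effective
pairs the two-sided p is computed by full enumeration of all 2^n
equiprobable sign assignments, as the doubled smaller tail capped at 1 —
this convention is stated so results reproduce bit-for-bit. Because the
enumeration reuses the observed midranks, exact p-values remain valid under
ties, where the classical signed-rank distribution does not apply. Beyond 12
pairs (4096 sign vectors) a normal approximation with tie-corrected variance
(`Σr²/4`) and a 0.5 continuity correction takes over; study-scale cohorts
(n = 8) always use the exact path, where exactness matters. With all n = 8
differences of one sign, the smallest achievable two-sided p is 2/256 =
0.0078125.

**Benjamini–Hochberg** across the declared comparison family — by default
all four treatment-vs-control comparisons per readout; the family is
configurable because different analyses may exclude, e.g., the gemcitabine
arm. Three identical raw p-values of 0.0078125 alongside one null
comparison adjust to 4 · 0.0078125/3 ≈ 0.0104. `bh_adjust()` validates and
delegates to `stats::p.adjust(method = "BH")`; the test suite checks it
against an independently coded step-up computation.

**Friedman test with Kendall's W** (`friedman_test()`): within-culture
midranks across the k conditions, chi-square statistic with the standard
tie correction
`χ² = 12 Σ_j (R_j − n(k+1)/2)² / (nk(k+1) − Σ(t³−t)/(k−1))`,
p from the χ²(k−1) distribution, and effect size
`W = χ²/(n(k−1))` — Kendall's coefficient of concordance, 1 exactly when
every culture ranks the conditions identically without ties. The tie groups
are taken from the midranks themselves so the correction is consistent with
the rank sums (and agrees with `stats::friedman.test` to machine precision).
Incomplete cultures are dropped with a logged count.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis assumes,
so every stage is testable without patient data:

- **Design**: 8 patients, conditions control (72 h, untreated), selenite 5,
  15, 30 µM and gemcitabine 1 µM, duplicate slices per condition; 2 of 8
  patients are quantified by within-slice tumor area instead of outgrowth
  (the first cultures of the cohort, a deterministic choice).
- **Baseline**: per-patient viable fraction `v0 ~ Beta(8, 2)` (mean 0.8,
  matching control cohorts whose median viability sits near 80%).
- **Dose-response**: `v = v0 · (1 − emax · d^h/(d^h + ec50^h))` with
  defaults emax = 0.99, ec50 = 7 µM, hill = 4 — the simplest monotone model
  reproducing the observed qualitative pattern: minimal effect at 5 µM,
  >90% damage at 15–30 µM. Outgrowth declines with the same Hill term:
  `o = o0 · (1 − 0.75 · d^h/(d^h + ec50^h))`, o0 = 0.55.
- **Gemcitabine** is a per-patient Bernoulli responder flag (probability
  1/8, matching a single responder in eight tumors); responders get the
  full-effect reduction, non-responders are untouched.
- **Slice noise** is applied on the logit scale (sd 0.3 by default) so
  fractions stay in (0, 1). The within-patient duplicate variance is not
  reported in the field at this granularity; 0.3 gives duplicate slices a
  realistic spread (roughly ±7 percentage points around a 50% fraction)
  without drowning the dose effect. With `noise_sd = 0` the perturbation is
  an exact pass-through, so pipeline readouts recover the ground-truth
  fractions to machine precision — the basis of the parameter-recovery
  tests.
- **Composition**: the viable length is split across the four viable classes
  (and damaged across two) by a flat Dirichlet draw; nothing downstream uses
  the split beyond re-grouping, so its law is not critical.
- **Determinism**: one master seed; each patient uses a substream at a fixed
  offset, so growing the cohort never reshuffles earlier patients, and
  identical config + seed gives byte-identical tables.

What the generator does **not** emulate: spatial structure within slices,
annotation error or inter-observer variability, correlations between
outgrowth length and viability beyond the shared dose term, tumor
heterogeneity between slice positions, and culture-related damage in
controls. Passing tests therefore demonstrate that the computation chain is
correct and calibrated under the assumed sampling model — not that the
readouts are unbiased on real histology.

`generate_de_table()` plays the same role for the differential-expression
filter: uniform null p-values, signal genes with |log2FC| bounded away from
the threshold and p ≤ 1e-5, and lognormal read counts whose meanlog is
solved so that a chosen fraction (default 0.3) falls below the 350-read
abundance cutoff. The two-stage filter — initial calls at adjusted
p ≤ 0.05 and |log2FC| ≥ 1, then a strict list at raw p ≤ 1e-4 and ≥ 350
reads — uses inclusive thresholds throughout ("≤", "at least"), reads
"+1 or −1 log2 fold change" as |log2FC| ≥ 1 (a point-equality reading would
be vacuous), and applies the 1e-4 cutpoint to the raw p-value by default
(`use_adjusted = TRUE` switches, since published descriptions are ambiguous
on this point). The strict list is ordered by ascending p, then descending
|log2FC|, then gene id, so "top gene" output is reproducible.

## Numerical and design choices

- Unknown annotation classes are rejected, never coerced: grouping drives
  every readout, so a silent mis-grouping would corrupt all three.
- Duplicate (slice, class, kind) rows are summed — multiple disjoint
  annotations of one morphology on one slice (e.g. on halved slice pieces)
  are one measurement.
- Outgrowth vs area mode is detected per slice from the record kinds
  present (a perimeter record ⇒ outgrowth mode); area-mode cultures simply
  lack the length-based readouts and drop out of those matrices.
- Percentages are reported to one decimal in rendered reports; full double
  precision is retained internally and in CSV output (15 significant
  digits).
- Pairwise-complete pairing: each treatment-vs-control test uses the
  cultures observed in both columns.
- Degenerate comparisons (all differences zero) return p = 1 with a flag
  rather than an error, so a control-vs-itself family member cannot crash a
  run.

## Problem sizes in the test suite

The suite exercises the study scale directly: exact-test enumeration is
verified against an independently coded brute force for all n ≤ 10 (200
random datasets), BH against step-up arithmetic on 500 random vectors, the
Friedman χ² p against a 10,000-draw within-block permutation null at
n = 8, k = 4 (tolerance 0.05, covering Monte-Carlo error plus the χ²
approximation error at this n), TVI bounds on 1,000 random slices, exact
parameter recovery on a noise-free cohort, and the test's size on 500 null
cohorts (emax = 0) at α = 0.05. These sizes make the suite run in a few
minutes while keeping Monte-Carlo margins small relative to the effects
checked.

## Limitations

- The package quantifies annotations; it does not classify morphology from
  images, align reads, or fit differential-expression models — it consumes
  their outputs.
- Exact inference is only available up to 12 effective pairs; beyond that
  the normal approximation is standard but not exact.
- The Evans mapping uses damage alone; the full grading system also weighs
  fibrosis, which annotation tables do not carry.
- Kendall's W is reported as the Friedman effect size by convention; other
  effect measures exist and are not implemented.
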