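---
title: "Methods: region-level GAG profiling and small-sample differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-level GAG profiling and small-sample differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagomics)
library(dplyr)
```

This vignette documents the statistical model behind `gagomics`, the
conventions the package commits to where the field leaves room, the
synthetic data model used for validation, and the package's known
limitations.

## The data and the problem

A region-annotated tissue study produces three tables: a region
metadata table (patient, morphological class, semiquantitative mucin
and stroma scores 1–3, absent for normal tissue), a GAG disaccharide
amount table (analyte × region, pmol), and a label-free protein
intensity matrix (protein × region) riddled with missing values. Group
sizes are tiny — three to ten regions per morphology class — so the
usual asymptotic tests and FDR machinery are a poor fit; the analysis
must be exact, transparent about what is achievable at such sizes, and
honest about missingness.

## Lawrence codes and composite analytes

Lyase digestion converts CS and HS chains into Δ-unsaturated
disaccharides named by the Lawrence code: `D` (Δ-uronic acid), a digit
for uronic 2-O-sulfation, a hexosamine letter (`a` GalNAc → CS, `A`
GlcNAc → HS, `S` N-sulfated GlcN → HS; case is meaningful), and
trailing digits for hexosamine O-sulfation (`0`, `4`, `6`, `10` =
4-O + 6-O). Total sulfates per disaccharide range 0–3.

Chromatography does not resolve every isomer: `D2A0`/`D0A6` and
`D2S0`/`D0S6` are quantified as single composite peaks. A composite is
only meaningful if its members agree in GAG class and in their
(N, O) sulfate counts — both supported composites do (0, 1) and
(1, 1) — and `build_analyte()` rejects any other pairing, because the
per-peak sulfation accounting would otherwise be ambiguous. Labels are
canonicalised to `+`-joined form with no spaces.

## Sulfation statistics

For a profile (one region, one GAG class) with amounts $a_i$ and
per-disaccharide sulfate counts $s_i$:

* total amount $T = \sum_i a_i$ (pmol; no normalisation to region area
  is applied);
* relative composition $100\, a_i / T$;
* **average rate of sulfation** $\bar{s} = \sum_i (a_i/T)\, s_i$. The
  field names this metric without writing a formula; the
  mole-fraction-weighted mean is the standard glycomics convention and
  the only linear choice: scaling all amounts by $c>0$ leaves
  $\bar{s}$, the composition and every ratio unchanged while scaling
  $T$ by $c$ (tested as an invariant).
* **6S/4S ratio** (CS): $a(\mathrm{D0a6}) / a(\mathrm{D0a4})$.
* **N/O ratios** (HS): computed by counting *sulfate groups*, not
  molecules. The monosulfated stratum compares `D0S0` (one N) with
  `D2A0+D0A6` (one O); the disulfated stratum compares the N-sulfate
  of `D2S0+D0S6` with its own O-sulfate plus the two O-sulfates of
  `D2A6`; the total ratio tallies $\sum a_i n_i / \sum a_i o_i$ over
  all analytes, so the trisulfated `D2S6` contributes 1 N and 2 O.
  Molecule counting is a defensible alternative, but it cannot handle
  composite peaks unambiguously; the group-counting convention is the
  package's committed choice and is cross-checked in the tests against
  a brute-force counter that expands composites into member codes.

Degenerate inputs never silently become numbers: a zero denominator or
an all-zero profile yields `NA` with a warning, not 0 or `Inf`.

## The exact rank test and the minimal-p regime

Groups are unpaired and unequal, so `exact_rank_p()` implements the
two-sample (Mann–Whitney) rank-sum test. Up to 12 pooled observations
(every group comparison in a 22-region cohort) the null distribution
is enumerated completely: all $\binom{n_1+n_2}{n_1}$ assignments of
the observed mid-ranks, with the two-sided p defined as the null mass
of rank sums at least as far from the null mean as observed. This
definition coincides with the classical tables for tie-free data and
extends cleanly to ties, because the enumeration is done on the
observed tied rank configuration. Larger pooled samples switch to the
mid-rank normal approximation with tie and continuity corrections
(agreement within 0.02 at 15 + 15 is a tested property).

With $n_1 = 3$ and $n_2 = 4$, complete separation gives
$p = 2/35 \approx 0.057$ — no feature can ever pass $p < 0.05$.
`compare_groups()` therefore applies a *relaxed* rule: when
`min_achievable_p(n1, n2) >= alpha`, significance becomes
$p \le$ that floor, so maximally separated features still register.
The rule is keyed to the per-feature observed counts (missing values
are dropped pairwise, never imputed for testing), generalising the
3-vs-4 case to any comparison driven into the same regime by
missingness. No multiple-testing correction is applied by default —
at these group sizes the exact test is already conservative and the
screening intent favours sensitivity — but Benjamini–Hochberg is one
argument away (`adjust = "BH"`). Fold changes are ratios of group
means of raw abundances (medians via `fc_method = "median"`); the
mean convention is the package's choice where the field reports only
ranges.

## Multivariate protocol

Feature selection is deliberately different for the two methods:
clustering tolerates limited missingness (features quantified in ≥ 10
regions; remaining gaps imputed with the per-feature minimum observed
value as a below-detection proxy), while PCA uses complete-case
features only. Protein intensities are log2-transformed before
scaling — intensity noise is multiplicative — whereas GAG matrices are
analysed as relative percentages, already compositional, untransformed.

Clustering is agglomerative with Euclidean distances under the
Ward.D2 criterion (`stats::hclust`); merge heights equal
$\sqrt{2\,\Delta\mathrm{ESS}}$ and are verified against an independent
naive Ward implementation that recomputes every merge from cluster
centroids. PCA runs on autoscaled variables via the singular value
decomposition (`stats::prcomp`), with one determinism fix on top: each
loading vector is oriented so its largest-magnitude element is
positive, making scores and loadings reproducible across platforms.
Nothing in this module is stochastic.

## The synthetic data model

The generator exists to validate the pipeline by parameter recovery,
and its defaults are fixed to the study conditions the package
targets:

* **Cohort layout** — 7 patients contributing 2, 2, 5, 3, 4, 3, 3
  regions (22 total); morphology sampled with probabilities 4/22
  normal, 10/22 solid, 3/22 tubular, 5/22 papillary; tumor regions
  carry mucin/stroma scores with probability 0.5 / 0.85.
* **GAG profiles** — expected amounts are (group composition) ×
  (class base total: CS 20, HS 10 pmol) × (morphology multiplier:
  CS 2.5 / 4.0 / 4.4 and HS 2.5 / 4.8 / 8.5 for solid / papillary /
  tubular). The normal HS composition was solved analytically so a
  noise-free normal profile hits N/O ratios of exactly
  0.34 / 0.89 / 0.53 (mono / di / total), and the CS baseline gives
  6S/4S ≈ 0.90. Tumor composition reweights the baseline: sulfated
  analytes × 20 (CS) or × 3 (HS), `D0a6` additionally × 1.36 (solid)
  or 1.47 (tubular), N-sulfated HS analytes ÷ 4. These land the
  noise-free tumor profiles at ≈ 3.9× the normal CS sulfation rate,
  6S/4S ≈ 1.23 (solid) / 1.33 (tubular), and a ≈ 3× drop in total
  N/O. One caveat is structural: because the normal N/O targets force
  a fairly sulfated normal HS baseline, the planted tumor increase in
  *average HS sulfation* is modest — the generator reproduces the
  directions and the ratio shifts, not every reported magnitude
  simultaneously.
* **Noise** — mean-preserving multiplicative log-normal noise,
  CV 0.2 by default, on every amount and intensity.
* **Proteins** — log2 baselines $\mathcal{N}(25, 2^2)$; a configurable
  fraction of proteins (default 10%) is multiplied by a log-uniform
  fold change (default 2–4, half inverted) in every tumor region.
  Missingness is two-component: 5% MCAR plus soft left-censoring
  below the 15th intensity percentile (logistic in log2 intensity,
  width 0.5), totalling ≈ 20% — typical of FFPE LFQ data; real
  per-region missingness profiles are unpublished, so these are
  literature-typical defaults, clearly labelled as such.

Everything is deterministic given (seed, config); changing only the
seed changes values but not the planted truth structure.

What passing the recovery tests does and does not show: the generator
plants clean group effects with exchangeable regions, no
patient-level correlation, no spatial structure within sections, no
batch effects, and missingness that follows intensity only. Recovery
under these conditions validates the arithmetic and the inferential
logic, not robustness to the full messiness of real tissue data.

## Problem sizes used in validation

The suite runs exhaustive rank-test oracle checks up to pooled size 8;
Ward-vs-naive comparisons on 50 random 6-point sets; a 1000-feature
5-vs-5 planted null for type-I calibration; 200 simulated 5-vs-5
cohorts for total-amount multiplier recovery (observed mean within
0.3% of the planted 4.0); a 200-protein 10-vs-10 power check at fold
change 4 (observed power 1.0); 100 seeded 12-region cohorts with
5-within-group-SD separation for dendrogram and PC1 label recovery
(100/100 in both); and 1000 random profiles for the metric
invariants. These sizes were chosen to make the Monte-Carlo margins
comfortable at desk scale.

## Known limitations

* No paired or covariate-adjusted designs; the tests assume
  exchangeable regions, ignoring that regions nest within patients.
* No isomer deconvolution: composite peaks stay composite, which is
  precisely why the N/O convention counts sulfate groups.
* Minimum-value imputation before clustering biases censored values
  downward; it is logged and applies only to the heatmap/clustering
  path, never to testing.
* The relaxed minimal-p rule trades type-I strictness for any
  sensitivity at all in 3-vs-4 comparisons; at those sizes a
  "significant" call means complete separation and nothing stronger.
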