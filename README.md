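# gagomics

Tidy R tools for comparing tissue regions by their glycosaminoglycan
(GAG) disaccharide profiles and label-free proteomes.

Tumor tissue is heterogeneous: a single FFPE section can contain
morphologically distinct regions (solid, tubular, papillary growth,
adjacent normal tissue) that differ in their extracellular matrix. Two
read-outs capture that difference well. On-tissue digestion of
chondroitin sulfate (CS) and heparan sulfate (HS) chains yields
disaccharide building blocks — named by the Lawrence code (`D0a4`,
`D2S6`, co-eluting pairs such as `D2A0+D0A6`) — whose amounts and
sulfation patterns summarise the GAG state of each region. In parallel,
label-free quantification (LFQ) gives a protein-by-region intensity
matrix with many missing values. Both tables are small in the sample
dimension (a handful of regions per group), which shapes every
statistical choice in this package.

`gagomics` provides:

* **Lawrence-code data model** — a case-sensitive parser
  (`parse_lawrence_code()`), composite co-eluting analytes
  (`build_analyte()`) with validated per-disaccharide N/O sulfate
  counts, and response-factor calibration of peak areas
  (`calibrate_areas()`).
* **Sulfation statistics** (`summarize_profiles()`) — per region and
  GAG class: total amount (pmol), relative composition (%), the average
  rate of sulfation

  `s̄ = Σᵢ (aᵢ / Σⱼ aⱼ) · sᵢ  ∈ [0, 3]`

  (mole-fraction-weighted sulfate groups per disaccharide), the CS
  6S/4S ratio `a(D0a6)/a(D0a4)`, and the HS N/O sulfation ratios
  computed by counting sulfate groups per stratum (mono, di, total).
* **Exact small-sample differential abundance** — `exact_rank_p()`
  enumerates all `C(n₁+n₂, n₁)` rank assignments, so for groups of 3
  and 4 the smallest achievable two-sided p is `2/35 ≈ 0.057`, above
  the conventional 0.05. `compare_groups()` therefore relaxes the
  cutoff to `p ≤ min_achievable_p(n₁, n₂)` whenever that floor is at or
  above α, reports mean-ratio fold changes, and applies the
  quantified-in-≥3-regions-in-≥2-groups filter (`filter_quantified()`).
* **Multivariate structure** — Ward.D2 hierarchical clustering
  (`ward_cluster()`, `heatmap_order()`) and PCA on autoscaled
  complete-case features (`gag_pca()`), with `tidy()`/`glance()`
  methods and `autoplot()`.
* **Synthetic cohorts with ground truth** (`synthetic_config()`,
  `generate_cohort()`) — seeded generators for region metadata, GAG
  profiles with planted total-amount and sulfation shifts, and LFQ
  matrices with planted fold changes and realistic missingness, used to
  validate the whole pipeline by parameter recovery.
* **Pipeline runner** (`run_pipeline()`) — reads the tabular inputs,
  chains filter → compare → summarise → cluster → PCA, and writes TSV
  results plus a JSON run log.

## Worked example

The package ships a transcribed 22-region annotation table
(7 patients; morphology plus semiquantitative mucin/stroma scores).

```r
library(gagomics)
library(dplyr)

meta <- read_region_table(gagomics_example("regions.tsv"))
table(meta$morphology)
#>    normal papillary     solid   tubular
#>         4         5        10         3

# synthetic GAG profiles for these regions, seeded
gag <- generate_gag_dataset(synthetic_config(seed = 1), meta)
summarize_profiles(gag$amounts) |>
  left_join(derive_groups(meta, "morphology"), by = "region") |>
  filter(gag_class == "CS") |>
  group_by(group) |>
  summarise(across(c(total_pmol, avg_sulfation, ratio_6s4s), mean))
#>   group     total_pmol avg_sulfation ratio_6s4s
#> 1 normal          20.5         0.250      1.04
#> 2 papillary       78.8         0.909      0.865
#> 3 solid           52.2         0.927      1.53
#> 4 tubular         93.8         0.950      1.18
```

Tumor regions carry 2.5–4.4× more CS than adjacent normal tissue and
an average sulfation rate almost 4× higher — these are the planted
generator effects being recovered from noisy per-region profiles.

```r
prot <- generate_protein_dataset(synthetic_config(seed = 1), meta)
grp  <- derive_groups(meta, "morphology")
filt <- filter_quantified(prot$matrix, grp)      # 260 of 300 kept
res  <- compare_groups(filt, grp, "normal", "tubular")
res |> filter(significant) |> arrange(p_value) |> head(3)
#>   feature   n_a  n_b p_value alpha_used fold_change
#> 1 PROT0006    4    3  0.0571     0.0571       0.499
#> 2 PROT0007    4    3  0.0571     0.0571       2.50
#> 3 PROT0010    4    3  0.0571     0.0571       0.350
```

With 4 normal vs 3 tubular regions no feature can reach p < 0.05, so
`compare_groups()` flags features at the exact floor 2/35 ≈ 0.0571
(`alpha_used`); the fold changes are tumor-over-normal mean ratios.

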