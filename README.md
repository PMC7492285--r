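# qmricart

Serial multiparametric quantitative MRI (qMRI) analysis of articular
cartilage under indentation loading, for imaging scientists studying
cartilage functionality: pixel-wise T1 / T1ρ / T2 / T2\* mapping with
quality control, zonal/regional ROI construction, response-to-loading
statistics and the paired statistical battery — plus a synthetic phantom
generator so the entire chain is testable with known ground truth.

## The analysis in one paragraph

A cartilage-on-bone sample is imaged serially: unloaded (δ₀) and indented
by a flat 10 mm piston at 15.1 N (δ₁) and 28.6 N (δ₂), both before and
after an exposure that alters its composition (e.g. enzymatic proteoglycan
depletion). Each acquisition series (inversion times for T1, spin-lock
durations for T1ρ, echo times for T2/T2\*) is fitted pixel-wise with
mono-exponential models — `S(t) = S₀ e^{−t/τ}`, or
`|S₀ (1 − b e^{−t/τ})|` for magnitude inversion recovery — keeping only
pixels whose degrees-of-freedom-adjusted R² exceeds 0.95 (and, for T2/T2\*,
only echoes < 60 ms). The segmented sample is split into seven ROIs: the
entire sample (ECS), the 8 mm sub-pistonal band (SPA), the merged bilateral
peri-pistonal remainder (PPA), and upper/lower halves of SPA and PPA.
Functionality is read out as relative changes of per-sample ROI means,

    Δx = (T_δx / T_δ0 − 1) · 100 [%]        (loading response, per session)
    Δ0 = (T_δ0post / T_δ0pre − 1) · 100 [%] (exposure effect at rest)

tested with Wilcoxon matched pairs (Δ₀), paired t (Δ₁/Δ₂ pre vs post),
Friedman + Dunn (absolute values across loads) and repeated-measures ANOVA
(heights, pixel counts), under Bonferroni–Holm correction at α = 0.01.

## Worked example

Simulate a two-arm study (5 controls, 5 high-dose samples), fit T2 maps,
and summarise the exposure effect at rest:

```r
library(qmricart)

res <- run_pipeline(study_config(
  arms = c(control = 5, HT = 5), seed = 42,
  modalities = "T2_SE", loads = "delta0",
  spec_args = list(grid_rows = 32, grid_cols = 96)))

t1 <- res$tables$table1
t1[t1$roi %in% c("ECS", "SPA_upper"),
   c("arm", "modality", "roi", "mean", "sd", "n", "p_raw", "p_holm")]
#>       arm modality       roi  mean    sd n  p_raw p_holm
#> 1      HT    T2_SE       ECS  10.2 0.245 5 0.0625  0.875
#> 2      HT    T2_SE SPA_upper  11.4 0.523 5 0.0625  0.875
#> 3 control    T2_SE       ECS -12.3 0.106 5 0.0625  0.875
#> 4 control    T2_SE SPA_upper -10.9 0.243 5 0.0625  0.875
```

Reading the output: each row is one arm × modality × ROI cell of the
"exposure effect at rest" table — the group mean ± SD of the per-sample Δ₀
in percent, with the raw Wilcoxon matched-pairs p value and its
Holm-adjusted counterpart. The control phantoms carry a global T2 decrease
(≈ −12%) and the high-dose phantoms a predominantly superficial increase
(≈ +11% in the sub-pistonal upper half); the pipeline recovers both from
noisy images at SNR 50. With only five samples per arm the smallest
attainable exact Wilcoxon p is 1/16, so nothing clears α = 0.01 — as it
should.

Lower-level entry points: `build_truth()` / `apply_load()` /
`apply_exposure()` / `synthesize_series()` (phantoms), `fit_map()`
(relaxometry), `exclude_boundaries()` / `partition_rois()` /
`caliper_heights()` (geometry), `build_delta_records()` (responses),
`wilcoxon_matched()` and friends (statistics), `write_series()` /
`read_series()` (NIfTI + JSON sidecar I/O).

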