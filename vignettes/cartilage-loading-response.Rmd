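---
title: "Serial qMRI analysis of cartilage under indentation loading: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial qMRI analysis of cartilage under indentation loading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Early cartilage degeneration — loss of matrix proteoglycans, collagen
disorganisation, water uptake — changes how the tissue bears load before any
morphological damage is visible. Serial quantitative MRI (qMRI) probes this
*functional* state: the same sample is mapped unloaded and under two levels
of pressure-controlled indentation (a flat 10 mm piston pressed onto the
articular surface at 15.1 N and 28.6 N), both before and after an exposure
that alters its composition. The readout is not the absolute relaxation
time but its *relative change*,

$$\Delta_x = \left(\frac{T_{\delta_x}}{T_{\delta_0}} - 1\right)\cdot 100\ [\%],
\qquad
\Delta_0 = \left(\frac{T_{\delta_0,\mathrm{post}}}{T_{\delta_0,\mathrm{pre}}} - 1\right)\cdot 100\ [\%],$$

computed per sample on region-of-interest (ROI) means and summarised across
samples as mean ± SD. `qmricart` implements this whole chain — phantom
simulation, pixel-wise relaxometry, ROI geometry, response statistics and
the paired statistical battery — as composable, tested R functions.

Because raw serial cartilage MRI of this kind is not publicly deposited,
the package ships a first-class synthetic-data generator. Every downstream
stage is exercised, and its recovery verified, against phantoms with known
ground truth.

# Signal models and fitting

Four modalities are supported, each a mono-exponential magnitude model of
its timing variable:

* spin echo (T2), gradient echo (T2\*) and spin lock (T1rho):
  $S(t) = S_0\, e^{-t/\tau}$;
* inversion recovery (T1): the three-parameter magnitude model
  $S(t) = \lvert S_0 (1 - b\, e^{-t/\tau}) \rvert$ with inversion factor
  $b \in (0, 2]$ fitted freely. Magnitude IR with a free $b$ is robust to
  imperfect inversion and needs no sign restoration of the magnitude data.

Default timing vectors mirror a clinical 3.0 T protocol: six inversion
times (150–1500 ms), five spin-lock durations (0–40 ms; the zero-duration
point is part of the series and is fitted), twelve spin echoes ($n \times
8.4$ ms) and fifteen gradient echoes ($3.3 + n \times 5.2$ ms). For T2 and
T2\* only echoes strictly below 60 ms are fitted (`select_times()`), which
limits noise-floor bias at long echo times; the cutoff does not apply to T1
or T1rho.

Fitting is bounded multi-start Levenberg–Marquardt least squares,
vectorised across the pixels of a map (all pixels share the timing vector,
so residuals, Jacobians and the damped 2×2 / 3×3 normal equations are plain
matrix operations; `fit_pixel()` and `fit_map()` run the same engine).
Numerical choices:

* **Bounds.** $\tau \in [1, 5000]$ ms for T1, $[1, 500]$ ms otherwise;
  $S_0 \in (0, 10\times \max S]$; $b \in (0, 2]$. Steps are projected onto
  the bounds.
* **Starts.** Five log-spaced $\tau$ values across the bounds, each with
  the analytic conditional amplitude $S_0^* = \langle y, m\rangle /
  \lVert m\rVert^2$ for the start's model shape $m$. The best-residual
  start wins; starts are scanned in increasing $\tau$ order with strict
  improvement, so ties break towards the smaller time constant. For
  inversion recovery the grid is augmented with null-point starts
  $\tau = \mathrm{TI}_k / \ln b_0$ (one per inversion time, $b_0 = 1.9$):
  the magnitude IR objective is multi-modal and log-spaced starts alone
  often converge to the wrong basin on noisy data.
* **Convergence.** A pixel converges when an accepted step changes the
  residual sum of squares by less than `ftol` (default $10^{-12}$,
  relative), when the gradient is negligible, or when damping saturates at
  a local minimum; pixels that exhaust `max_iter` (default 60) without
  meeting this are flagged unconverged, not raised.
* **Degenerate pixels** (constant or non-finite signal) are flagged and
  excluded downstream.

Fit quality is gated per pixel by the R² *adjusted to the degrees of
freedom*, $1 - (1 - R^2)(n-1)/(n-p-1)$, at a default threshold of 0.95.
Whether such a threshold should be read against the plain or the adjusted
R² is ambiguous when both are quoted together; this package applies it to
the adjusted statistic (the stricter reading, since adjusted ≤ plain) and
makes the threshold configurable. ROI means aggregate *valid pixels only* —
consistent with gating pixels at R² > 0.95 in the first place.

# Geometry: masks, heights, seven ROIs

Row 1 of the raster is the articular surface (adjacent to piston or
medium); row index grows with depth. On a segmentation mask
(`seg_mask()`):

* `column_heights()` returns per-column pixel counts × pixel spacing;
* `caliper_heights()` mimics a digital caliper with single-pixel
  resolution: heights at the piston centre column and at
  ±`round(2 mm / spacing)` columns, averaged;
* `exclude_boundaries()` removes the topmost and lowermost in-mask pixel
  of every column (partial-volume control at both interfaces);
* `partition_rois()` builds the seven ROIs: the sub-pistonal area (SPA) is
  the band of `round(8 mm / spacing)` columns centred on the piston centre;
  the peri-pistonal area (PPA) merges all remaining in-mask pixels on both
  sides (no outer limit); each column's upper half holds its
  $\lceil h/2 \rceil$ shallowest pixels. ECS = SPA ∪ PPA.

Fixed conventions, chosen once and documented rather than inferred: for an
even SPA band width the extra column goes to the right of the centre; odd
column heights give the extra pixel to the upper half; fractional pixel
heights are floored (a conservative mask). ROIs are rebuilt per load level
from that configuration's mask, since loading changes the geometry; no
pixel correspondence across configurations is assumed, which is also why
all response statistics are computed on ROI means per sample, never
per-pixel.

# The phantom generator

`phantom_spec()` + `build_truth()` construct a flat cartilage slab of
`round(12 mm / spacing)` columns on a 64 × 128 grid (0.232 mm pixels) by
default, with the truth thickness drawn per sample from a normal
distribution (controls 2.77 ± 0.19 mm; low-dose arm 2.59 ± 0.32 mm;
high-dose arm 2.40 ± 0.41 mm). Within each column every relaxation
parameter falls linearly from a surface to a deep value (defaults: T1
1200→900 ms, T1rho 60→40 ms, T2 55→30 ms, T2\* 35→20 ms) — real cartilage
shows depth-decreasing profiles, and a linear ramp is the simplest shape
with that property; the values are configurable, not measurements.

Three kinds of effects are injected multiplicatively, per parameter × zone
(upper/lower) × region (SPA/PPA):

* **Exposure** (`apply_exposure()`): the unloaded post-exposure truth is
  the pre-exposure truth scaled by arm-specific factors $1 + \Delta_0/100$,
  with the default percentages taken from the group-mean effects the
  generator is designed to emulate (controls: global decreases of roughly
  −12% in T1rho/T2; high-dose trypsin: superficial increases, e.g. +4.0%
  for sub-pistonal upper-half T1).
* **Loading** (`apply_load()`): sub-pistonal columns are compressed by 8%
  (15.1 N) or 15% (28.6 N) of their height, peri-pistonal columns by 2% /
  4% (compressed heights floored to whole pixels; the mask therefore
  strictly shrinks), the depth profile is re-spanned over the compressed
  column, and session-specific loading multipliers are applied. Strain
  magnitudes are generator conventions — the emulated experiment reports
  significant height decreases but no strain values.
* **Session-specific loading multipliers.** The loading multipliers differ
  between the pre- and post-exposure sessions, sourced from the respective
  observed loading responses. A single session-independent set cannot
  represent the phenomenon of interest — exposure *changing the response to
  loading* (e.g. the post-exposure sub-pistonal T2 decrease under strong
  loading roughly tripling after high-dose exposure) — so the generator
  makes the session a first-class axis of the loading model.

Noise is Rician: each pixel magnitude becomes
$\sqrt{(S + \sigma X)^2 + (\sigma Y)^2}$ with independent standard normal
$X, Y$, default $\sigma = S_0/50$ (SNR 50; the emulated protocol does not
state an SNR, and 50 is a realistic magnitude-image figure at 3.0 T with a
small surface coil). All randomness derives from one master seed via
`derive_seed()`; regeneration is bit-identical.

What the phantom does **not** emulate: biphasic/poroelastic mechanics,
lateral bulging, B0/B1 inhomogeneity, partial-volume mixing at interfaces,
slice profile, motion, and biological between-sample variability of the
*effect sizes* (every sample in an arm receives the same multipliers, so
group SDs of recovered Δ reflect noise and fitting alone and are much
smaller than biological SDs). Passing recovery tests therefore shows the
*pipeline* is unbiased and correctly wired — not that the simplified image
model captures real tissue.

# Statistics

The battery mirrors standard practice for this design:

* `wilcoxon_matched()` — exposure effects at rest (δ0 pre vs post), exact
  signed-rank distribution up to n = 25 untied differences, tie-corrected
  normal approximation beyond;
* `paired_t()` — pre- vs post-exposure loading responses (Δ1, Δ2);
* `friedman_dunn()` — absolute values across the three load levels
  (mid-ranks for ties), with Dunn's pairwise z tests on mean ranks and
  Bonferroni scaling over the three load pairs;
* `rm_anova()` — heights and pixel counts across load levels
  (within-subject one-way F, no sphericity correction: with k = 3
  equally-spaced levels and no stated correction in the practice being
  mirrored, the uncorrected F is reported);
* `holm_adjust()` — step-down Bonferroni–Holm, α = 0.01.

The Holm family is one family per modality per table by default
(configurable to per-table or none): p values from different relaxation
parameters answer different physiological questions and are not pooled.
`study_tables()` assembles the two report tables (exposure effects at
rest; loading responses pre vs post) with group mean ± SD, raw and adjusted
p values and significance flags; cells with fewer than two samples report a
mean with a missing SD.

Degenerate inputs are flagged rather than raised throughout: all-zero
difference vectors (Wilcoxon p = 1), zero-variance differences (paired t),
fully tied load triples (Friedman statistic 0, p = 1), constant
repeated-measures data.

# Verification strategy and problem sizes

* **Oracles.** Noiseless synthesis → fit recovers generating parameters to
  10⁻⁴ relative error for all four modalities; the fitter matches an
  exhaustive 0.1 ms × 0.1-unit grid search within 1% median on noisy
  pixels, and an independent Levenberg–Marquardt implementation
  (`minpack.lm`) on decay data; Wilcoxon exact p equals full 2ⁿ sign
  enumeration; Holm equals hand-computed step-down; the repeated-measures F
  equals hand-partitioned sums of squares.
* **Recovery.** With effects injected at the defaults, the full pipeline
  (SNR 50 synthesis → fitting → R² gate → ROI partition → Δ) recovers the
  injected group effects within 2·SD/√n of their sourced values on studies
  of 9–10 phantoms at the 64 × 128 grid; caliper heights recover the truth
  height distribution up to the one-pixel floor quantisation (≈ −0.12 mm on
  average at 0.232 mm spacing).
* **Null calibration.** With all multipliers at 1 and zero strain, repeated
  acquisitions of one truth are exchangeable; over 200 replicates of an
  8-sample study at a reduced grid (16 × 48 at 0.4 mm — the calibration of
  the tests does not depend on grid size), each test's empirical rejection
  rate at α = 0.01 stays inside its binomial 99% interval.
* **Regression.** A frozen one-sample pipeline output guards against silent
  drift; CSV outputs are byte-identical across reruns with one seed.

# Known limitations

* The inversion-recovery magnitude fit carries a small τ-dependent noise
  bias; combined with validity gating it can shift recovered group Δ0 by a
  few tenths of a percentage point at SNR 50 (well inside the sampling
  tolerances above, but visible).
* Exact Wilcoxon p values are only used for untied differences; ROI means
  are continuous so ties are practically absent in this pipeline.
* The phantom's flat-slab geometry makes caliper heights exact multiples of
  the pixel spacing; real masks have rougher surfaces.
* `run_pipeline()` is single-threaded; a full 29-sample, 4-modality,
  6-configuration study is a few minutes of CPU, and subsets (modalities,
  loads, sessions) scale linearly.
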