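---
title: "Methods: white matter lesion segmentation in wmlseg"
author: "wmlseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: white matter lesion segmentation in wmlseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter and
why their defaults are what they are, what the synthetic phantoms do and
do not establish, and where the method's known limits are.

# Problem setting

White matter lesions appear on FLAIR MRI as hyperintense regions within
white matter. At mild loads (< 5 mL per subject) they are small — often
punctate, a few voxels across — and the operating regime is dominated by
false positives: flow artefacts, incomplete skull stripping, and noise all
produce hyperintensities that a pure intensity threshold cannot tell from
lesions. The pipeline therefore splits the task into a sensitive
intensity-based *detector*, a texture-based *classifier* that removes
false positives, and a density-based *boundary refiner*. Inputs are
assumed bias-corrected, skull-stripped and co-registered; the package
does not perform those corrections (the phantom generator produces data
born that way).

# Intensity standardization

MR intensities are scanner- and session-dependent, so any fixed texture or
threshold machinery needs a common scale first. We use percentile-landmark
standardization: the source landmarks are the brain-masked percentiles
{p1, p10, …, p90, p99} of a volume, mapped piecewise-linearly onto target
positions of a standardized scale `[0, 8191]` (8192 levels). Quantiles use
the linear interpolation between closest ranks (R's type 7) everywhere;
this is fixed and documented because every later threshold inherits it.

Design choices:

* **Target scale.** With no external standard, the target landmarks of a
  cohort are the average of each member's landmarks after anchoring the
  first landmark at 0 and the last at 85 % of the scale
  (`fit_standard_scale()`). The 15 % headroom keeps resolution for
  intensities *above* p99 — which is where lesions live — before clipping;
  beyond the terminal landmarks the terminal segment's slope is
  extrapolated. A single volume standardized against itself receives the
  anchored affine map, which preserves its histogram shape exactly.
* **Invariances.** Percentile landmarks are equivariant under positive
  affine intensity transforms, so standardized output is invariant to
  scanner gain/offset; this is tested exactly. Outputs are rounded to
  integers, so re-standardizing an already standardized volume is the
  identity only up to one integer step — the tests assert that bound
  rather than bit-equality.
* **Degenerate inputs.** Tied adjacent landmarks (e.g. a long constant
  plateau) are collapsed with a warning; an all-constant brain region is
  an error since no map exists.

Fuzzy C-means tissue segmentation (fuzzifier m = 2, tolerance 1e-5 on
center shift, max 300 iterations, deterministic initialization at the
p10/p50/p90 masked intensities) produces CSF/GM/WM memberships. It is
exposed for downstream anatomical filters and parity with the full
preprocessing chain, but the default classification path does not consume
it. The implementation clusters the weighted unique-intensity histogram,
which is exact for scalar features and makes cost independent of volume
size; the per-iteration objective is recorded and asserted non-increasing
in the tests, with `e1071::cmeans` as an independent cross-check.

# Candidate detection

Per axial slice, the normal-brain intensity distribution is estimated by
the trimmed mean and its boxplot. Defaults, configurable:

* `trim_fraction = 0.2` per tail — enough to discard CSF and most GM from
  a FLAIR slice so the quartiles describe normal parenchyma;
* `k_extreme = 3` — Tukey's *extreme*-outlier fence `q3 + 3·IQR`, the
  conventional reading of "extreme outliers";
* `min_area = 3` px — suppresses single-voxel noise components;
* `margin_px = 2` — patch context around the component bounding box for
  texture extraction;
* ties at the fence: strictly-greater-than.

Components are 8-connected and strictly 2-D per slice; detection is
per-slice by design (the acquisition is 2D-axial with 5 mm slices and a
1 mm gap, so in-plane texture carries the signal; across-slice merging is
a reporting concern only).

# Texture features and the embedded clustering

Each candidate yields exactly ten features. Histogram features (mean,
variance, moment-standardized skewness `m3/σ³` and kurtosis `m4/σ⁴`,
energy `Σp²`, Shannon entropy `−Σ p log₂ p`) are computed from the
standardized intensities **within the component mask** — the histogram
describes the lesion itself. The GLCM is computed over the **whole
margin-dilated patch** masked to brain — the texture *context* around a
hyperintensity is precisely what separates a smooth-profiled lesion from
a streak artefact. (A config switch restricts the GLCM to the mask for
users who prefer symmetry.)

The GLCM pipeline quantizes the patch to `L = 5` gray levels by 1-D
k-means on the masked intensities (deterministic initialization at the
`(i − 0.5)/L` quantiles, Lloyd iterations on the weighted unique-value
histogram, centers relabeled ascending, ties to the lower label), then
counts ordered co-occurring pairs at unit distance, orientation 0°
(offset (0, 1) in row/col; 45°/90°/135° available). Pairs touching
unmasked pixels are skipped and the normalizer reduced accordingly, so
the probability mass is exactly 1 under any mask. Pairs are one-directed
without symmetrization; relative to writing the displacement negatively
this transposes the count matrix, which leaves contrast, energy and
homogeneity unchanged and correlation unchanged up to marginal exchange.
Features are the four Haralick statistics: contrast, energy, correlation
(with marginal means/SDs; defined as 0 when a marginal is degenerate),
homogeneity. `L = 5` at 0° is the operating point selected by stratified
cross-validation; L = 1 provably destroys all texture signal (every GLCM
is a single cell), which the cross-validation harness demonstrates.

Printed-formula conventions: sources in this literature sometimes print
entropy without the minus sign, skewness with a `σ^{3/2}` denominator, or
GLCM marginal SDs without the square root. We implement the standard
definitions (Shannon entropy, `m3/σ³`, `m4/σ⁴`, product-moment
correlation); a Gaussian sample then has kurtosis ≈ 3, which the tests
assert.

# Random-forest false-positive removal

A forest of `T = 25` trees with depth at most `D = 25`, Gini splits and
`⌈√10⌉ = 4` candidate features per split classifies each 10-feature
vector; the score is the forest vote fraction and the default decision
threshold 0.5. No class rebalancing is applied by default — clinical
candidate sets are heavily imbalanced toward non-lesions (roughly 1 : 7.4)
and the forest is trained on that reality; class weights are available
behind a flag. Training is seeded and single-threaded, so results are
bit-reproducible, and models round-trip through serialization with
identical predictions. The tenfold stratified cross-validation harness
(`cross_validate()`) re-extracts features per grid point over cluster
count, orientation and quantizer, and reports mean fold accuracy.

# LOF boundary refinement

The extreme fence detects lesion *cores*; the lesion extends below the
fence. To recover the full extent, every voxel of a surviving candidate's
patch is scored with the Local Outlier Factor against a reference model
of training-lesion standardized intensities (the intensities under the
ground-truth masks of the training set). The distance is the absolute
intensity difference, taken literally as scalar; an experimental
3-feature space (intensity, 3×3 local mean, local SD) sits behind a flag.
A voxel whose LOF is at most τ is an *inlier with respect to the lesion
intensity model* and counts as lesion. When a query value coincides with
a reference element, exactly one coincident element is excluded — a point
is never its own neighbour; duplicate-heavy neighbourhoods with zero mean
reachability take a capped density (1e12) so scores stay finite.

Parameters the source literature leaves open, surfaced prominently in the
interface:

* `min_pts = 20` — the recommended working range of the original LOF
  authors; on ≥ 10³ reference intensities the score is insensitive to
  ±10 around this value.
* `τ = 1.5` — LOF ≈ 1 inside a uniform-density reference; 1.5 tolerates
  the density fluctuation of a finite sample while rejecting clear
  outliers.
* Reference downsampling to ≤ 10⁴ intensities by seeded
  stratified sampling (100 quantile strata); exact mode available.
* Decision orientation: lesion voxels are *inliers* against the lesion
  model (the reference is built from lesion voxels). The converse reading
  (outliers against a normal-tissue model) is defensible but couples the
  decision to the much broader normal-tissue density; the inlier reading
  gave strictly better boundary behaviour and is the package's choice.

**Refinement zone.** Intensity-only LOF answers "is this voxel's
intensity lesion-like anywhere in the cohort?" — it cannot localize a
boundary defined relative to the *local* background, and applied alone it
inflates small lesions by an inlier ring. The final mask is therefore the
LOF inliers intersected with the candidate's full-width-at-half-maximum
zone: voxels above halfway between the local normal-brain level (median
of non-component patch voxels, falling back to the slice trimmed mean)
and the candidate peak. FWHM is the standard operational definition of a
blob boundary in imaging; LOF then removes textural outliers within that
zone and can only shrink, never grow, a candidate. Candidates whose
refinement is empty are dropped.

# Evaluation and agreement statistics

Voxel-wise confusion counts within the brain mask feed the six standard
metrics. Two deliberate conventions: FPR is implemented as `FP/(TP+TN)`
exactly as printed in the MICCAI-derived metric table this field uses,
with the conventional `FP/(FP+TN)` exposed separately as
`fpr_conventional` to avoid silent ambiguity; and the volume difference
is signed, `VD = (Vol(auto) − Vol(GT))/Vol(GT)`, reported as `+Inf` only
when GT is empty and the prediction is not. Undefined denominators give
`NaN`, never silent zeros. Load strata: mild < 5 mL, moderate 5–15 mL
(both boundaries inclusive — the printed "5–15 mL" is ambiguous and a
choice had to be fixed), severe > 15 mL. Volumes use
`count · spacing_x · spacing_y · thickness / 1000`; the 1 mm inter-slice
gap is recorded in the geometry but not folded into per-voxel volume,
matching the stated voxel size 0.4297 × 0.4297 × 5 mm.

Agreement between automated and reference loads uses ICC(2,1) — two-way
random effects, single measure, absolute agreement — computed from the
ANOVA mean squares with the F-based 95 % CI, plus Pearson (t-based
two-sided p) and Spearman (Pearson on average ranks). ICC is the
agreement statistic because it, unlike r, punishes systematic offsets;
the tests construct exactly that contrast. Paired t-tests with ×4
Bonferroni correction support metric comparisons between methods;
two-sided by default.

# The synthetic phantom: what it establishes

`generate_phantom()` emulates the data regime the method targets:
256×256 axial slices (10 per subject) at 0.4297 × 0.4297 × 5 mm with a
1 mm gap; an elliptical brain with a WM core (CSF 2500 < GM 8500 <
WM 12000 on the 16-bit native scale), a smooth multiplicative bias field
(amplitude 0.03), additive Gaussian noise (σ = 200; Rician optional);
lesions as Gaussian-profile hyperintensities whose half-peak contour sits
exactly at the nominal radius (ground truth is the half-peak set), with
spatially correlated internal texture (12 % of contrast); and three mimic
families that are hyperintense enough to pass the fence but texturally
distinct: alternating-intensity streaks, bimodal rim fragments along the
cortical ribbon, and punctate noise clusters. Mild-profile cohorts sample
punctate-to-small radii (2–6 px) and contrasts U(3800, 5600) until a
target load in (1, 4.2) mL is reached, with post-hoc verification and
deterministic resampling if voxelization leaves the stratum. All
randomness flows from a single seed; regeneration is bit-identical.

These sizes — 10 + 10 subjects, 10 slices each — are the package's
benchmark operating point: large enough that every stage sees hundreds of
candidates, small enough to run in about a minute.

Honesty about what passing proves: the mimics differ from lesions chiefly
in GLCM texture and histogram shape because that is exactly the axis the
classifier claims to exploit — the benchmark therefore validates the
*machinery* (detection recall, feature separability, refinement
behaviour, reproducibility), not clinical performance. Real FLAIR data
have anatomy, partial-volume effects, registration error and artefact
diversity the phantom does not model; clinical accuracy claims require
clinical data.

# Numerical choices and degenerate inputs

* Quantile type 7 everywhere; trimming counts are floored.
* k-means ties go to the lower label; quantile-tied initial centers are
  spread into the widest gaps; fewer distinct intensities than clusters
  reduces L with a warning.
* GLCM on a patch smaller than the offset, or with no valid pairs under
  the mask, is an error, not a silent zero.
* Constant patches: variance 0, skewness/kurtosis 0 by convention,
  energy 1, entropy 0, GLCM contrast 0, correlation 0.
* LOF neighbourhood boundary membership is decided with the same
  floating-point arithmetic as the k-distance itself, so ties at exactly
  the k-distance are included without reconstruction error.
* The full CLI chain (simulate → train → segment → evaluate) is
  byte-reproducible under a fixed seed; reports carry no timestamps and
  masks are written as uncompressed NIfTI.

# Known limitations

* Boundary refinement operates on scalar intensity; lesions whose
  boundary is defined by texture rather than intensity contrast will be
  refined only as well as the FWHM zone allows.
* Detection is per-slice; a lesion visible on one slice only at
  sub-`min_area` size is missed.
* The standardization headroom (15 %) clips extreme hyperintensities of
  very high-contrast lesions; their cores saturate at the scale maximum,
  which slightly lowers the half-maximum threshold for those candidates.
* ICC on small cohorts (n = 10) has a wide CI; the benchmark reports it
  for completeness, but volume agreement at that n is better read from
  the correlation and per-phantom VD.
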