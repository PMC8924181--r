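# wmlseg

Automated segmentation of white matter lesions (WML) — the bright
hyperintensities visible on FLAIR MRI — aimed at the regime where it is
hardest: **mild lesion loads (< 5 mL)**, where lesions are small, often
punctate, and easily confused with flow artefacts, residual skull, and
noise. The package is for neuroimaging researchers who need per-subject
lesion masks and loads without manual delineation, and for method
developers who want every stage of such a pipeline exposed, tested, and
reproducible.

## The method

The pipeline has four stages, each available as plain R functions:

1. **Intensity standardization.** Scanner-dependent FLAIR intensities are
   mapped onto a common scale `[0, L-1]` (L = 8192) by piecewise-linear
   interpolation between percentile landmarks (p1, deciles p10…p90, p99),
   fitted per volume against a cohort-wide standard scale
   (`fit_standard_scale()`, `standardize()`). Fuzzy C-means tissue
   segmentation into CSF/GM/WM is provided
   (`fcm_tissue_segmentation()`).

2. **Candidate detection (TMOD).** For each axial slice, the normal-brain
   intensity distribution is estimated by the trimmed mean (20 % per
   tail) and a boxplot is built on the trimmed distribution; voxels above
   the extreme-outlier fence

   `T = q3 + 3 · IQR`

   form 8-connected components that become lesion candidates
   (`detect_candidates()`).

3. **False-positive removal.** Each candidate patch yields 10 features —
   six intensity-histogram statistics (μ, σ², skewness, kurtosis, energy,
   entropy) and four GLCM texture features (contrast, energy, correlation,
   homogeneity) computed on the **k-means-quantized** patch (L = 5
   clusters, θ = 0°, d = (1,0)); quantile binning is available as the
   baseline. A random forest (T = 25 trees, depth D = 25) classifies
   candidates as WML / non-WML (`extract_features()`,
   `train_classifier()`, `cross_validate()`).

4. **Boundary refinement (LOF).** Voxels of each surviving candidate are
   scored with the Local Outlier Factor against a reference model of
   known-lesion standardized intensities:

   `LOF(o) = mean_{p ∈ N_k(o)} lrd(p) / lrd(o)`,

   with `lrd` the local reachability density built from reachability
   distances `max(k-distance(p), d(o, p))`. LOF-inliers (≤ τ = 1.5)
   within the candidate's full-width-at-half-maximum zone form the final
   mask (`fit_lof_model()`, `refine_boundary()`).

Evaluation utilities implement the six standard voxel-wise metrics (Dice,
Jaccard, TPR, FPR, PPV, signed volume difference), lesion-load
stratification (mild < 5 mL, moderate 5–15 mL, severe > 15 mL), and
agreement statistics for automated-vs-manual loads: ICC(2,1) with 95 % CI,
Pearson and Spearman correlations.

Because clinical FLAIR data cannot ship with a package, `wmlseg` includes
a synthetic phantom generator (`generate_phantom()`, `generate_cohort()`)
producing skull-stripped multi-slice FLAIR-like volumes with known ground
truth: three tissue classes, smooth multiplicative bias, configurable
noise, textured hyperintense lesions, and false-positive mimics (streaks,
rim fragments, punctate clusters).

## Worked example

Train on three mild-load phantoms, segment a held-out one:

```r
library(wmlseg)
cohort <- generate_cohort(3, "mild", seed = 42)
model  <- train_wml_pipeline(cohort, seed = 42)
model
#> wml_pipeline_model:
#>   forest: 25 trees, depth <= 25
#> lof_model: 7026 reference intensities in [6211, 8191], MinPts 20, tau 1.5

held <- generate_cohort(1, "mild", seed = 99)[[1]]
held
#> phantom_bundle: 256x256x10 slices, GT load 1.821 mL (54 lesions, 21 mimics)

seg <- wml_segment(held$flair, held$brain, model)
seg
#> wml_segmentation: 68 candidates -> 53 kept, 2429 voxels final (5510 before refinement)

evaluate_segmentation(seg$mask, held$gt_lesions, held$brain, held$flair$geometry)
#> evaluation_report: DI 0.837, JI 0.719, TPR 0.934, FPR 0.002, PPV 0.758, VD +0.232
#>   volumes: auto 2.242 mL vs GT 1.821 mL (mild load)
```

Reading the numbers: of the 68 hyperintense candidates the trimmed-mean
fence detected, the forest kept 53 (the rest are mimics); LOF refinement
then shrank the 5510 candidate voxels to 2429, giving a Dice overlap of
0.84 with ground truth and an automated load of 2.24 mL against a true
1.82 mL (volume difference +23 %) — a mild-load subject correctly
stratified.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "wmlseg.R", package = "wmlseg"))')
Rscript $CLI simulate --profile mild --subjects 10 --seed 42 --out data/
Rscript $CLI train    --cohort data/ --out model.rds
Rscript $CLI segment  --flair data/subject_01_flair.nii \
                      --brain-mask data/subject_01_brain.nii \
                      --model model.rds --out final.nii
Rscript $CLI evaluate --pred final.nii --truth data/subject_01_gt.nii \
                      --brain data/subject_01_brain.nii --report report.json
```

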