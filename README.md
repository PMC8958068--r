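# radrobust

Quantifies how CT image preprocessing biases radiomic feature estimates.

Radiomic features — morphological and textural indices mined from medical
images — are only useful if they measure the patient rather than the
pipeline. Before feature extraction, CT volumes are typically resampled to
an isotropic grid (with some interpolation kernel), the delineated region of
interest is clipped at a Hounsfield-unit floor to exclude air, and
intensities are discretized into fixed-width bins. `radrobust` treats each
of those choices as a *rater* re-measuring the same subjects and quantifies
the disagreement, for 105 features in seven classes (14 shape, 18
first-order, 22 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM), with:

* the two-way mixed-effects, absolute-agreement, single-rater intraclass
  correlation
  `ICC = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E))`,
  stratified poor (≤ 0.5) / moderate / good / excellent (> 0.9);
* per-subject percentage coefficients of variation `100·sd/|mean|` across
  the varied preprocessing item, pooled as median (IQR);
* the repeated-measures correlation (ANCOVA with subject intercepts and a
  common slope) between feature estimates and bin width or voxel size, with
  Bonferroni adjustment.

The package is audience-complete for methodologists who want to replicate or
extend preprocessing-robustness analyses at desk scale: it ships a
reproducible synthetic CT-lesion cohort generator (no patient data are
required), a from-scratch 3D feature engine, and the four standard
perturbation analyses — A: interpolators (10 kernels at fixed 5 HU bins),
B: bin widths (3–8 HU at fixed B-spline kernel), C/D: voxel sizes (1–2.5 mm)
per bin width / per kernel.

## Worked example

```r
library(radrobust)

# two synthetic subjects: CT-like lesion volumes + masks
spec <- cohort_spec(n_subjects = 2, seed = 31, lesion_diameter_mm = c(18, 26),
                    inplane_pixel_mm = c(1.0, 1.27))
cohort <- make_cohort(spec)

# extract a reduced preprocessing grid
features <- extract_grid(cohort,
                         voxel_sizes = c(1.9, 2.5),
                         interps = c("BS", "L", "NN"),
                         bin_widths = c(4, 5, 6))

# effect B: vary the bin width at fixed B-spline kernel
resB <- run_effect(effect_plan("B", voxel_sizes = c(1.9, 2.5),
                               bin_widths = c(4, 5, 6)), features)
resB
#> <effect_result B> raters: bin_width; conditions: voxel_size (2)
#>   ICC heatmap 105 x 2; pooled CV over 105 feature rows

subset(resB$cv_summary,
       feature_name %in% c("shape_mesh_volume", "firstorder_mean",
                           "firstorder_entropy", "glcm_contrast"))
#>          feature_name median_cv    iqr_cv n_pooled
#> 9   shape_mesh_volume  0.000000 0.0000000        4
#> 18 firstorder_entropy  5.400549 0.3405182        4
#> 23    firstorder_mean  0.000000 0.0000000        4
#> 38      glcm_contrast 40.596503 0.1760139        4
```

Reading: shape features use only the mask (resampled with nearest neighbor
regardless of the image kernel) and intensity-based first-order features use
undiscretized HU, so both are *exactly* invariant to bin width — their CV is
0 by construction. Histogram and texture features are not: the entropy drifts
a little and GLCM contrast swings by tens of percent across 3–8 HU bins,
which is precisely the preprocessing sensitivity the analysis measures. The
companion ICC heatmap (`resB$icc_matrix`) and the repeated-measures
correlations (`resB$rmcorr`; e.g. entropy vs bin width has r_rm ≈ −1) show
whether that variability scrambles subject rankings and whether it is a
monotone trend (here entropy falls monotonically with bin width,
r_rm ≈ −0.998, Bonferroni-adjusted p < 0.05).

`write_cohort()`, `write_feature_table()` and `write_effect_result()` persist
cohorts (NIfTI + JSON manifest), the long feature table (CSV) and the effect
tables (CSV/JSON).

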