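---
title: "How CT preprocessing biases radiomic feature estimates"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Radiomic analyses of CT images routinely resample the scan to an isotropic
grid, clip the delineated region of interest at a Hounsfield-unit floor to
exclude air, and discretize intensities into fixed-width bins before
computing texture matrices. Each of those choices — the resampling voxel
size, the interpolation kernel, and the bin width — alters the voxel data
that the features see, and therefore the feature values themselves.
`radrobust` quantifies that preprocessing-induced variability: it treats
each choice of a preprocessing item as a *rater* re-measuring the same
subjects, and asks how large the rater-to-rater disagreement is relative to
the between-subject signal.

Four perturbation analyses are built in:

* **A** — vary the interpolation algorithm (10 kernels) at fixed bin width,
  once per voxel size;
* **B** — vary the bin width (3–8 HU) at fixed kernel, once per voxel size;
* **C** — vary the voxel size (1–2.5 mm) at fixed kernel, once per bin width;
* **D** — vary the voxel size at fixed bin width, once per kernel.

## Robustness statistics

For each feature and each condition, the subjects-by-raters matrix feeds a
two-way mixed-effects, absolute-agreement, single-rater intraclass
correlation:

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

with $MS_R$, $MS_C$, $MS_E$ the row (subject), column (rater) and error mean
squares, $n$ subjects and $k$ raters. Absolute agreement is the right flavor
here: a kernel that systematically shifts a feature should be penalized, not
forgiven as a "consistent" rater. Estimates are stratified poor
($\le 0.5$), moderate, good, excellent ($> 0.9$), with boundary values
falling into the lower stratum and negative estimates reported as computed
but stratified poor. When every cell of the matrix is identical the
estimator is $0/0$; we define ICC $= 1$ (the raters agree perfectly on the
observed data) and flag the case.

The ICC is a *relative* measure — it compares rater noise to between-subject
spread — so it is complemented by an absolute one: for each subject, the
percentage coefficient of variation $100\,\mathrm{sd}/|\bar{x}|$ across the
raters, pooled as median (IQR) over subjects and conditions. The sample SD
and the absolute mean are used because several features (skewness, cluster
shade, Imc1) are signed; a mean within $10^{-12}$ of zero flags the CV
undefined and excludes it from pooling rather than producing an arbitrary
huge value.

Monotone trends along the numeric preprocessing axes (bin width in effect B,
voxel size in effect C) are measured by the repeated-measures correlation:
an ANCOVA with subject-specific intercepts and a common slope $b$, reported
as $r_{rm} = \mathrm{sign}(b)\sqrt{SS_x/(SS_x+SS_{err})}$ on
$N - n_{\text{subjects}} - 1$ degrees of freedom, Bonferroni-adjusted with a
configurable family size defaulting to 105 (all features in one analysis
column).

## The preprocessing chain

`extract_all()` runs resample → resegment → discretize → features.

* **Resampling.** The output grid is isotropic at the requested voxel size,
  covers the input extent, and is centered on the input volume center. The
  image is interpolated with the named kernel: cubic B-spline (`BS`, with
  the exact recursive prefilter), five windowed sincs of radius 3 voxels
  (`BL`, `CWS`, `HWS`, `LWS`, `WWS` — Blackman, cosine, Hamming, Lanczos,
  Welch windows), Gaussian (`G`, $\sigma$ = 0.5 × output spacing),
  Gaussian-weighted label voting (`LG`), trilinear (`L`) and nearest
  neighbor (`NN`). Per-axis tap weights are normalized to sum to one, so
  every kernel reproduces constant images exactly; out-of-support taps clamp
  to the nearest edge sample. The **mask is always resampled with nearest
  neighbor** and re-binarized at 0.5, regardless of the image kernel. This
  is a deliberate modeling decision: it makes the ROI geometry at a fixed
  voxel size identical across interpolators and bin widths, which is what
  forces the shape-feature CVs to be exactly zero under effects A and B.
* **Resegmentation.** ROI voxels with HU strictly below the floor (default
  −500 HU) are removed; boundary values stay. The floor is applied *after*
  resampling: its purpose is to exclude air-contaminated voxels from the
  intensities actually analyzed, and those intensities live on the resampled
  grid. Both the floor and the ordering are visible in the configuration.
* **Discretization.** Fixed bin width $W$: level$(x) = \lfloor (x -
  x_{\min})/W \rfloor + 1$ with bins anchored at the ROI minimum, giving
  $N_g = \lfloor (x_{\max}-x_{\min})/W \rfloor + 1$ levels. Anchoring at the
  ROI minimum is one of two dialects in circulation (the other anchors at
  multiples of $W$); it is recorded as an explicit convention.
  `check_level_budget()` flags ROIs outside the suggested 30–130 level band
  but never aborts.

## The feature engine

105 features in seven classes, 3D only. Texture matrices are built at
Chebyshev distance 1 over the 13 unique direction vectors of the
26-neighborhood; GLCM and GLRLM features are computed per directional matrix
and averaged at the feature level. The GLDM uses dependence tolerance
$\alpha = 0$ and stores dependence $d$ in column $d+1$ so emphasis formulas
stay finite at zero dependence. Zones (GLSZM) are 26-connected components of
equal level.

Shape features use only the mask: mesh volume and surface area come from an
iso-surface extracted at 0.5 from the mask indicator after a light Gaussian
anti-aliasing of 0.8 voxels, triangulated by marching tetrahedra with
interpolated, outward-oriented vertices. Anti-aliasing matters: the
iso-surface of a raw binary field has staircase facets that overestimate the
area of a 10-mm digital ball by about 9% (sphericity 0.91); after
anti-aliasing the same ball measures sphericity 0.99. Masks so small that
the smoothed indicator never reaches 0.5 fall back to the voxel rectangular
hull. Axis lengths are $4\sqrt{\lambda}$ from the eigenvalues of the
physical voxel-coordinate covariance (population normalization);
single-voxel ROIs define elongation and flatness as 1.

First-order features are computed from raw, undiscretized HU values —
except entropy and uniformity, which are histogram features by nature. This
is why effect B (bin width) leaves 16 of the 18 first-order features
bit-identical. Kurtosis is Pearson kurtosis (a Gaussian scores 3, not 0);
total energy is voxel volume × sum of squared intensities; the robust mean
absolute deviation averages over the closed percentile interval
$[P_{10}, P_{90}]$ with linearly interpolated percentiles.

Degenerate inputs resolve to finite conventions rather than NaN, because
the downstream statistics need complete matrices: on a constant ROI,
skewness and kurtosis are 0, GLCM correlation is 1, Imc1 and Imc2 are 0,
NGTDM busyness is 0 and coarseness is capped at $10^6$.

## The synthetic cohort

No public imaging accompanies this analysis, so the package generates a
cohort with the statistical structure the statistics require. Each subject
draws its own parameters (between-subject heterogeneity), and within the
lesion:

* an ellipsoid-like ROI (random orientation, semi-axis ratios 0.75–1, mild
  smooth boundary perturbation, largest 26-connected component kept),
  diameter 25–55 mm;
* intra-lesion texture: a Gaussian random field obtained by smoothing white
  noise with a Gaussian kernel of the subject's correlation length (3–8 mm),
  plus a smooth core-to-rim radial gradient (60–90 HU), jointly standardized
  and scaled to the subject's mean (10–60 HU) and SD (28–45 HU);
* small connected air pockets replacing up to 2% of ROI voxels with values
  below −500 HU, exercising the resegmentation path the way partial-volume
  air does;
* an acquisition grid with in-plane pixel 0.82–1.27 mm and 5 mm slices,
  soft-tissue background noise within about ±100 HU.

The HU ranges were fixed once so that, on the native grid, every subject's
resegmented ROI discretizes to roughly 30–130 levels at a 5 HU bin width —
the regime the analysis design assumes. After resampling, interpolation
through air pockets produces a realistic partial-volume tail down to the
−500 HU floor that can push the level count somewhat above the band; the
pipeline logs this through `check_level_budget()`.

What the generator does *not* emulate: scanner reconstruction kernels, noise
spectra, contrast enhancement, or anatomically realistic lesion shapes.
Passing tests on this cohort therefore demonstrate the *structural*
properties of the pipeline (invariances, conservation laws, statistical
recovery), not the clinical magnitudes of preprocessing bias, which depend
on real tissue texture.

Generation is a pure function of the specification and seed: one global seed
fans out to per-subject seeds by `seed + subject_index`.

## Numerical choices

* B-spline prefilter: exact finite-length mirror initialization, pole
  $\sqrt{3}-2$.
* Windowed-sinc radius 3 voxels; Gaussian kernels truncated at $3\sigma$.
* ANOVA error sum of squares is obtained by subtraction; a residue within
  $10^{-12}$ of zero (relative) snaps to exactly zero so identical raters
  yield ICC exactly 1.
* Mask binarization after nearest-neighbor resampling thresholds at 0.5.
* Discretization guards the floating-point edge case at the ROI maximum.

## Problem sizes

Unit and acceptance tests run on lesions of 18–32 mm at voxel sizes
1.6–2.5 mm with cohorts of 2–5 subjects; the oracle-equivalence suite uses
100 random ROIs of up to $6^3$ voxels and 6 gray levels, where exhaustive
enumeration is feasible. The acceptance script analyzes a 3-subject cohort
over the complete study grid (6 voxel sizes × {10 interpolators at 5 HU} ∪
{B-spline at 3–8 HU}). These sizes were chosen so a desk-scale replication
of the full four-effect analysis stays in the minutes range; all statistics
scale unchanged to larger cohorts.

## Known limitations

* Interpolation kernels follow standard definitions but are not bit-matched
  to any specific toolkit build; feature values on identical inputs may
  differ in the last decimals from other engines even where formulas agree.
* The label-voting interpolator (`LG`) degenerates toward nearest-neighbor
  behavior on continuous-valued images, since almost every input voxel
  carries a distinct "label"; it is included for vocabulary completeness.
* No ICC confidence intervals are produced (the analysis reports point
  estimates and strata only).
* NIfTI is the supported on-disk format; geometry is carried through
  spacing and origin (axis-aligned grids).
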