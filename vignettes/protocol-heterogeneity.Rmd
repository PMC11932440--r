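---
title: "Simulating DWI protocol heterogeneity and its effect on ischemic core estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating DWI protocol heterogeneity and its effect on ischemic core estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwicore)
```

## The problem

Apparent diffusion coefficient (ADC) maps are the workhorse of acute stroke
imaging: a single threshold of 620e-6 mm²/s (the DEFUSE criterion) applied
to the ADC map inside white matter delineates the ischemic core, and the
resulting volume feeds directly into treatment eligibility decisions. But
ADC is not strictly quantitative. Its value at a voxel depends on how many
diffusion-encoding directions the acquisition used and on how those
directions were oriented relative to the patient's head. Emergency-room
protocols often use 4 directions; research-grade protocols use 12, 20 or
more. `dwicore` provides a tested simulation pipeline for quantifying what
this protocol heterogeneity does to (i) the white-matter ADC distribution,
(ii) the segmented core volume and location, and (iii) downstream
correlations between core volume and clinical severity scores.

Real patient cohorts for this question are not generally shareable, so the
package includes a first-class synthetic-subject generator. Everything
downstream of the generator operates on ordinary DWI data structures (NIfTI
volumes plus FSL-style bvec/bval tables) and works identically on real
acquisitions.

## The signal model

For each voxel the diffusion-weighted signal along unit direction $g_i$ at
diffusion weighting $b$ follows the monoexponential model

$$S_i = S_0 \exp(-b\, g_i^\top D\, g_i),$$

where $D$ is the local diffusion tensor (isotropic $D = \mathrm{ADC}\cdot I$
for most tissue). ADC estimation inverts this by the mean exponential decay
over the $N$ encoding directions:

$$\widehat{\mathrm{ADC}} = \frac{1}{N}\sum_{i=1}^{N}
  \frac{-\ln(S_i/\bar S_0)}{b},$$

with $\bar S_0$ the voxelwise average of the b = 0 repetitions. Two
numerical guards apply, both counted and reported: each $S_i$ is floored at
$10^{-6}\bar S_0$ before the log (noise zeros), and the final voxel value is
floored at 0 (noise can push $S_i$ above $\bar S_0$, making the mean decay
negative; we keep the negative per-direction terms in the mean but report a
non-negative ADC). Voxels with $\bar S_0 \le 0$ are flagged and zeroed.

Two facts drive everything in this package:

* with *isotropic* diffusion and no noise, $\widehat{\mathrm{ADC}}$ is exact
  for **any** number and orientation of directions — so every downstream
  difference between protocols is attributable to noise and anisotropy, and
  the noise-free isotropic phantom is a strict null control;
* with anisotropic diffusion, $\widehat{\mathrm{ADC}}$ estimates the mean of
  $g_i^\top D g_i$ over the directions actually used. For a well-spread
  20-direction scheme this approximates the orientation-invariant mean
  diffusivity $\mathrm{tr}(D)/3$; for 4 directions it depends strongly on
  how the scheme happens to be oriented relative to the local fiber axis.

## The phantom

`phantom_spec()` / `generate_phantom()` draw a synthetic subject on a
64 × 64 × 24 grid at 1.6 × 1.6 × 3 mm (the clinical stroke DWI resolution):
an ellipsoidal head with a CSF shell (ADC ≈ 3000 μm²/s), a grey-matter
shell (≈ 950 μm²/s) and a white-matter core, an embedded spherical (or
box) lesion with ADC drawn around 450 ± 80 μm²/s (below the DEFUSE
threshold while white matter is above it — enforced by the constructor),
and Rician magnitude noise $|S + \sigma(Z_1 + iZ_2)|$ applied to all
volumes inside the head. The default $\sigma = 50$ with $S_0 = 1000$ gives
SNR 20 at b = 0. The b = 0 reference uses 10 repetitions, and the
reference protocol is a 20-direction electrostatic-repulsion scheme at
b = 1000 s/mm².

Half of the non-lesion white matter (by default) carries a prolate
diffusion tensor with eigenvalues (1700, 300, 300) μm²/s instead of an
isotropic ADC. Four modelling points deserve emphasis:

* **The white-matter ADC marginal is heavy-tailed, not Gaussian.**
  High-angular-resolution clinical white matter shows a strongly
  right-skewed ADC distribution (mean ≈ 865 μm²/s, SD ≈ 262, skewness
  ≈ 3.8, kurtosis ≈ 24): a tight left flank that approaches the 620
  threshold and a long right tail toward partial-volume CSF. The phantom
  realizes this as a shifted lognormal matched to the target mean, SD and
  skewness (`wm_adc_skew = 0` gives a Gaussian instead). This shape is not
  a cosmetic detail — the near-threshold mass on the left flank is
  precisely what makes threshold segmentation sensitive to protocol-driven
  changes in ADC spread, and with a tight Gaussian marginal most of the
  studied effect disappears.
* **Diffusivity texture.** Per-voxel tissue ADC varies around its class
  mean as a *smooth* random field (`adc_texture_mm`, default 6 mm), not as
  voxelwise white noise: tissue diffusivity is a material property with
  spatial structure, while voxel-independent fluctuation in real maps is
  measurement noise — which the phantom models separately through the
  Rician channel. Conflating the two (iid tissue draws) makes every
  sub-threshold excursion salt-and-pepper, and the segmentation's own
  morphological opening then removes the entire protocol effect.
* **Fiber coherence.** The tensor orientation field is *spatially smooth*
  (box-smoothed Gaussian vector field, coherence length
  `fiber_coherence_mm = 10`), and the anisotropic region itself is made of
  coherent patches rather than independent voxels. This mirrors real white
  matter, where neighbouring voxels share a tract orientation. It is also a
  mechanistic requirement: the segmentation pipeline opens the thresholded
  mask with a 2 × 2 × 2 structuring element, so *isolated* low-ADC voxels
  can never contribute to the core. Direction-dependent ADC underestimation
  only inflates the segmented volume if it is spatially coherent — with
  independently oriented voxels the entire effect under study would be
  silently erased by the morphological cleanup. Setting
  `fiber_coherence_mm = 0` recovers independent per-voxel orientations.
* **Rician, not Gaussian, noise.** Magnitude MRI noise is Rician; at low
  SNR it biases signals upward, which in turn biases ADC. The generator is
  validated against the closed-form Rician mean (numerical integration of
  the Rice density) in the test suite.

What the phantom does **not** model: real anatomy (no template brains, no
gyri), perfusion, partial-volume mixtures at tissue borders, spatially
correlated scanner noise, motion, eddy currents, and EPI distortion.
Passing tests on the phantom therefore demonstrate the *mechanisms* —
noise- and anisotropy-driven protocol sensitivity of threshold segmentation
— not cohort-level magnitudes. All printed clinical-cohort numbers from
real data differ from phantom results for exactly this reason, and no test
asserts them.

## Protocol subsampling

`cosine_match()` emulates a target acquisition from an acquired one by
greedy matching: targets in order, each taking the unused candidate
b-vector with the largest absolute cosine similarity, ties broken by lowest
candidate index. The absolute value reflects the antipodal symmetry of
diffusion encoding ($g$ and $-g$ are equivalent); a signed-cosine variant
is available via `absolute = FALSE`.

`subsample_4dir()` models the emergency-room 4-direction protocol: three
orthonormal axes plus the oblique (1,1,1)/√3, rotated per repetition by a
uniformly random rotation that stands in for head tilt and calibration
differences between sites. Repetitions must yield distinct index sets;
because only five disjoint 4-sets exist inside 20 directions while 14
repetitions are drawn, sets are distinct but may overlap — the only reading
consistent with having 14 of them. With a 20-point parent scheme the
matched "orthogonal" triplets are orthogonal only up to the ~25° sampling
density of the parent: across random tilts the maximum pairwise |dot| of a
selected triplet is typically ~0.5, with favourable tilts reaching below
0.35. `subsample_12dir()` matches a fixed 12-direction equispaced target
and is fully deterministic.

## Segmentation

`segment_core()` implements the DEFUSE-style pipeline in a fixed order:
threshold (`0 < ADC < 620e-6` inside white matter), morphological opening
then closing with a 2 × 2 × 2 cube, 26-connected component decomposition
(the full 3 × 3 × 3 neighbourhood), and removal of components smaller than
1 mm³. The even-sized element has no natural centre; the package anchors it
at its (0,0,0) corner with erosion as `AND` over offsets `{0,1}³` and
dilation as `OR` over the reflected offsets, which makes opening exactly
the union of element translates contained in the mask (and both composites
idempotent — asserted on fixtures). The `ADC > 0` guard excludes voxels
zeroed by the ADC module, which would otherwise be spuriously "ischemic"
(the threshold is an upper bound). At 1.6 × 1.6 × 3 mm a single voxel is
7.68 mm³, so the 1 mm³ filter removes nothing at clinical resolution; it is
exposed because finer grids (used in tests) do exercise it.

## Statistics

* `wm_adc_moments()`: mean, SD, skewness (g1) and kurtosis (Fisher excess
  g2, Pearson convention available) of white-matter ADC in μm²/s.
* `paired_moment_test()`: two-sided Wilcoxon signed-rank per moment across
  subjects; zero differences dropped; for ≤ 14 effective pairs the p-value
  is computed by exact enumeration of sign assignments, which stays valid
  under tied differences (the large-sample branch uses the standard normal
  approximation).
* `bland_altman()`: alternative-minus-reference differences; nonparametric
  95% range of agreement as empirical 2.5th/97.5th percentiles with linear
  interpolation between order statistics (quantile type 7 — the
  interpolation can leave coverage up to 2/n short of 95% at small n, a
  documented property of the convention; the choice is immaterial at
  cohort sizes).
* `jaccard()`: intersection over union; two empty masks score 1 (two
  protocols agreeing that there is no core agree perfectly) — pass
  `empty_value = NA` to flag instead.
* `spearman_with_ci()`: Spearman rho with average ranks, t-approximation
  p-value, and a Fisher-z confidence interval with the 1.06/(n−3) Spearman
  variance correction (bootstrap percentile CI available); complete-case
  handling with the dropped count reported.

## The cohort experiment

`generate_cohort()` draws subjects with lesion volumes from a clipped
log-normal (right-skewed, like clinical core volumes) and clinical scores
as monotone noisy functions of the true volume:
`score = clip(round(alpha * log1p(V) + noise))` for an NIHSS-like admission
score (0–42, alpha = 6, noise SD 3), a 24-hour NIHSS-like score and an
mRS-like ordinal (0–6). Intervention labels (EVT / r-tPA / Bridging / none)
are drawn with configurable proportions, and small missingness
probabilities exercise the complete-case path. `attenuation_experiment()`
then runs the full image pipeline per subject and protocol and compares
Spearman correlations; the headline output is the attenuation
`rho(20dir) − rho(4dir)`.

Problem sizes: single-phantom analyses use the full 64 × 64 × 24 grid.
Cohort-scale experiments default to a 32 × 32 × 16 grid — the package's own
desk-scale choice, which makes a 20-cohort × 200-subject simulation
tractable on a single CPU. Lesion volumes scale down *with the white-matter
volume*: the cohort's lognormal median is 3 mL × (phantom WM / 480 mL), so
the ratio of lesion size to white matter — which governs how much
protocol-driven spurious volume matters relative to the true volume ranks —
is grid-independent (about 0.2 mL median in the 36 mL desk-scale WM). The
draw is additionally capped at the largest lesion inscribable in the WM
ellipsoid (about 20 mL at desk scale, 67 mL at the full grid — a geometric
limit of spherical lesions in a 72 mm-thick slab; clinical cores up to
~120 mL correspond to non-spherical lesions in ~480 mL of WM). The
attenuation and inflation mechanisms are scale-free, which is what the
acceptance checks assert (signs and orderings, never cohort magnitudes).

## Numerical and design choices

* b0 volumes are detected at b < 50 s/mm² (vendor near-zero b-values);
  the bvec dialect is strictly FSL (3 × N); other layouts are rejected,
  not guessed.
* Physical volumes are always voxel count × voxel volume; all spatial
  reasoning is in the native DWI grid (no affine resampling), voxel
  indices are those of the stored array.
* The canonical ADC unit is mm²/s internally; reporting uses μm²/s via
  `adc_to_reporting_units()`; the DEFUSE threshold constant is stored once
  (`defuse_threshold`, 620e-6 mm²/s).
* The electrostatic scheme construction minimizes the Coulomb energy of
  point-plus-antipode pairs with an energy-guarded adaptive step; it is
  deterministic given its seed and cached per argument set. The 4-point
  solution reaches the tetrahedral optimum (70.5° folded separation);
  20 points reach ~30°.
* Per-subject head tilts, phantom draws and score noise are all derived
  from explicit integer seeds; every result in the package is exactly
  reproducible.

## Known limitations

The phantom's tissue geometry is an idealized ellipsoid; boundary effects
(partial volume at GM/WM interfaces, which real DEFUSE thresholding is
known to suffer from in deep grey matter) are not represented. The
4-direction target models one family of clinical protocols; actual vendor
schemes vary. Conclusions about *magnitudes* of volume bias or correlation
attenuation in any real cohort require real data; the package establishes
directions of effect and provides the tooling to process such data when
available.
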