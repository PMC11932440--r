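# dwicore

Diffusion-weighted MRI (DWI) protocol heterogeneity and its effect on
ischemic core estimation in acute stroke.

ADC (apparent diffusion coefficient) maps computed from DWI are used with a
single threshold — 620×10⁻⁶ mm²/s inside white matter, the DEFUSE criterion
— to delineate the ischemic core, whose volume feeds directly into
revascularization decisions. But the ADC value at a voxel depends on the
acquisition protocol: the number of diffusion-encoding directions (4 in
many emergency-room protocols, 20 in research-grade ones) and their
orientation relative to the head. `dwicore` simulates exactly this
degradation and measures its consequences:

* **ADC estimation** from the mean exponential decay,
  `ADC = (1/N) Σᵢ [−ln(Sᵢ/S̄₀)]/b`, with documented guards for noise
  zeros and negative decays;
* **protocol subsampling** by greedy |cosine|-similarity matching of an
  acquired 20-direction scheme onto 4-direction (3 orthogonal axes + 1
  oblique, randomly rotated per repetition to model head tilt) and
  12-direction equispaced targets;
* **DEFUSE core segmentation**: threshold → 2×2×2 morphological opening and
  closing → 26-connected components → sub-1 mm³ component removal;
* **agreement and association metrics**: Jaccard overlap, nonparametric
  Bland-Altman limits, white-matter ADC distribution moments with paired
  Wilcoxon signed-rank comparisons, Spearman correlations (Fisher-z CIs)
  between core volume and NIHSS/mRS-like severity scores;
* a **synthetic subject generator** (multi-tissue head phantom with
  coherent white-matter fiber anisotropy, truncated-normal lesion ADC and
  Rician noise) plus a cohort generator with volume-linked clinical
  scores, standing in for non-shareable patient data.

All volumes are NIfTI; gradient tables are FSL-dialect bvec/bval. The same
pipeline functions run on real acquisitions.

## Worked example

```r
library(dwicore)

ph <- generate_phantom(phantom_spec(seed = 7))     # 64x64x24, SNR 20 at b0
ph$truth$true_lesion_volume_ml
#> [1] 7.13472

adc20 <- compute_adc(ph$dwi, mask = ph$truth$brain_mask)
seg20 <- segment_core(adc20, ph$truth$wm_mask)
seg20
#> <core_segmentation> 1 component(s), total volume 6.766 mL

r4 <- subsample_4dir(ph$dwi$scheme, n_repetitions = 1, seed = 7)[[1]]
r4
#> <subsample_result> repetition 1: indices [9, 6, 5, 10], mean |cos| = 0.9772

adc4 <- compute_adc(extract_subsampled_dwi(ph$dwi, r4), mask = ph$truth$brain_mask)
seg4 <- segment_core(adc4, ph$truth$wm_mask)
seg4
#> <core_segmentation> 3 component(s), total volume 6.927 mL

jaccard(seg4$mask, seg20$mask)
#> [1] 0.9465
```

The 20-direction acquisition finds one coherent core of 6.77 mL where the
truth is 7.13 mL (threshold + morphology trim the lesion boundary). The
simulated 4-direction protocol — the same data, four encoding directions,
one random head tilt — inflates the core to 6.93 mL, fragments it into 3
components and moves ~5% of its voxels (Jaccard 0.95). The white-matter
ADC distribution widens from SD 217 to 241 μm²/s while skewness and
kurtosis drop (3.76 → 2.87 and 22.8 → 15.6 — fewer directions blur the
sharp, skewed high-angular-resolution distribution):

```r
wm_adc_moments(adc20, ph$truth$wm_mask)$sd   #> 216.8
wm_adc_moments(adc4,  ph$truth$wm_mask)$sd   #> 241.2
```

Across many phantoms the 4-direction volumes are systematically inflated
and their correlation with severity scores attenuated; the acceptance
script below measures all of this from scratch.

A thin command-line wrapper over the same functions is installed at
`inst/cli/dwicore.R` (subcommands `adc`, `subsample`, `segment`).

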