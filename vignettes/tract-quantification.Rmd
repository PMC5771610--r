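---
title: "Tract-specific quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-specific quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractmetrics)
```

## Scope and model

`tractmetrics` quantifies a white-matter tract that has already been
segmented — by probabilistic tractography per subject, by a cohort
template, or by a histological atlas — on voxel grids that are already
co-registered per subject. Three representations drive everything:

* a **binary mask** `v`, `v_i ∈ {0, 1}` (individual tract, lesion and
  exclusion masks);
* a **probability map** `ω`, `ω_i ∈ [0, 1]` (templates and atlases);
* scalar **diffusivity maps** `D` (AD, RD, MD in 10⁻³ mm²/s; FA
  dimensionless).

The key modelling commitment is that a probability-weighted tract is used
*as weights*, never binarised implicitly. Volumes are
`r·Σω_i` (voxel volume `r` in mm³, reported in mL), lesion load is
`r·Σ v_i ω_i`, and tissue summaries are weighted means
`Σ D_i ω_i / Σ ω_i`. This makes results continuous in the template and
avoids committing to one threshold for quantities that do not need one.

The lesional/non-lesional split is voxel-wise: lesional tract =
tract weights on voxels covered by the lesion mask, non-lesional tract =
the complement. The two compartments partition the weights exactly, so the
whole-tract mean is always the weight-proportional mixture of the two
compartment means — an identity the test suite verifies on random inputs.
A fibre-wise split (lesional / proximal / distal along streamlines) would
need the streamlines themselves and is out of scope.

## Template construction and threshold selection

A template is the voxel-wise average of n aligned binary masks, so each
voxel holds the fraction of the cohort whose tract occupies it, and the
probability-weighted template volume equals the mean individual volume
exactly. For visual comparison and ROI-style use the template is binarised
at the threshold, swept over 1%–99% in 1% steps, that maximises the mean
Dice similarity coefficient against the individual masks.

Numerical choices, each pinned by a test:

* **Inclusive thresholding** (`value ≥ t`): only voxels strictly below the
  threshold are zeroed. Whether a voxel exactly at the threshold survives
  is ambiguous in common practice, so the rule is exposed as a flag
  (`inclusive`), with the inclusive variant as default.
* **Tie-break: lowest threshold.** Equal mean DSC at several thresholds is
  resolved toward the more inclusive (larger) template.
* **Both-empty Dice = 1.** Two empty masks are identical; defining the
  coefficient as 1 keeps `dice(a, a) = 1` universally. An empty subject
  mask in an ensemble contributes DSC 0 at every threshold (with a
  warning) rather than being dropped, so cohort summaries stay honest.
* **Common-space DSC.** Full studies map each thresholded template back to
  every subject's native grid through inverse deformations before
  computing DSC. Registration is upstream of this package, so the sweep
  runs in whatever common space the masks are supplied in; callers with
  per-subject warped masks recover the native-space procedure by passing
  those.

## Grids, units and degenerate inputs

* Grid equality requires identical shapes, voxel dimensions within
  1e-6 mm, affines within 1e-4, and identical space tags. Any mismatch is
  a `grid_mismatch` error: resampling belongs upstream, and silent
  interpolation of masks would corrupt volumes.
* `r` in the volume formulas is the voxel *volume* (product of the three
  voxel edge lengths, mm³) — the only reading with correct units; mL
  conversion divides by 1000.
* Diffusivities are handled in 10⁻³ mm²/s; manifests can declare mm²/s and
  are rescaled on load.
* `NA`/`NaN` voxels in scalar maps (background, CSF-masked tissue) are
  excluded from weighted means pairwise — from numerator and denominator
  alike. A region whose weights vanish after exclusion raises
  `empty_region`, except for the lesional compartment of a lesion-free
  subject, where the mean is reported as `NA` (missing, not erroneous).
* The exclusion mask (e.g. thalamus) is applied to the tract *before* any
  metric, so every downstream quantity sees the same reduced tract.
* No additional CSF or lesion-filling exclusion is applied to whole-tract
  means beyond what the maps' own `NA` voxels encode.
* Normalised volume is `absolute volume × scaling factor`, with a single
  user-supplied scaling factor (SIENAX-style) used both for the normalised
  volume and for the brain-volume fraction
  (`normalised volume / normalised brain volume × 100`).

## Agreement statistics

Bland–Altman uses differences `x − y` with the sample (n−1) SD and
`bias ± 1.96·SD` limits; the multiplier is configurable but 1.96 is the
convention the limits are named after. The comparison battery always
reports both the parametric route (one-way ANOVA + Tukey HSD) and the
rank-based route (paired Wilcoxon, medians); normality is deliberately not
auto-tested — which route to cite is a per-metric judgement the caller
makes, and emitting both keeps that choice transparent. No
multiple-testing correction is applied across the battery. Standard tests
are delegated to `stats` (`aov`, `TukeyHSD`, `wilcox.test`, `cor.test`);
Bland–Altman, CV and Dice summaries, which have no single-call standard
equivalent, are implemented directly.

A degenerate Wilcoxon comparison (all paired differences zero) has no
defined p-value and is reported as `NA`. Zero-variance series likewise
yield `NA` correlations with a warning rather than errors, so one constant
metric does not abort a batch report.

## The phantom generator

`phantom_config()` + `generate_cohort()` produce cohorts in which every
quantity the pipeline estimates is known exactly:

* **Tract**: a tube of radius 3 voxels around a quadratic Bézier arc from
  an anterior-lateral "LGN" point to a posterior "occipital" point, inside
  an ellipsoidal brain. Per subject the arc's control points are displaced
  by Gaussian jitter (default SD 0.75 voxels), emulating residual
  inter-subject misalignment; jitter SD 0 collapses the ensemble onto one
  tube and drives the optimal-threshold mean DSC to 1, while increasing it
  degrades attainable DSC (a tested monotonicity).
* **Lesions**: a Poisson number (mean 3) of spheres with radii uniform in
  1.5–3 voxels, centred on tract voxels sampled with a 4× weight for the
  middle third of the arc — reproducing the periventricular predominance
  of demyelinating lesions along the tract's middle segment, which the
  lesion-frequency map then recovers.
* **Diffusivity**: non-lesional baselines AD 1.17, RD 0.63, MD 0.81
  (10⁻³ mm²/s), FA 0.38; lesional offsets +0.29, +0.19, +0.22, −0.01;
  i.i.d. Gaussian voxel noise (SD 0.03). These defaults are realistic
  white-matter and lesion values for a demyelinating-disease cohort and
  were fixed once, up front, as the generator's study conditions. FA is
  clamped to [0, 1] and AD floored at RD to respect tensor-eigenvalue
  constraints; with the default means these clamps are ~13 noise SDs away
  and effectively never bind.

The default grid is 48×56×40 at 2 mm isotropic — a realistically sized
bundle (template volume ≈ 9–10 mL) at clinical DWI resolution, small
enough that a ten-subject cohort generates in well under a second.

What the phantoms do **not** emulate: anatomical tract shape (Meyer's
loop's sharp curvature and its tractography failure modes), realistic
lesion texture and confluence, partial-volume and registration artefacts,
atrophy, or spatially correlated noise. Passing tests therefore establish
the *computational* correctness of the machinery — conservation laws,
oracle-matched threshold selection, calibrated tests, parameter recovery
under known noise — not the biological fidelity of any upstream
segmentation.

`truth_check()` compares recovered metrics with the generative record:
volumes must match exactly (binary-mask volumetry is voxel counting), and
each compartment mean must fall within `4·noise_SD/√n_voxels` of its
expectation — four standard errors of the voxel-noise mean, giving a
per-check false-alarm probability of ~6×10⁻⁵ under the generative model.

## Problem sizes and reproducibility

The test suite exercises cohorts of 1–8 subjects on 24×28×20 grids
(milliseconds per cohort), 100-replicate conservation sweeps, a
200-replicate parameter-recovery study and a 1000-replicate Wilcoxon
null calibration; the full suite runs in well under a minute. Each cohort
draws from one RNG stream seeded explicitly from its config, the state of
the caller's RNG is restored afterwards, and NIfTI/CSV outputs are
byte-identical across repeated runs with the same seed.

## Known limitations

* No registration or resampling: inputs must share grids exactly.
* Space tags cannot round-trip through NIfTI (the format carries none), so
  volumes read from disk default to the `"unknown"` tag; mixing in-memory
  and on-disk objects requires consistent tags.
* Along-tract (profile) parameterisation and streamline-based analyses are
  out of scope; the lesional split is voxel-wise only.
* Whether a probability atlas was built inclusively or exclusively at its
  published threshold cannot be inferred from the map; the `inclusive`
  flag exists precisely to probe that sensitivity.
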