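# tractmetrics

Tract-specific quantitative analysis on voxel grids: probabilistic
white-matter tract templates with Dice-optimised binarisation,
probability-weighted tract and lesion volumetry, lesional / non-lesional
compartment diffusivity, and method-agreement statistics — with a synthetic
phantom generator so the whole pipeline is testable end to end without any
imaging data.

## The problem

Delineating a white-matter bundle such as the optic radiation in patients
with multiple sclerosis is hard: focal T2 lesions reduce anisotropy and
derail tractography, while template-based segmentation inherits registration
error. Studies therefore reconstruct the same tract with several techniques
— individual probabilistic tractography, a cohort-built probability
template, a histological atlas — and need a common quantitative machinery
to (a) build and binarise templates, (b) measure tract-specific lesion load
and diffusivity per subject, and (c) quantify how well the techniques agree.
`tractmetrics` implements exactly that machinery. Registration, tensor
fitting and lesion segmentation are upstream: every input is a NIfTI volume
already resampled to a common per-subject grid, and grid mismatches are
errors, never silently resampled.

## The core quantities

Given per-voxel tract weights ω_i ∈ [0, 1] (a binary mask is the special
case ω_i ∈ {0, 1}) on voxels of volume r mm³:

- **Probability template** from n binary masks v⁽¹⁾ … v⁽ⁿ⁾:
  ω_i = (1/n) Σ_s v_i⁽ˢ⁾ — the fraction of subjects whose tract occupies
  voxel i.
- **Dice-optimal threshold**: the template is binarised at thresholds
  1%–99% (step 1%); the threshold maximising the mean Dice similarity
  coefficient DSC = 2|A∩B| / (|A|+|B|) against the individual masks is
  selected (ties → lowest threshold).
- **Weighted lesion volume**: V = r Σ_i v_i ω_i (v_i the binarised lesion
  mask), reported in mL.
- **Weighted diffusivity mean**: D̄ = Σ_i D_i ω_i / Σ_i ω_i for each of
  AD, RD, MD (10⁻³ mm²/s) and FA, computed for the whole tract and for the
  lesional (tract ∩ lesions) and non-lesional compartments, which partition
  the tract weights exactly.
- **Agreement battery**: Pearson r, Bland–Altman bias ± 1.96 SD limits,
  inter-subject CV = 100·SD/mean, paired Wilcoxon signed-rank, one-way
  ANOVA with Tukey HSD post-hoc, and pairwise Dice summaries.

## Worked example

Everything below runs on synthetic phantoms — cohorts of jittered tube
tracts with middle-biased spherical lesions and noisy diffusivity maps with
known ground truth:

```r
library(tractmetrics)

cfg    <- phantom_config(n_subjects = 8, seed = 99)
cohort <- generate_cohort(cfg)

fit <- tract_template(lapply(cohort$subjects, `[[`, "tract"))
fit
#> Dice-optimised tract template
#>   subjects:          8
#>   optimal threshold: 0.38 (inclusive)
#>   mean DSC at optimum: 0.8574
#>   template volume:   9.63 mL (probability-weighted), 9.70 mL (binarised)
```

The fitted threshold (0.38) is the binarisation level at which the template
best matches the individual masks on average (mean DSC 0.86); the
probability-weighted template volume equals the mean of the individual mask
volumes by construction.

```r
s  <- cohort$subjects[[1]]
mt <- compute_tract_metrics(s$tract, s$lesions, s$diffusivity,
                            brain_volume_ml = 1510, scaling_factor = 1.1,
                            subject_id = s$subject_id)
mt
#> Tract metrics for subject 'phantom001'
#>   tract volume:         9.640 mL (normalised 10.604 mL)
#>   lesion volume:       0.2160 mL (lesional 0.216 + non-lesional 9.424 mL)
#>   % of brain volume:    0.702
#>   weighted means (whole | lesional | non-lesional):
#>     AD: 1.1772 | 1.4689 | 1.1705
#>     RD: 0.6339 | 0.8241 | 0.6296
#>     MD: 0.8165 | 1.0293 | 0.8116
#>     FA: 0.3795 | 0.3743 | 0.3797
```

Lesional AD/RD/MD are elevated and FA mildly reduced relative to the
non-lesional compartment — the configured generative pattern, recovered from
the voxel data. `truth_check()` verifies volumes exactly and compartment
means within the noise-predicted tolerance:

```r
metrics <- lapply(cohort$subjects, function(s)
  compute_tract_metrics(s$tract, s$lesions, s$diffusivity,
                        subject_id = s$subject_id))
truth_check(cohort, metrics)
#> Phantom truth check: 120/120 quantities within tolerance
```

Comparing lesion volumes measured under the subject's own mask vs the
cohort template:

```r
tpl <- lapply(cohort$subjects, function(s)
  compute_tract_metrics(fit$probability_template, s$lesions, s$diffusivity))
ag <- paired_method_comparison(data.frame(
  individual = sapply(metrics, `[[`, "lesion_volume_ml"),
  template   = sapply(tpl,     `[[`, "lesion_volume_ml")))
ag
#> Method agreement: 2 methods, 8 subjects
#> One-way ANOVA across methods: p = 0.9226
#> ...
#>    method_a method_b pearson_r    bias  loa_low loa_high wilcoxon_p tukey_p
#>  individual template    0.9974 0.01987 -0.03855   0.0783    0.07813  0.9226
```

`plot(fit)` draws the threshold-vs-DSC curve; `plot(ag)` the scatter and
Bland–Altman panels.

## Command line

A thin CLI over the same functions is installed under `exec/`:

```sh
tractmetrics simulate       --config phantom.yaml --out cohort/ --seed 42
tractmetrics build-template --masks cohort/ --pattern tract --out-prob tpl.nii.gz \
                            --out-bin tpl_bin.nii.gz --curve dsc_curve.csv
tractmetrics metrics        --manifest cohort/manifest.csv --out metrics.csv
tractmetrics compare        --metrics a.csv,b.csv --out report.csv --plots figs/
```

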