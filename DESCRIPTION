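Package: tractmetrics
Title: Tract-Specific Quantitative Analysis of White-Matter Probability
    Templates, Lesion Load and Diffusivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tract-specific quantitative analysis on voxel grids:
    construction of probabilistic white-matter tract templates from ensembles
    of binary tractography masks, Dice-optimised binarisation thresholds,
    probability-weighted tract and lesion volumetry, lesional versus
    non-lesional compartment partitioning, probability-weighted diffusivity
    means (AD, RD, MD, FA), and method-agreement statistics (Pearson
    correlation, Bland-Altman limits of agreement, inter-subject coefficient
    of variation, paired Wilcoxon and one-way ANOVA with Tukey post-hoc
    comparisons). Includes a synthetic voxel-phantom generator with known
    ground truth so every pipeline stage is testable end to end, NIfTI-1
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
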