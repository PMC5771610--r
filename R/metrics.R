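#' Bundle co-registered diffusivity maps
#'
#' Holds the four scalar diffusion-tensor summaries on one grid: axial (AD),
#' radial (RD) and mean (MD) diffusivity in units of 1e-3 mm^2/s, and
#' fractional anisotropy (FA, dimensionless in [0, 1]). `NA`/`NaN` voxels mark
#' background or CSF-masked tissue and are excluded pairwise by every
#' weighted mean. AD must be at least RD wherever both are defined (axial is
#' the largest tensor eigenvalue, radial the mean of the two smallest); a
#' violation beyond `1e-9` raises a warning since noisy upstream fits can
#' produce it, but it usually indicates mislabelled inputs.
#'
#' @param ad,rd,md,fa `voxel_grid` objects (or 3D arrays) on one common grid.
#' @param scale multiply all of ad/rd/md on input; set to `1000` when the
#'   maps are in mm^2/s to convert to the package's 1e-3 mm^2/s convention.
#' @return An object of class `diffusivity_set`.
#' @export
diffusivity_set <- function(ad, rd, md, fa, scale = 1) {
  ad <- voxel_grid(ad); rd <- voxel_grid(rd)
  md <- voxel_grid(md); fa <- voxel_grid(fa)
  assert_same_grid(ad, rd, "diffusivity maps")
  assert_same_grid(ad, md, "diffusivity maps")
  assert_same_grid(ad, fa, "diffusivity maps")
  if (scale != 1) {
    ad$data <- ad$data * scale
    rd$data <- rd$data * scale
    md$data <- md$data * scale
  }
  fv <- fa$data
  if (any(!is.na(fv) & (fv < 0 | fv > 1)))
    stop(errorCondition("FA map has values outside [0, 1]",
                        class = c("validation_error", "tractmetrics_error",
                                  "error", "condition")))
  both <- !is.na(ad$data) & !is.na(rd$data)
  if (any(ad$data[both] < rd$data[both] - 1e-9))
    warning("AD < RD at ", sum(ad$data[both] < rd$data[both] - 1e-9),
            " voxel(s); check that the maps are labelled correctly")
  structure(list(ad = ad, rd = rd, md = md, fa = fa),
            class = "diffusivity_set")
}

#' @export
print.diffusivity_set <- function(x, ...) {
  cat("<diffusivity_set> AD/RD/MD [1e-3 mm^2/s] + FA on ")
  print(x$ad)
  invisible(x)
}

#' Probability-weighted lesion volume within a tract
#'
#' `voxel_volume * sum(lesion_i * w_i)` over voxels, converted mm^3 to mL,
#' where `lesion_i` is the binarised lesion mask and `w_i` the tract weight.
#' With a binary tract mask this reduces to the intersection voxel count
#' times the voxel volume.
#'
#' @param lesions a `binary_mask` of T2 lesions.
#' @param tract a `probability_map` (a binary tract mask is accepted and
#'   treated as weights in {0, 1}).
#' @return Lesion volume in mL.
#' @export
weighted_lesion_volume <- function(lesions, tract) {
  lesions <- binary_mask(lesions)
  tract <- probability_map(tract)
  assert_same_grid(lesions, tract, "lesion mask and tract map")
  s <- sum(lesions$grid$data * tract$grid$data, na.rm = TRUE)
  voxel_volume(tract) * s / 1000
}

#' Partition a tract into lesional and non-lesional compartments
#'
#' Voxel-wise split: the lesional map keeps the tract weight wherever the
#' lesion mask is 1 and is zero elsewhere; the non-lesional map is the
#' complement. The two outputs sum voxel-wise to the input tract map
#' exactly, so weighted volumes and diffusivity denominators are conserved.
#'
#' @param tract a `probability_map`.
#' @param lesions a `binary_mask` on the same grid.
#' @return A list with `probability_map` components `lesional` and
#'   `nonlesional`.
#' @export
partition_lesional <- function(tract, lesions) {
  tract <- probability_map(tract)
  lesions <- binary_mask(lesions)
  assert_same_grid(tract, lesions, "tract map and lesion mask")
  w <- tract$grid$data
  les <- lesions$grid$data
  les[is.na(les)] <- 0
  lesional <- w * (les == 1)
  nonlesional <- w * (les != 1)
  list(lesional = new_probability_map(with_data(tract$grid, lesional)),
       nonlesional = new_probability_map(with_data(tract$grid, nonlesional)))
}

#' Probability-weighted mean of a scalar map over a tract
#'
#' `sum(D_i w_i) / sum(w_i)` over voxels where the scalar map is defined;
#' `NA`/`NaN` voxels (background, CSF-masked) are dropped from numerator and
#' denominator alike. Raises an `empty_region` error when no weight remains.
#'
#' @param d a `voxel_grid` (or 3D array) of scalar values, e.g. one
#'   diffusivity map.
#' @param tract a `probability_map` of voxel weights.
#' @return The weighted mean, a single number.
#' @export
weighted_mean_diffusivity <- function(d, tract) {
  d <- voxel_grid(d)
  tract <- probability_map(tract)
  assert_same_grid(d, tract, "scalar map and tract map")
  v <- d$data
  w <- tract$grid$data
  w[is.na(w)] <- 0
  ok <- !is.na(v)
  wsum <- sum(w[ok])
  if (wsum <= 0)
    stop(errorCondition(
      "tract weight is zero over the defined voxels of the scalar map",
      class = c("empty_region", "tractmetrics_error", "error", "condition")))
  sum(v[ok] * w[ok]) / wsum
}

# Weighted mean that returns NA instead of raising empty_region; used for
# compartments that may legitimately be empty (e.g. no lesions).
weighted_mean_or_na <- function(d, tract) {
  tryCatch(weighted_mean_diffusivity(d, tract),
           empty_region = function(e) NA_real_)
}

#' Per-subject tract metrics
#'
#' Assembles the full per-subject record: probability-weighted tract volume,
#' weighted lesion volume, lesional/non-lesional partition volumes, the
#' twelve weighted diffusivity means (AD/RD/MD/FA for whole, lesional and
#' non-lesional tract), the normalised tract volume (absolute volume times a
#' SIENAX-style scaling factor) and the tract volume as a percentage of
#' normalised brain volume. The exclusion mask (e.g. thalamus) is applied to
#' the tract map before any other computation.
#'
#' An empty lesional compartment yields `NA` lesional diffusivity means, not
#' an error.
#'
#' @param tract `probability_map` (or binary mask) of the tract.
#' @param lesions `binary_mask` of T2 lesions; `NULL` means no lesions.
#' @param diffusivity a [diffusivity_set()], or `NULL` to skip diffusivity.
#' @param exclusion optional `binary_mask` zeroed out of the tract first.
#' @param brain_volume_ml normalised brain volume in mL (e.g. SIENAX
#'   output); `NA` disables the brain-volume fraction.
#' @param scaling_factor volumetric normalisation factor (> 0), 1 by default.
#' @param subject_id identifier carried into the output row.
#' @return Object of class `tract_metrics`; `as.data.frame()` gives a
#'   one-row data frame.
#' @export
compute_tract_metrics <- function(tract, lesions = NULL, diffusivity = NULL,
                                  exclusion = NULL, brain_volume_ml = NA_real_,
                                  scaling_factor = 1,
                                  subject_id = NA_character_) {
  tract <- probability_map(tract)
  if (!is.numeric(scaling_factor) || length(scaling_factor) != 1L ||
      !is.finite(scaling_factor) || scaling_factor <= 0)
    stop("'scaling_factor' must be a single positive number")
  if (!is.null(exclusion))
    tract <- mask_exclude(tract, exclusion)
  if (is.null(lesions)) {
    lesions <- new_binary_mask(with_data(tract$grid,
                                         array(0, grid_dim(tract))))
  }
  lesions <- binary_mask(lesions)
  assert_same_grid(tract, lesions, "tract map and lesion mask")

  parts <- partition_lesional(tract, lesions)
  tract_volume_ml <- weighted_volume(tract)
  lesional_volume_ml <- weighted_volume(parts$lesional)
  nonlesional_volume_ml <- weighted_volume(parts$nonlesional)
  lesion_volume_ml <- weighted_lesion_volume(lesions, tract)

  diff_means <- list()
  if (!is.null(diffusivity)) {
    stopifnot(inherits(diffusivity, "diffusivity_set"))
    assert_same_grid(tract, diffusivity$ad, "tract map and diffusivity maps")
    regions <- list(whole = tract, lesional = parts$lesional,
                    nonlesional = parts$nonlesional)
    for (metric in c("ad", "rd", "md", "fa"))
      for (rn in names(regions))
        diff_means[[paste(metric, rn, sep = "_")]] <-
          weighted_mean_or_na(diffusivity[[metric]], regions[[rn]])
  } else {
    for (metric in c("ad", "rd", "md", "fa"))
      for (rn in c("whole", "lesional", "nonlesional"))
        diff_means[[paste(metric, rn, sep = "_")]] <- NA_real_
  }

  normalized_tract_volume_ml <- tract_volume_ml * scaling_factor
  tract_volume_fraction_of_brain <-
    if (is.finite(brain_volume_ml) && brain_volume_ml > 0)
      normalized_tract_volume_ml / brain_volume_ml * 100
    else NA_real_

  structure(
    c(list(subject_id = as.character(subject_id),
           tract_volume_ml = tract_volume_ml,
           lesion_volume_ml = lesion_volume_ml,
           lesional_volume_ml = lesional_volume_ml,
           nonlesional_volume_ml = nonlesional_volume_ml),
      diff_means,
      list(normalized_tract_volume_ml = normalized_tract_volume_ml,
           tract_volume_fraction_of_brain = tract_volume_fraction_of_brain)),
    class = "tract_metrics")
}

#' @export
as.data.frame.tract_metrics <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @export
print.tract_metrics <- function(x, ...) {
  cat(sprintf("Tract metrics for subject '%s'\n", x$subject_id))
  cat(sprintf("  tract volume:      %8.3f mL (normalised %.3f mL)\n",
              x$tract_volume_ml, x$normalized_tract_volume_ml))
  cat(sprintf("  lesion volume:     %8.4f mL (lesional %.3f + non-lesional %.3f mL)\n",
              x$lesion_volume_ml, x$lesional_volume_ml,
              x$nonlesional_volume_ml))
  if (is.finite(x$tract_volume_fraction_of_brain))
    cat(sprintf("  %% of brain volume: %8.3f\n",
                x$tract_volume_fraction_of_brain))
  if (is.finite(x$ad_whole)) {
    cat("  weighted means (whole | lesional | non-lesional):\n")
    for (m in c("ad", "rd", "md", "fa")) {
      vals <- unlist(x[paste(m, c("whole", "lesional", "nonlesional"),
                             sep = "_")])
      cat(sprintf("    %s: %s\n", toupper(m),
                  paste(ifelse(is.na(vals), "   --",
                               sprintf("%.4f", vals)), collapse = " | ")))
    }
  }
  invisible(x)
}

#' Lesion frequency map over a tract
#'
#' Voxel value = fraction of subjects with a lesion at that voxel, restricted
#' to voxels inside the tract support (tract weight > 0); zero elsewhere.
#' Maps how focal pathology distributes along the tract across a cohort.
#'
#' @param lesion_masks non-empty list of `binary_mask` objects on one grid.
#' @param tract `probability_map` on the same grid.
#' @return A `probability_map` of lesion frequencies.
#' @export
lesion_frequency_map <- function(lesion_masks, tract) {
  if (!is.list(lesion_masks) || length(lesion_masks) == 0L)
    stop("'lesion_masks' must be a non-empty list of binary masks")
  tract <- probability_map(tract)
  freq <- build_probability_template(lesion_masks)
  assert_same_grid(freq, tract, "lesion masks and tract map")
  w <- tract$grid$data
  v <- freq$grid$data
  v[!(w > 0) | is.na(w)] <- 0
  new_probability_map(with_data(tract$grid, v))
}
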