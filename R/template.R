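#' Build a probabilistic tract template from binary masks
#'
#' Averages an ensemble of individual binary tract masks voxel-wise on a
#' common reference grid. Each voxel of the result is the fraction of
#' subjects whose tract occupies it: 0 means present in no subject, 1 means
#' present in every subject.
#'
#' @param masks non-empty list of `binary_mask` objects on one common grid.
#' @return A `probability_map` on the same grid.
#' @examples
#' g <- array(0, c(3, 3, 3))
#' a <- g; a[1:2, 1, 1] <- 1
#' b <- g; b[2:3, 1, 1] <- 1
#' tpl <- build_probability_template(list(binary_mask(a), binary_mask(b)))
#' grid_data(tpl)[1:3, 1, 1]  # 0.5 1.0 0.5
#' @export
build_probability_template <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("'masks' must be a non-empty list of binary masks")
  masks <- lapply(masks, binary_mask)
  ref <- masks[[1]]
  acc <- array(0, dim = grid_dim(ref))
  for (m in masks) {
    assert_same_grid(ref, m, "tract masks")
    v <- m$grid$data
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  new_probability_map(with_data(ref$grid, acc / length(masks)))
}

#' Fit a binarised tract template by Dice-optimal thresholding
#'
#' Sweeps a grid of probability thresholds (default 1% to 99% in 1% steps);
#' at each threshold the template is binarised and compared with every
#' individual mask by Dice similarity coefficient (DSC). The threshold with
#' the largest mean DSC wins; ties go to the lowest threshold, which favours
#' the more inclusive template. The full threshold-vs-DSC curve is returned
#' for audit.
#'
#' `tract_template()` is the one-call interface: it builds the probability
#' template from the masks and optimises the threshold in one step.
#' `optimize_threshold()` accepts a pre-built template, e.g. a histological
#' atlas read from NIfTI.
#'
#' @param masks list of `binary_mask` objects on one common grid. A subject
#'   with an empty mask contributes DSC 0 at every threshold (with a
#'   warning) rather than being dropped.
#' @param template a `probability_map` on the masks' grid.
#' @param thresholds increasing vector of thresholds in (0, 1).
#' @param inclusive passed to [binarize()]; the default keeps voxels exactly
#'   at the threshold.
#' @return An object of class `tract_template` with components
#'   `probability_template`, `optimal_threshold`, `binary_template`,
#'   `per_subject_dsc` (DSC of each subject at the optimum), `dsc_curve`
#'   (data frame: `threshold`, `mean_dsc`, `sd_dsc`) and `n_subjects`.
#' @examples
#' cohort <- generate_cohort(phantom_config(n_subjects = 5, seed = 1))
#' fit <- tract_template(lapply(cohort$subjects, `[[`, "tract"))
#' fit$optimal_threshold
#' @export
tract_template <- function(masks, thresholds = seq(0.01, 0.99, by = 0.01),
                           inclusive = TRUE) {
  template <- build_probability_template(masks)
  optimize_threshold(template, masks, thresholds = thresholds,
                     inclusive = inclusive)
}

#' @rdname tract_template
#' @export
optimize_threshold <- function(template, masks,
                               thresholds = seq(0.01, 0.99, by = 0.01),
                               inclusive = TRUE) {
  template <- probability_map(template)
  if (!is.list(masks) || length(masks) == 0L)
    stop("'masks' must be a non-empty list of binary masks")
  masks <- lapply(masks, binary_mask)
  for (m in masks) assert_same_grid(template, m, "template and tract masks")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0L || any(thresholds <= 0 | thresholds >= 1) ||
      is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing values in (0, 1)")

  n_empty <- sum(vapply(masks, function(m) {
    sum(m$grid$data, na.rm = TRUE) == 0
  }, logical(1)))
  if (n_empty > 0)
    warning(n_empty, " subject mask(s) are empty; they contribute DSC 0 at ",
            "every threshold")

  tv <- template$grid$data
  tv[is.na(tv)] <- 0
  mask_mat <- vapply(masks, function(m) {
    v <- m$grid$data
    v[is.na(v)] <- 0
    as.vector(v)
  }, numeric(length(tv)))
  mask_sizes <- colSums(mask_mat)

  dsc <- matrix(NA_real_, nrow = length(thresholds), ncol = length(masks))
  for (i in seq_along(thresholds)) {
    bin <- if (inclusive) as.vector(tv) >= thresholds[i]
           else as.vector(tv) > thresholds[i]
    tpl_size <- sum(bin)
    inter <- as.vector(crossprod(mask_mat, bin))
    denom <- mask_sizes + tpl_size
    dsc[i, ] <- ifelse(denom == 0, 1, 2 * inter / denom)
  }
  mean_dsc <- rowMeans(dsc)
  best <- which.max(mean_dsc)  # which.max takes the first (lowest) on ties

  binary_template <- binarize(template, thresholds[best], inclusive = inclusive)
  structure(
    list(probability_template = template,
         optimal_threshold = thresholds[best],
         binary_template = binary_template,
         per_subject_dsc = dsc[best, ],
         dsc_curve = data.frame(threshold = thresholds,
                                mean_dsc = mean_dsc,
                                sd_dsc = apply(dsc, 1, stats::sd)),
         n_subjects = length(masks),
         inclusive = inclusive),
    class = "tract_template")
}

#' Probability-weighted volume of a tract template
#'
#' @param template a `probability_map` (or a fitted `tract_template`, whose
#'   probability template is used).
#' @return Volume in mL: voxel volume times the sum of voxel weights,
#'   divided by 1000.
#' @export
template_volume <- function(template) {
  if (inherits(template, "tract_template"))
    template <- template$probability_template
  weighted_volume(probability_map(template))
}

#' @export
print.tract_template <- function(x, ...) {
  cat("Dice-optimised tract template\n")
  cat(sprintf("  subjects:          %d\n", x$n_subjects))
  cat(sprintf("  optimal threshold: %.2f (%s)\n", x$optimal_threshold,
              if (x$inclusive) "inclusive" else "exclusive"))
  cat(sprintf("  mean DSC at optimum: %.4f\n", mean(x$per_subject_dsc)))
  cat(sprintf("  template volume:   %.2f mL (probability-weighted), %.2f mL (binarised)\n",
              template_volume(x), weighted_volume(x$binary_template)))
  invisible(x)
}

#' @export
summary.tract_template <- function(object, ...) {
  print(object)
  cat("\nPer-subject DSC at optimum:\n")
  print(summary(object$per_subject_dsc))
  cat("\nDSC curve (top 5 thresholds by mean DSC):\n")
  cc <- object$dsc_curve
  print(utils::head(cc[order(-cc$mean_dsc), ], 5), row.names = FALSE)
  invisible(object)
}

#' Plot the threshold-vs-Dice curve of a fitted template
#'
#' @param x a `tract_template`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tract_template <- function(x, ...) {
  cc <- x$dsc_curve
  graphics::plot(cc$threshold, cc$mean_dsc, type = "l",
                 xlab = "binarisation threshold", ylab = "mean DSC",
                 main = "Template threshold optimisation", ...)
  graphics::abline(v = x$optimal_threshold, lty = 2, col = "grey40")
  graphics::points(x$optimal_threshold,
                   cc$mean_dsc[match(x$optimal_threshold, cc$threshold)],
                   pch = 19)
  invisible(x)
}
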