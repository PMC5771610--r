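# Small in-code fixtures shared across test files.

# A mask/map from a flat vector of values on a cubic grid.
mk_mask <- function(values, shape = c(3, 3, 3), vdims = c(2, 2, 2)) {
  binary_mask(array(values, shape), voxel_dims = vdims)
}

mk_map <- function(values, shape = c(3, 3, 3), vdims = c(2, 2, 2)) {
  probability_map(array(values, shape), voxel_dims = vdims)
}

# A random binary mask with the given fill fraction.
random_mask <- function(shape = c(6, 6, 6), p = 0.3, vdims = c(1, 1, 1)) {
  mk_mask(rbinom(prod(shape), 1, p), shape, vdims)
}

# A tiny phantom config the tests reuse; grids are kept small so whole
# cohorts generate in milliseconds.
tiny_config <- function(seed, n_subjects = 3, ...) {
  args <- list(...)
  defaults <- list(grid_shape = c(24, 28, 20), n_subjects = n_subjects,
                   lesion_count_mean = 2, seed = seed)
  do.call(phantom_config, utils::modifyList(defaults, args))
}

# Independent brute-force oracle for threshold optimisation: plain loops,
# set-arithmetic Dice, no calls into the package's template code.
brute_force_threshold <- function(template, masks,
                                  thresholds = seq(0.01, 0.99, by = 0.01)) {
  tv <- grid_data(template)
  tv[is.na(tv)] <- 0
  mean_dsc <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    tpl_set <- which(tv >= thresholds[i])
    dscs <- numeric(length(masks))
    for (j in seq_along(masks)) {
      mask_set <- which(grid_data(masks[[j]]) == 1)
      denom <- length(tpl_set) + length(mask_set)
      dscs[j] <- if (denom == 0) 1 else
        2 * length(intersect(tpl_set, mask_set)) / denom
    }
    mean_dsc[i] <- mean(dscs)
  }
  best <- which(mean_dsc == max(mean_dsc))[1]
  list(threshold = thresholds[best], mean_dsc = mean_dsc)
}
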