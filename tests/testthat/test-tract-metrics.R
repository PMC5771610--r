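test_that("weighted lesion volume matches the closed form", {
  tract_bin <- probability_map(mk_mask(1))  # w = 1 everywhere
  no_lesions <- mk_mask(0)
  expect_equal(weighted_lesion_volume(no_lesions, tract_bin), 0)
  # 1 mm^3 voxels, lesion voxels with tract weights 0.5 and 0.25
  w <- rep(0, 27); w[1] <- 0.5; w[2] <- 0.25
  les <- rep(0, 27); les[1:2] <- 1
  expect_equal(
    weighted_lesion_volume(mk_mask(les, vdims = c(1, 1, 1)),
                           mk_map(w, vdims = c(1, 1, 1))),
    7.5e-4)
  # binary tract: reduces to overlap count x voxel volume (oracle: set ops)
  set.seed(3)
  for (i in 1:10) {
    tr <- random_mask(vdims = c(2, 2, 2))
    le <- random_mask(vdims = c(2, 2, 2))
    overlap <- length(intersect(which(grid_data(tr) == 1),
                                which(grid_data(le) == 1)))
    expect_equal(weighted_lesion_volume(le, probability_map(tr)),
                 overlap * 8 / 1000)
  }
})

test_that("lesional/non-lesional partition conserves the tract exactly", {
  set.seed(8)
  for (i in 1:10) {
    tract <- mk_map(runif(27))
    les <- random_mask(shape = c(3, 3, 3), vdims = c(2, 2, 2))
    parts <- partition_lesional(tract, les)
    expect_identical(grid_data(parts$lesional) + grid_data(parts$nonlesional),
                     grid_data(tract))
    expect_equal(weighted_volume(parts$lesional) +
                   weighted_volume(parts$nonlesional),
                 weighted_volume(tract), tolerance = 1e-12)
  }
  tract <- mk_map(0.5)
  all_les <- mk_mask(1)
  expect_equal(sum(grid_data(partition_lesional(tract, all_les)$nonlesional)), 0)
  none <- mk_mask(0)
  p <- partition_lesional(tract, none)
  expect_equal(sum(grid_data(p$lesional)), 0)
  expect_identical(grid_data(p$nonlesional), grid_data(tract))
  # checkerboard lesion on a uniform tract splits the weight in half
  chk <- mk_mask(rep(c(1, 0), length.out = 27))
  pc <- partition_lesional(mk_map(rep(1, 27)), chk)
  expect_equal(sum(grid_data(pc$lesional)), sum(grid_data(chk)))
  expect_equal(sum(grid_data(pc$nonlesional)), 27 - sum(grid_data(chk)))
})

test_that("weighted diffusivity mean matches the closed form and drops NaN", {
  # D = {1, 3}, w = {1, 3} -> 2.5
  d <- array(0, c(3, 3, 3)); d[1] <- 1; d[2] <- 3
  w <- rep(0, 27); w[1] <- 0.25; w[2] <- 0.75
  expect_equal(weighted_mean_diffusivity(voxel_grid(d), mk_map(w, vdims = c(1, 1, 1))),
               2.5)
  # uniform weights -> arithmetic mean over the mask
  set.seed(2)
  vals <- array(rnorm(27), c(3, 3, 3))
  m <- rep(0, 27); m[5:10] <- 1
  expect_equal(
    weighted_mean_diffusivity(voxel_grid(vals), mk_map(m, vdims = c(1, 1, 1))),
    mean(vals[5:10]))
  # NaN voxels are excluded from numerator and denominator
  vals[5] <- NaN
  expect_equal(
    weighted_mean_diffusivity(voxel_grid(vals), mk_map(m, vdims = c(1, 1, 1))),
    mean(vals[6:10]))
  expect_error(
    weighted_mean_diffusivity(voxel_grid(vals), mk_map(0, vdims = c(1, 1, 1))),
    class = "empty_region")
})

test_that("weighted means scale linearly in the map; volumes ignore it", {
  set.seed(13)
  vals <- array(abs(rnorm(27)), c(3, 3, 3))
  w <- mk_map(runif(27), vdims = c(1, 1, 1))
  base <- weighted_mean_diffusivity(voxel_grid(vals), w)
  expect_equal(weighted_mean_diffusivity(voxel_grid(3.7 * vals), w),
               3.7 * base, tolerance = 1e-12)
  expect_equal(weighted_volume(w), weighted_volume(w))
})

test_that("compute_tract_metrics assembles a consistent record", {
  cohort <- generate_cohort(tiny_config(seed = 31, n_subjects = 3))
  s <- cohort$subjects[[1]]
  mt <- compute_tract_metrics(s$tract, s$lesions, s$diffusivity,
                              brain_volume_ml = 1500, scaling_factor = 1.2,
                              subject_id = s$subject_id)
  expect_s3_class(mt, "tract_metrics")
  expect_equal(mt$lesional_volume_ml + mt$nonlesional_volume_ml,
               mt$tract_volume_ml, tolerance = 1e-9)
  expect_equal(mt$normalized_tract_volume_ml, mt$tract_volume_ml * 1.2)
  expect_equal(mt$tract_volume_fraction_of_brain,
               mt$normalized_tract_volume_ml / 1500 * 100)
  # mixture identity: whole mean is the weight-sum mix of the compartments
  parts <- partition_lesional(probability_map(s$tract), s$lesions)
  wl <- sum(grid_data(parts$lesional)); wn <- sum(grid_data(parts$nonlesional))
  for (m in c("ad", "rd", "md", "fa")) {
    mixed <- (wl * mt[[paste0(m, "_lesional")]] +
                wn * mt[[paste0(m, "_nonlesional")]]) / (wl + wn)
    expect_equal(mt[[paste0(m, "_whole")]], mixed, tolerance = 1e-12)
  }
  df <- as.data.frame(mt)
  expect_equal(nrow(df), 1)
  expect_true(all(c("subject_id", "ad_lesional", "fa_whole") %in% names(df)))
})

test_that("no lesions: whole means equal non-lesional, lesional undefined", {
  cohort <- generate_cohort(tiny_config(seed = 77, lesion_count_mean = 0))
  s <- cohort$subjects[[1]]
  expect_equal(sum(grid_data(s$lesions)), 0)
  mt <- compute_tract_metrics(s$tract, s$lesions, s$diffusivity)
  expect_true(is.na(mt$ad_lesional))
  expect_equal(mt$ad_whole, mt$ad_nonlesional)
  expect_equal(mt$lesion_volume_ml, 0)
})

test_that("the exclusion mask is applied before any metric", {
  cohort <- generate_cohort(tiny_config(seed = 41))
  s <- cohort$subjects[[1]]
  # exclude a slab through the tract
  ex_arr <- array(0, grid_dim(s$tract)); ex_arr[, 1:14, ] <- 1
  ex <- binary_mask(voxel_grid(ex_arr, voxel_dims = c(2, 2, 2),
                               space = "phantom"))
  mt_ex <- compute_tract_metrics(s$tract, s$lesions, s$diffusivity,
                                 exclusion = ex)
  reduced <- mask_exclude(probability_map(s$tract), ex)
  expect_equal(mt_ex$tract_volume_ml, weighted_volume(reduced))
  expect_lt(mt_ex$tract_volume_ml,
            compute_tract_metrics(s$tract, s$lesions)$tract_volume_ml)
})

test_that("lesion frequency map counts subject fractions on tract support", {
  tract <- mk_map(rep(1, 27))
  les <- lapply(c(1, 1, 1, 0), function(on)
    mk_mask(c(rep(on, 1), rep(0, 26))))
  freq <- lesion_frequency_map(les, tract)
  expect_equal(grid_data(freq)[1], 0.75)
  expect_equal(sum(grid_data(freq)[-1]), 0)
  # restricted to tract support
  narrow <- mk_map(c(0, rep(1, 26)))
  expect_equal(sum(grid_data(lesion_frequency_map(les, narrow))), 0)
  # single subject: the map is that subject's mask within support
  f1 <- lesion_frequency_map(les[1], tract)
  expect_identical(grid_data(f1), grid_data(les[[1]]))
  expect_error(lesion_frequency_map(list(), tract), "non-empty")
})
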