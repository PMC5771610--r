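test_that("probability template is the voxel-wise subject fraction", {
  base <- array(0, c(3, 3, 3))
  a <- base; a[1:2, 1, 1] <- 1
  b <- base; b[2:3, 1, 1] <- 1
  tpl <- build_probability_template(list(binary_mask(a), binary_mask(b)))
  expect_equal(grid_data(tpl)[1:3, 1, 1], c(0.5, 1, 0.5))
  one <- binary_mask(a)
  expect_equal(grid_data(build_probability_template(list(one))),
               grid_data(one))
  empties <- replicate(3, mk_mask(0), simplify = FALSE)
  expect_equal(sum(grid_data(build_probability_template(empties))), 0)
  expect_error(build_probability_template(list()), "non-empty")
  expect_error(build_probability_template(
    list(one, mk_mask(1, shape = c(2, 2, 2)))), class = "grid_mismatch")
})

test_that("template volume equals the mean of individual mask volumes", {
  set.seed(5)
  for (i in 1:10) {
    masks <- replicate(sample(2:6, 1), random_mask(vdims = c(2, 2, 2)),
                       simplify = FALSE)
    tpl <- build_probability_template(masks)
    expect_equal(template_volume(tpl),
                 mean(vapply(masks, weighted_volume, numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("template volume follows voxel volume and weights", {
  expect_equal(template_volume(mk_map(0)), 0)
  # 1000 voxels of w=1 at 2x2x2 mm -> 8 mL
  tpl <- probability_map(array(1, c(10, 10, 10)), voxel_dims = c(2, 2, 2))
  expect_equal(template_volume(tpl), 8)
})

test_that("threshold optimisation matches the brute-force sweep", {
  set.seed(99)
  for (rep in 1:5) {
    cohort <- generate_cohort(tiny_config(seed = 100 + rep, n_subjects = 4))
    masks <- lapply(cohort$subjects, `[[`, "tract")
    fit <- tract_template(masks)
    oracle <- brute_force_threshold(fit$probability_template, masks)
    expect_identical(fit$optimal_threshold, oracle$threshold)
    expect_equal(fit$dsc_curve$mean_dsc, oracle$mean_dsc, tolerance = 1e-12)
  }
})

test_that("fitted template satisfies its structural invariants", {
  cohort <- generate_cohort(tiny_config(seed = 21, n_subjects = 5))
  masks <- lapply(cohort$subjects, `[[`, "tract")
  fit <- tract_template(masks)
  expect_true(fit$optimal_threshold %in% seq(0.01, 0.99, by = 0.01))
  k <- match(fit$optimal_threshold, fit$dsc_curve$threshold)
  expect_equal(mean(fit$per_subject_dsc), fit$dsc_curve$mean_dsc[k],
               tolerance = 1e-12)
  expect_true(all(fit$dsc_curve$mean_dsc[k] >= fit$dsc_curve$mean_dsc))
  expect_true(all(is.finite(fit$dsc_curve$mean_dsc)))
})

test_that("identical masks give DSC 1 everywhere and tie-break at 0.01", {
  m <- mk_mask(c(rep(1, 8), rep(0, 19)))
  fit <- tract_template(list(m, m, m))
  expect_true(all(fit$dsc_curve$mean_dsc == 1))
  expect_equal(fit$optimal_threshold, 0.01)
})

test_that("thresholds above the template maximum give empty templates, DSC 0", {
  m1 <- mk_mask(c(rep(1, 6), rep(0, 21)))
  m2 <- mk_mask(c(rep(0, 10), rep(1, 6), rep(0, 11)))  # disjoint from m1
  fit <- tract_template(list(m1, m2))  # max template value 0.5
  high <- fit$dsc_curve$mean_dsc[fit$dsc_curve$threshold > 0.5 + 1e-9]
  expect_true(all(high == 0))
})

test_that("empty subject masks contribute DSC 0 with a warning", {
  m <- mk_mask(c(rep(1, 6), rep(0, 21)))
  empty <- mk_mask(0)
  expect_warning(fit <- tract_template(list(m, empty)), "empty")
  expect_equal(fit$per_subject_dsc[2], 0)
})

test_that("jitter degrades the attainable mean DSC", {
  mean_dsc_at <- function(jitter_sd) {
    vals <- vapply(1:3, function(s) {
      cohort <- generate_cohort(tiny_config(seed = 300 + s, n_subjects = 4,
                                            jitter_sd = jitter_sd))
      fit <- tract_template(lapply(cohort$subjects, `[[`, "tract"))
      max(fit$dsc_curve$mean_dsc)
    }, numeric(1))
    mean(vals)
  }
  d0 <- mean_dsc_at(0)
  d1 <- mean_dsc_at(1)
  d3 <- mean_dsc_at(3)
  expect_equal(d0, 1)  # no jitter: all tracts identical
  expect_gt(d1, d3)
})
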