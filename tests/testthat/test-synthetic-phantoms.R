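test_that("phantom config validates its parameters", {
  expect_error(phantom_config(tube_radius = 0), "tube_radius")
  expect_error(phantom_config(jitter_sd = -1), ">= 0")
  expect_error(phantom_config(lesional_offset = c(ad = -0.1, rd = 0.1,
                                                  md = 0.1, fa = -0.01)),
               "offsets")
  expect_error(phantom_config(lesional_offset = c(ad = 0.1, rd = 0.1,
                                                  md = 0.1, fa = 0.05)),
               "offsets")
  expect_error(phantom_config(lesion_radius_range = c(3, 1)), "increasing")
})

test_that("cohort generation is deterministic given the seed", {
  c1 <- generate_cohort(tiny_config(seed = 55))
  c2 <- generate_cohort(tiny_config(seed = 55))
  expect_identical(grid_data(c1$subjects[[2]]$tract),
                   grid_data(c2$subjects[[2]]$tract))
  expect_identical(grid_data(c1$subjects[[2]]$lesions),
                   grid_data(c2$subjects[[2]]$lesions))
  expect_identical(grid_data(c1$subjects[[2]]$diffusivity$ad),
                   grid_data(c2$subjects[[2]]$diffusivity$ad))
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(tiny_config(seed = 56))
  expect_false(identical(grid_data(c1$subjects[[1]]$diffusivity$ad),
                         grid_data(c3$subjects[[1]]$diffusivity$ad)))
})

test_that("cohort generation leaves the caller's RNG stream untouched", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_cohort(tiny_config(seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("zero jitter collapses the ensemble onto one tube", {
  cohort <- generate_cohort(tiny_config(seed = 12, jitter_sd = 0,
                                        n_subjects = 4))
  masks <- lapply(cohort$subjects, `[[`, "tract")
  for (m in masks[-1])
    expect_identical(grid_data(m), grid_data(masks[[1]]))
  tpl <- build_probability_template(masks)
  expect_true(all(grid_data(tpl) %in% c(0, 1)))
})

test_that("zero lesion rate leaves every lesion mask empty", {
  cohort <- generate_cohort(tiny_config(seed = 3, lesion_count_mean = 0))
  expect_true(all(vapply(cohort$subjects, function(s)
    sum(grid_data(s$lesions)) == 0, logical(1))))
})

test_that("phantom diffusivity respects tensor-derived constraints", {
  cohort <- generate_cohort(tiny_config(seed = 17))
  d <- cohort$subjects[[1]]$diffusivity
  ad <- grid_data(d$ad); rd <- grid_data(d$rd); fa <- grid_data(d$fa)
  ok <- !is.na(ad) & !is.na(rd)
  expect_true(all(ad[ok] >= rd[ok]))
  expect_true(all(fa[!is.na(fa)] >= 0 & fa[!is.na(fa)] <= 1))
  expect_true(any(is.na(ad)))  # background outside the brain ellipsoid
})

test_that("truth check: volumes exact, means inside CLT tolerance", {
  cohort <- generate_cohort(tiny_config(seed = 29, n_subjects = 4))
  metrics <- lapply(cohort$subjects, function(s)
    compute_tract_metrics(s$tract, s$lesions, s$diffusivity,
                          subject_id = s$subject_id))
  tc <- truth_check(cohort, metrics)
  vols <- tc[grepl("volume", tc$quantity), ]
  expect_true(all(vols$ok))
  expect_equal(vols$recovered, vols$expected, tolerance = 1e-12)
  means <- tc[!grepl("volume", tc$quantity) & !is.na(tc$ok), ]
  expect_true(mean(means$ok) > 0.99)
  expect_error(truth_check(cohort, metrics[1:2]), "one entry per")
})

test_that("noise-free phantoms recover configured means exactly", {
  cohort <- generate_cohort(tiny_config(seed = 44, noise_sd = 0))
  s <- cohort$subjects[[1]]
  mt <- compute_tract_metrics(s$tract, s$lesions, s$diffusivity)
  expect_equal(mt$ad_nonlesional, 1.17, tolerance = 1e-12)
  expect_equal(mt$rd_nonlesional, 0.63, tolerance = 1e-12)
  if (!is.na(mt$ad_lesional)) {
    expect_equal(mt$ad_lesional, 1.46, tolerance = 1e-12)
    expect_equal(mt$fa_lesional, 0.37, tolerance = 1e-12)
  }
})

test_that("raising the configured lesional RD raises the recovered mean", {
  recovered_rd <- function(offset) {
    cohort <- generate_cohort(
      tiny_config(seed = 61, lesion_count_mean = 4,
                  lesional_offset = c(ad = 0.29, rd = offset, md = 0.22,
                                      fa = -0.01)))
    vals <- vapply(cohort$subjects, function(s)
      compute_tract_metrics(s$tract, s$lesions, s$diffusivity)$rd_lesional,
      numeric(1))
    mean(vals, na.rm = TRUE)
  }
  r <- vapply(c(0.05, 0.19, 0.4), recovered_rd, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("lesions concentrate in the tract's middle third", {
  for (seed in c(101, 202, 303)) {
    cohort <- generate_cohort(tiny_config(seed = seed, n_subjects = 6,
                                          lesion_count_mean = 4))
    masks <- lapply(cohort$subjects, `[[`, "tract")
    tpl <- build_probability_template(masks)
    freq <- lesion_frequency_map(lapply(cohort$subjects, `[[`, "lesions"),
                                 tpl)
    # arc-length thirds approximated by the anterior-posterior (y) extent
    # of the template support
    w <- grid_data(tpl); f <- grid_data(freq)
    ys <- which(apply(w > 0, 2, any))
    cuts <- quantile(ys, c(1 / 3, 2 / 3))
    yidx <- slice.index(w, 2)
    sup <- w > 0
    mid <- sup & yidx > cuts[1] & yidx <= cuts[2]
    ends <- sup & !mid
    expect_gt(mean(f[mid]), mean(f[ends]))
  }
})
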