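#' Configuration for synthetic tract phantoms
#'
#' Describes a cohort of synthetic subjects sharing a common curved-tube
#' tract (an analytic arc from an "LGN" point to an "occipital" region —
#' statistically, not anatomically, faithful). Each subject's tract is the
#' common tube with its control points displaced by smooth Gaussian jitter;
#' spherical T2-like lesions are placed with a configurable bias towards the
#' tract's middle third; diffusivity maps are a non-lesional baseline plus a
#' lesional offset inside lesions plus i.i.d. voxel noise, with background
#' outside an ellipsoidal "brain" set to `NA`.
#'
#' Default diffusivity parameters put phantoms in realistic white-matter
#' ranges for a demyelinating-lesion cohort: non-lesional AD 1.17, RD 0.63,
#' MD 0.81 (1e-3 mm^2/s), FA 0.38; lesions raise AD/RD/MD by 0.29/0.19/0.22
#' and lower FA by 0.01.
#'
#' @param grid_shape integer length-3 array shape.
#' @param voxel_dims voxel edge lengths in mm.
#' @param tube_radius tract tube radius in voxels (> 0).
#' @param n_subjects number of subjects in the cohort.
#' @param jitter_sd SD (voxels) of the Gaussian displacement applied to the
#'   tube's control points per subject; 0 makes all tracts identical.
#' @param lesion_count_mean Poisson mean of the per-subject lesion count.
#' @param lesion_radius_range uniform range (voxels) of lesion sphere radii.
#' @param middle_bias sampling-weight multiplier for lesion centres in the
#'   middle third of the tract's arc length (1 = unbiased).
#' @param nonlesional named numeric, baseline means for `ad`, `rd`, `md`
#'   (1e-3 mm^2/s) and `fa`.
#' @param lesional_offset named numeric added inside lesions; `ad`, `rd`,
#'   `md` must be >= 0 and `fa` <= 0 (lesions raise diffusivity, lower
#'   anisotropy).
#' @param noise_sd i.i.d. voxel noise SD applied to every map (>= 0).
#' @param seed integer RNG seed recorded in the truth records; `NULL` uses
#'   the current RNG state.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48, 56, 40),
                           voxel_dims = c(2, 2, 2),
                           tube_radius = 3,
                           n_subjects = 10,
                           jitter_sd = 0.75,
                           lesion_count_mean = 3,
                           lesion_radius_range = c(1.5, 3),
                           middle_bias = 4,
                           nonlesional = c(ad = 1.17, rd = 0.63,
                                           md = 0.81, fa = 0.38),
                           lesional_offset = c(ad = 0.29, rd = 0.19,
                                               md = 0.22, fa = -0.01),
                           noise_sd = 0.03,
                           seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("'grid_shape' must be three integers >= 8")
  if (!is.numeric(tube_radius) || tube_radius <= 0)
    stop("'tube_radius' must be > 0 voxels")
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1")
  if (jitter_sd < 0 || noise_sd < 0 || lesion_count_mean < 0)
    stop("SDs and rates must be >= 0")
  if (length(lesion_radius_range) != 2L ||
      any(lesion_radius_range <= 0) ||
      lesion_radius_range[1] > lesion_radius_range[2])
    stop("'lesion_radius_range' must be an increasing positive pair")
  if (middle_bias < 1) stop("'middle_bias' must be >= 1")
  for (nm in c("ad", "rd", "md", "fa")) {
    if (is.na(nonlesional[nm]) || is.na(lesional_offset[nm]))
      stop("'nonlesional' and 'lesional_offset' need names ad, rd, md, fa")
  }
  if (any(lesional_offset[c("ad", "rd", "md")] < 0) ||
      lesional_offset["fa"] > 0)
    stop("lesional offsets must raise AD/RD/MD (>= 0) and lower FA (<= 0)")
  structure(
    list(grid_shape = grid_shape, voxel_dims = as.numeric(voxel_dims),
         tube_radius = tube_radius, n_subjects = as.integer(n_subjects),
         jitter_sd = jitter_sd, lesion_count_mean = lesion_count_mean,
         lesion_radius_range = as.numeric(lesion_radius_range),
         middle_bias = middle_bias,
         nonlesional = nonlesional[c("ad", "rd", "md", "fa")],
         lesional_offset = lesional_offset[c("ad", "rd", "md", "fa")],
         noise_sd = noise_sd, seed = seed),
    class = "phantom_config")
}

# Quadratic Bezier control points for the common tube, in continuous voxel
# coordinates; the arc bulges laterally between an anterior "LGN" point and
# a posterior "occipital" endpoint, all well inside the brain ellipsoid.
tube_control_points <- function(shape) {
  rbind(c(0.38, 0.30, 0.50) * shape,
        c(0.68, 0.52, 0.58) * shape,
        c(0.50, 0.78, 0.45) * shape)
}

# Voxels of an ellipsoidal "brain" inscribed in the grid.
brain_mask_array <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- shape / 2 - 1
  ii <- slice.index(array(0, shape), 1)
  jj <- slice.index(array(0, shape), 2)
  kk <- slice.index(array(0, shape), 3)
  ((ii - ctr[1]) / ax[1])^2 + ((jj - ctr[2]) / ax[2])^2 +
    ((kk - ctr[3]) / ax[3])^2 <= 1
}

# Integer offsets of a voxel-space ball of the given radius.
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
}

# Stamp a ball at each centre (matrix of rows x 3, continuous coords) into a
# logical array; returns the array. Out-of-grid voxels are clipped.
stamp_balls <- function(shape, centers, radius) {
  out <- array(FALSE, shape)
  off <- as.matrix(ball_offsets(radius))
  for (i in seq_len(nrow(centers))) {
    ctr <- round(centers[i, ])
    vox <- sweep(off, 2, ctr, "+")
    keep <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
            vox[, 2] >= 1 & vox[, 2] <= shape[2] &
            vox[, 3] >= 1 & vox[, 3] <= shape[3]
    if (any(keep))
      out[vox[keep, , drop = FALSE]] <- TRUE
  }
  out
}

# Rasterise a jittered tube: returns list(mask = logical array,
# arc = numeric array of the arc-length parameter t in [0,1] that first
# reached each tract voxel, NA outside).
rasterize_tube <- function(shape, ctrl, radius, n_samples = 150) {
  t <- seq(0, 1, length.out = n_samples)
  bez <- outer((1 - t)^2, ctrl[1, ]) + outer(2 * t * (1 - t), ctrl[2, ]) +
    outer(t^2, ctrl[3, ])
  mask <- array(FALSE, shape)
  arc <- array(NA_real_, shape)
  off <- as.matrix(ball_offsets(radius))
  for (i in seq_along(t)) {
    ctr <- round(bez[i, ])
    vox <- sweep(off, 2, ctr, "+")
    keep <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
            vox[, 2] >= 1 & vox[, 2] <= shape[2] &
            vox[, 3] >= 1 & vox[, 3] <= shape[3]
    vox <- vox[keep, , drop = FALSE]
    if (nrow(vox) == 0) next
    new <- !mask[vox]
    mask[vox] <- TRUE
    if (any(new))
      arc[vox[new, , drop = FALSE]] <- t[i]
  }
  list(mask = mask, arc = arc)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n_subjects` phantoms from a [phantom_config()]: per subject a
#' jittered tube tract mask, a lesion mask (spheres biased towards the
#' tract's middle third, clipped to the brain), a [diffusivity_set()] built
#' from the configured baseline, lesional offsets and voxel noise, and a
#' truth record holding the exact tract/lesion volumes and the expected
#' compartment means implied by the generative parameters. Deterministic
#' given `config$seed`; the caller's RNG state is left untouched.
#'
#' @param config a [phantom_config()].
#' @return Object of class `phantom_cohort`: list with `subjects` (each a
#'   list `subject_id`, `tract`, `lesions`, `diffusivity`, `truth`),
#'   `config`, and `truth` (all truth records as one data frame).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed))
        rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(config$seed)
  }

  shape <- config$grid_shape
  vdims <- config$voxel_dims
  vox_ml <- prod(vdims) / 1000
  ctrl0 <- tube_control_points(shape)
  brain <- brain_mask_array(shape)
  metrics <- c("ad", "rd", "md", "fa")

  mk_grid <- function(arr) voxel_grid(arr, voxel_dims = vdims,
                                      space = "phantom")

  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    ctrl <- ctrl0 + matrix(stats::rnorm(9, 0, config$jitter_sd), 3, 3)
    tube <- rasterize_tube(shape, ctrl, config$tube_radius)
    tract_arr <- tube$mask & brain

    # lesion centres sampled from tract voxels, middle third up-weighted
    lesion_arr <- array(FALSE, shape)
    n_lesions <- stats::rpois(1, config$lesion_count_mean)
    tract_idx <- which(tract_arr)
    if (n_lesions > 0 && length(tract_idx) > 0) {
      tpos <- tube$arc[tract_idx]
      wts <- ifelse(!is.na(tpos) & tpos >= 1 / 3 & tpos <= 2 / 3,
                    config$middle_bias, 1)
      for (l in seq_len(n_lesions)) {
        idx <- sample(seq_along(tract_idx), 1, prob = wts)
        ctr <- arrayInd(tract_idx[idx], shape)[1, ]
        radius <- stats::runif(1, config$lesion_radius_range[1],
                               config$lesion_radius_range[2])
        lesion_arr <- lesion_arr |
          stamp_balls(shape, matrix(ctr, 1, 3), radius)
      }
      lesion_arr <- lesion_arr & brain
    }

    lesional_arr <- tract_arr & lesion_arr
    n_tract <- sum(tract_arr)
    n_les <- sum(lesional_arr)
    n_nonles <- n_tract - n_les

    maps <- list()
    for (m in metrics) {
      base <- config$nonlesional[[m]]
      arr <- array(stats::rnorm(prod(shape), base, config$noise_sd), shape)
      arr[lesion_arr] <- arr[lesion_arr] + config$lesional_offset[[m]]
      arr[!brain] <- NA_real_
      maps[[m]] <- arr
    }
    maps$fa <- pmin(pmax(maps$fa, 0), 1)
    maps$ad <- pmax(maps$ad, maps$rd)  # axial >= radial by construction

    expected <- list()
    for (m in metrics) {
      base <- config$nonlesional[[m]]
      les <- base + config$lesional_offset[[m]]
      expected[[paste0(m, "_lesional")]] <-
        if (n_les > 0) les else NA_real_
      expected[[paste0(m, "_nonlesional")]] <-
        if (n_nonles > 0) base else NA_real_
      expected[[paste0(m, "_whole")]] <-
        if (n_tract > 0) (n_les * les + n_nonles * base) / n_tract
        else NA_real_
    }

    truth <- c(list(subject_id = sprintf("phantom%03d", s),
                    n_tract_voxels = n_tract,
                    n_lesional_voxels = n_les,
                    n_nonlesional_voxels = n_nonles,
                    tract_volume_ml = n_tract * vox_ml,
                    lesional_volume_ml = n_les * vox_ml,
                    nonlesional_volume_ml = n_nonles * vox_ml,
                    noise_sd = config$noise_sd,
                    seed = if (is.null(config$seed)) NA_integer_
                           else config$seed),
               expected)

    subjects[[s]] <- list(
      subject_id = truth$subject_id,
      tract = binary_mask(mk_grid(array(as.double(tract_arr), shape))),
      lesions = binary_mask(mk_grid(array(as.double(lesion_arr), shape))),
      diffusivity = suppressWarnings(
        diffusivity_set(mk_grid(maps$ad), mk_grid(maps$rd),
                        mk_grid(maps$md), mk_grid(maps$fa))),
      truth = truth)
  }

  structure(
    list(subjects = subjects, config = config,
         truth = do.call(rbind, lapply(subjects, function(s)
           as.data.frame(s$truth, stringsAsFactors = FALSE)))),
    class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf(
    "<phantom_cohort> %d subjects on a %s grid (%s mm voxels), seed %s\n",
    length(x$subjects), paste(x$config$grid_shape, collapse = "x"),
    paste(x$config$voxel_dims, collapse = "x"),
    if (is.null(x$config$seed)) "unset" else x$config$seed))
  cat(sprintf("  tract voxels per subject: %s; lesional: %s\n",
              paste(range(x$truth$n_tract_voxels), collapse = "-"),
              paste(range(x$truth$n_lesional_voxels), collapse = "-")))
  invisible(x)
}

#' Check recovered metrics against phantom ground truth
#'
#' Compares [compute_tract_metrics()] output on a generated cohort with the
#' cohort's truth records. Volumes must match exactly (binary-mask volumetry
#' is voxel counting); each compartment diffusivity mean must fall within
#' the noise-predicted tolerance `4 * noise_sd / sqrt(n_voxels)` of its
#' generative expectation (four standard errors of the voxel-noise mean).
#'
#' @param cohort a `phantom_cohort`.
#' @param metrics list of `tract_metrics`, one per subject in cohort order.
#' @return Data frame of class `truth_check`, one row per subject x
#'   quantity: columns `subject_id`, `quantity`, `recovered`, `expected`,
#'   `tolerance`, `ok` (NA when the compartment is empty).
#' @export
truth_check <- function(cohort, metrics) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (length(metrics) != length(cohort$subjects))
    stop("'metrics' must have one entry per cohort subject")
  rows <- list()
  for (s in seq_along(cohort$subjects)) {
    tr <- cohort$subjects[[s]]$truth
    mt <- metrics[[s]]
    stopifnot(inherits(mt, "tract_metrics"))
    add <- function(qty, rec, exp, tol) {
      rows[[length(rows) + 1]] <<- data.frame(
        subject_id = tr$subject_id, quantity = qty,
        recovered = rec, expected = exp, tolerance = tol,
        ok = if (is.na(rec) || is.na(exp)) NA else
          abs(rec - exp) <= tol,
        stringsAsFactors = FALSE)
    }
    vol_tol <- 1e-9 * max(1, tr$tract_volume_ml)
    add("tract_volume_ml", mt$tract_volume_ml, tr$tract_volume_ml, vol_tol)
    add("lesional_volume_ml", mt$lesional_volume_ml, tr$lesional_volume_ml,
        vol_tol)
    add("nonlesional_volume_ml", mt$nonlesional_volume_ml,
        tr$nonlesional_volume_ml, vol_tol)
    ns <- c(whole = tr$n_tract_voxels, lesional = tr$n_lesional_voxels,
            nonlesional = tr$n_nonlesional_voxels)
    for (m in c("ad", "rd", "md", "fa"))
      for (comp in names(ns)) {
        key <- paste(m, comp, sep = "_")
        tol <- if (ns[[comp]] > 0)
          4 * tr$noise_sd / sqrt(ns[[comp]]) else NA_real_
        add(key, mt[[key]], tr[[key]], tol)
      }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("truth_check", "data.frame")
  out
}

#' @export
print.truth_check <- function(x, ...) {
  n_ok <- sum(x$ok, na.rm = TRUE)
  n_tot <- sum(!is.na(x$ok))
  cat(sprintf("Phantom truth check: %d/%d quantities within tolerance\n",
              n_ok, n_tot))
  bad <- x[!is.na(x$ok) & !x$ok, ]
  if (nrow(bad) > 0) {
    cat("Outside tolerance:\n")
    print.data.frame(bad, row.names = FALSE)
  }
  invisible(x)
}
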