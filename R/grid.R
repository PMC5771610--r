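#' Voxel grids, binary masks and probability maps
#'
#' A `voxel_grid` is the substrate of every image in the package: a 3D numeric
#' array together with its voxel dimensions (mm), a 4x4 voxel-to-world affine
#' and a free-text label of the coordinate space. All arithmetic in the
#' package happens in voxel space; the affine is carried only so that NIfTI
#' round trips preserve world coordinates. Registration and resampling are
#' upstream concerns: every operation requires its inputs to live on the same
#' grid and raises a `grid_mismatch` error otherwise, never resampling
#' silently.
#'
#' @param data numeric 3D array (or an object coercible to one).
#' @param voxel_dims length-3 positive numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal scaling
#'   by `voxel_dims` with zero translation.
#' @param space free-text coordinate-space tag (e.g. `"ICBM2009a"`,
#'   `"subject-native"`).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), voxel_dims = c(2, 2, 2))
#' voxel_volume(g)  # 8 mm^3
#' @export
voxel_grid <- function(data, voxel_dims = c(1, 1, 1), affine = NULL,
                       space = "unknown") {
  if (inherits(data, "voxel_grid")) return(data)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array, got ", length(dim(data)), " dimensions")
  storage.mode(data) <- "double"
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stop("'voxel_dims' must be three strictly positive lengths in mm")
  if (is.null(affine)) {
    affine <- diag(c(voxel_dims, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)))
      stop("'affine' must be a 4x4 matrix")
  }
  structure(
    list(data = data, voxel_dims = voxel_dims, affine = affine,
         space = as.character(space)[1]),
    class = "voxel_grid"
  )
}

#' @rdname voxel_grid
#' @param x a `voxel_grid`, `binary_mask` or `probability_map`.
#' @export
voxel_volume <- function(x) {
  prod(as_grid(x)$voxel_dims)
}

#' @rdname voxel_grid
#' @export
grid_data <- function(x) {
  as_grid(x)$data
}

#' @rdname voxel_grid
#' @export
grid_dim <- function(x) {
  dim(as_grid(x)$data)
}

# Internal: unwrap masks/maps to their underlying voxel_grid.
as_grid <- function(x) {
  if (inherits(x, c("binary_mask", "probability_map"))) return(x$grid)
  if (inherits(x, "voxel_grid")) return(x)
  stop("expected a voxel_grid, binary_mask or probability_map")
}

# Replace the data of x while keeping grid geometry and class.
with_data <- function(x, data) {
  g <- as_grid(x)
  g$data <- data
  if (inherits(x, "binary_mask")) return(new_binary_mask(g))
  if (inherits(x, "probability_map")) return(new_probability_map(g))
  g
}

new_binary_mask <- function(grid) structure(list(grid = grid),
                                            class = "binary_mask")
new_probability_map <- function(grid) structure(list(grid = grid),
                                                class = "probability_map")

#' Binary masks and probability maps
#'
#' A `binary_mask` is a voxel grid restricted to values {0, 1}: individual
#' tract masks from tractography, T2 lesion masks, exclusion masks. A
#' `probability_map` is a voxel grid restricted to [0, 1]: tract templates and
#' atlases, where each voxel carries the fraction of a reference cohort whose
#' tract occupies it (or any other per-voxel weight).
#'
#' @param x a 3D array, `voxel_grid`, or an existing mask/map.
#' @param ... passed to [voxel_grid()] when `x` is a plain array.
#' @return A `binary_mask` or `probability_map`.
#' @examples
#' m <- binary_mask(array(c(0, 1), c(2, 2, 2)), voxel_dims = c(2, 2, 2))
#' p <- probability_map(array(0.5, c(2, 2, 2)))
#' @export
binary_mask <- function(x, ...) {
  if (inherits(x, "binary_mask")) return(x)
  if (inherits(x, "probability_map")) x <- x$grid
  g <- voxel_grid(x, ...)
  v <- g$data
  bad <- !is.na(v) & v != 0 & v != 1
  if (any(bad))
    stop(errorCondition(
      sprintf("binary mask contains %d voxel(s) outside {0, 1} (e.g. %g)",
              sum(bad), v[bad][1]),
      class = c("validation_error", "tractmetrics_error", "error", "condition")))
  new_binary_mask(g)
}

#' @rdname binary_mask
#' @export
probability_map <- function(x, ...) {
  if (inherits(x, "probability_map")) return(x)
  if (inherits(x, "binary_mask")) return(new_probability_map(x$grid))
  g <- voxel_grid(x, ...)
  v <- g$data
  bad <- !is.na(v) & (v < 0 | v > 1)
  if (any(bad))
    stop(errorCondition(
      sprintf("probability map contains %d voxel(s) outside [0, 1] (e.g. %g)",
              sum(bad), v[bad][1]),
      class = c("validation_error", "tractmetrics_error", "error", "condition")))
  new_probability_map(g)
}

#' Test whether two images live on the same voxel grid
#'
#' Pure predicate: shapes must be equal, voxel dimensions equal within
#' `dim_tol` mm, affines equal within `affine_tol`, and space tags identical.
#' Callers raise a `grid_mismatch` error when this returns `FALSE`; the
#' package never resamples to reconcile grids.
#'
#' @param a,b voxel grids (or masks/maps).
#' @param dim_tol absolute tolerance on voxel dimensions, mm.
#' @param affine_tol absolute tolerance on affine entries.
#' @return `TRUE` or `FALSE`.
#' @export
check_same_grid <- function(a, b, dim_tol = 1e-6, affine_tol = 1e-4) {
  ga <- as_grid(a); gb <- as_grid(b)
  identical(dim(ga$data), dim(gb$data)) &&
    all(abs(ga$voxel_dims - gb$voxel_dims) <= dim_tol) &&
    all(abs(ga$affine - gb$affine) <= affine_tol) &&
    identical(ga$space, gb$space)
}

stop_grid_mismatch <- function(what = "inputs") {
  stop(errorCondition(
    paste0(what, " are not on the same voxel grid ",
           "(shape, voxel dimensions, affine and space tag must all match)"),
    class = c("grid_mismatch", "tractmetrics_error", "error", "condition")))
}

assert_same_grid <- function(a, b, what = "inputs") {
  if (!check_same_grid(a, b)) stop_grid_mismatch(what)
  invisible(TRUE)
}

#' Binarise a probability map at a threshold
#'
#' Voxels below the threshold are zeroed; with `inclusive = TRUE` (default) a
#' voxel exactly at the threshold survives, i.e. the rule is `value >=
#' threshold`. The exclusive variant (`value > threshold`) is exposed for
#' sensitivity analysis.
#'
#' @param p a `probability_map`.
#' @param threshold fraction strictly inside (0, 1).
#' @param inclusive keep voxels exactly at the threshold?
#' @return A `binary_mask` on the same grid.
#' @export
binarize <- function(p, threshold, inclusive = TRUE) {
  p <- probability_map(p)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must be a single number strictly inside (0, 1)")
  v <- p$grid$data
  out <- if (inclusive) (v >= threshold) else (v > threshold)
  out <- array(as.double(out & !is.na(v)), dim = dim(v))
  new_binary_mask(with_data(p$grid, out))
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. When both masks are empty the masks are
#' identical, and by convention the coefficient is 1.
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return Overlap fraction in [0, 1].
#' @export
dice <- function(a, b) {
  a <- binary_mask(a); b <- binary_mask(b)
  assert_same_grid(a, b, "masks")
  va <- a$grid$data; vb <- b$grid$data
  na <- sum(va, na.rm = TRUE)
  nb <- sum(vb, na.rm = TRUE)
  if (na + nb == 0) return(1.0)
  2 * sum(va * vb, na.rm = TRUE) / (na + nb)
}

#' Zero out voxels covered by an exclusion mask
#'
#' Applies an anatomical exclusion (e.g. a thalamus mask) to a tract map:
#' voxels where the exclusion mask is 1 are set to 0, all others are left
#' unchanged. Idempotent.
#'
#' @param target a `probability_map` or `binary_mask`.
#' @param exclusion a `binary_mask` on the same grid.
#' @return Object of the same class as `target`.
#' @export
mask_exclude <- function(target, exclusion) {
  exclusion <- binary_mask(exclusion)
  assert_same_grid(target, exclusion, "target and exclusion mask")
  v <- grid_data(target)
  ex <- exclusion$grid$data
  v[!is.na(ex) & ex == 1] <- 0
  with_data(target, v)
}

#' Probability-weighted volume of a map or mask
#'
#' `voxel_volume * sum(weights)`, converted from mm^3 to mL. For a binary
#' mask this is voxel count times voxel volume; for a probability map each
#' voxel contributes its weight, so the volume of a cohort-average template
#' equals the mean of the individual mask volumes.
#'
#' @param x a `probability_map`, `binary_mask` or `voxel_grid`.
#' @return Volume in mL.
#' @export
weighted_volume <- function(x) {
  voxel_volume(x) * sum(grid_data(x), na.rm = TRUE) / 1000
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s, %s mm voxels, space '%s'\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$voxel_dims, trim = TRUE), collapse = " x "),
              x$space))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels set, volume %.3f mL on ",
              format(sum(x$grid$data, na.rm = TRUE)), weighted_volume(x)))
  print(x$grid)
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  v <- x$grid$data
  cat(sprintf(
    "<probability_map> support %d voxels, sum(w) = %.2f, volume %.3f mL on ",
    sum(v > 0, na.rm = TRUE), sum(v, na.rm = TRUE), weighted_volume(x)))
  print(x$grid)
  invisible(x)
}
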