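#' Read and write voxel grids as NIfTI-1
#'
#' `read_volume()` loads a `.nii`/`.nii.gz` file into a [voxel_grid()] (or a
#' mask/map when `type` is given), taking voxel dimensions and the affine
#' from the header. `write_volume()` writes one back; binary masks are
#' stored as unsigned 8-bit integers, probability maps as 32-bit float, so a
#' round trip preserves data within float32 precision along with voxel
#' dimensions and affine.
#'
#' Validation on read: a `"mask"` must contain only {0, 1} (otherwise a
#' `validation_error`); a `"probability"` map may stray outside [0, 1] by at
#' most 1e-6 — such values are clamped with a warning, anything further out
#' is a `validation_error`.
#'
#' @param path file path to a NIfTI-1 image.
#' @param type `"scalar"` (plain grid), `"mask"`, or `"probability"`.
#' @param space coordinate-space tag to attach (NIfTI carries none).
#' @return `read_volume()`: a `voxel_grid`, `binary_mask` or
#'   `probability_map`; `write_volume()`: the path, invisibly.
#' @export
read_volume <- function(path, type = c("scalar", "mask", "probability"),
                        space = "unknown") {
  type <- match.arg(type)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(errorCondition(
                    paste0("cannot read '", path, "' as NIfTI: ",
                           conditionMessage(e)),
                    class = c("format_error", "tractmetrics_error",
                              "error", "condition"))))
  data <- array(as.double(img), dim = dim(img)[1:3])
  vdims <- abs(RNifti::pixdim(img))[1:3]
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  g <- voxel_grid(data, voxel_dims = vdims, affine = affine, space = space)
  switch(type,
    scalar = g,
    mask = binary_mask(g),
    probability = {
      v <- g$data
      low <- !is.na(v) & v < 0 & v >= -1e-6
      high <- !is.na(v) & v > 1 & v <= 1 + 1e-6
      if (any(low) || any(high)) {
        warning(sum(low) + sum(high),
                " voxel(s) within 1e-6 outside [0, 1] clamped")
        v[low] <- 0; v[high] <- 1
        g$data <- v
      }
      probability_map(g)
    })
}

#' @rdname read_volume
#' @param x a `voxel_grid`, `binary_mask` or `probability_map`.
#' @export
write_volume <- function(x, path) {
  g <- as_grid(x)
  datatype <- if (inherits(x, "binary_mask")) "uint8" else "float"
  img <- RNifti::asNifti(g$data)
  RNifti::pixdim(img) <- g$voxel_dims  # before the xforms, which rescale it
  RNifti::qform(img) <- structure(g$affine, code = 2L)
  RNifti::sform(img) <- structure(g$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Load and validate a cohort manifest
#'
#' A manifest is a CSV (UTF-8, comma-separated, '.' decimal, header row)
#' with one row per subject: `subject_id`, `tract_path`, `lesion_path`, and
#' optionally `exclusion_path`, `ad_path`, `rd_path`, `md_path`, `fa_path`,
#' `brain_volume_ml` and `scaling_factor` (default 1). Subject ids must be
#' unique and every referenced path must exist.
#'
#' @param path CSV file path, or a data frame already in manifest layout.
#' @return The validated manifest data frame.
#' @export
read_manifest <- function(path) {
  man <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(man) == 0L) stop("manifest has no subjects")
  required <- c("subject_id", "tract_path", "lesion_path")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols) > 0)
    stop("manifest lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(man$subject_id))
    stop("manifest subject_id values must be unique")
  path_cols <- intersect(
    c("tract_path", "lesion_path", "exclusion_path",
      "ad_path", "rd_path", "md_path", "fa_path"), names(man))
  for (col in path_cols) {
    p <- man[[col]]
    p <- p[!is.na(p) & p != ""]
    bad <- p[!file.exists(p)]
    if (length(bad) > 0)
      stop("manifest ", col, " file(s) not found: ",
           paste(utils::head(bad, 3), collapse = ", "))
  }
  if (is.null(man$scaling_factor)) man$scaling_factor <- 1
  man$scaling_factor[is.na(man$scaling_factor)] <- 1
  if (is.null(man$brain_volume_ml)) man$brain_volume_ml <- NA_real_
  man
}

manifest_field <- function(row, col) {
  if (!col %in% names(row)) return(NA_character_)
  v <- row[[col]]
  if (is.na(v) || v == "") NA_character_ else v
}

#' Run the tract-metrics pipeline over a cohort manifest
#'
#' For every manifest row, loads the tract (the subject's own tractography
#' mask in `"individual"` mode, or a shared probability template — already
#' warped to each subject's grid upstream — in `"template"` mode), the
#' lesion mask, the optional exclusion mask and diffusivity maps, and runs
#' [compute_tract_metrics()]. Per-subject failures are logged and skipped;
#' the run aborts if more than half the cohort fails.
#'
#' @param manifest path to a manifest CSV, or a data frame (see
#'   [read_manifest()]).
#' @param mode `"individual"` (per-subject tract masks) or `"template"`.
#' @param template in template mode: a `probability_map` or a NIfTI path.
#' @param diffusivity_units `"1e-3 mm^2/s"` (package convention, default)
#'   or `"mm^2/s"` (converted on load).
#' @param out_csv optional path; the metrics table is written there as CSV,
#'   with undefined (NA) cells left empty.
#' @return Data frame of per-subject metrics (one row per subject that
#'   succeeded), with attribute `"failures"` naming skipped subjects.
#' @export
run_pipeline <- function(manifest, mode = c("individual", "template"),
                         template = NULL,
                         diffusivity_units = c("1e-3 mm^2/s", "mm^2/s"),
                         out_csv = NULL) {
  mode <- match.arg(mode)
  diffusivity_units <- match.arg(diffusivity_units)
  scale <- if (diffusivity_units == "mm^2/s") 1000 else 1
  man <- read_manifest(manifest)
  if (mode == "template") {
    if (is.null(template)) stop("template mode needs a 'template'")
    if (is.character(template))
      template <- read_volume(template, type = "probability")
    template <- probability_map(template)
  }

  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    res <- tryCatch({
      tract <- if (mode == "individual") {
        probability_map(read_volume(row$tract_path, type = "mask"))
      } else {
        template
      }
      lesions <- read_volume(row$lesion_path, type = "mask")
      if (mode == "template" && !check_same_grid(tract, lesions))
        stop(errorCondition(
          paste0("template grid does not match subject '",
                 row$subject_id, "'"),
          class = c("grid_mismatch", "tractmetrics_error",
                    "error", "condition")))
      exclusion <- if (!is.na(manifest_field(row, "exclusion_path")))
        read_volume(row$exclusion_path, type = "mask") else NULL
      dset <- if (!is.na(manifest_field(row, "ad_path"))) {
        diffusivity_set(read_volume(row$ad_path),
                        read_volume(row$rd_path),
                        read_volume(row$md_path),
                        read_volume(row$fa_path),
                        scale = scale)
      } else NULL
      as.data.frame(compute_tract_metrics(
        tract, lesions, dset, exclusion = exclusion,
        brain_volume_ml = row$brain_volume_ml,
        scaling_factor = row$scaling_factor,
        subject_id = row$subject_id))
    }, grid_mismatch = function(e) e, error = function(e) e)
    if (inherits(res, "grid_mismatch")) stop(res)
    if (inherits(res, "error")) {
      warning("subject '", row$subject_id, "' failed: ",
              conditionMessage(res))
      failures <- c(failures, row$subject_id)
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(failures) > nrow(man) / 2)
    stop("more than half the cohort failed (",
         length(failures), "/", nrow(man), " subjects)")
  metrics <- do.call(rbind, rows)
  attr(metrics, "failures") <- failures
  if (!is.null(out_csv))
    utils::write.csv(metrics, out_csv, row.names = FALSE, na = "")
  metrics
}

#' Compare metric tables from several reconstruction methods
#'
#' Takes one per-subject metrics table per method (the output of
#' [run_pipeline()] or `tractmetrics metrics`), aligns subjects by
#' `subject_id`, and runs [paired_method_comparison()] on every shared
#' numeric metric column.
#'
#' @param tables named list of metrics data frames, one per method.
#' @param metrics character vector of metric columns to compare; default is
#'   every numeric column present in all tables.
#' @return List with `report` (data frame: one row per metric x method
#'   pair, plus per-metric ANOVA p) and `agreement` (named list of
#'   `method_agreement` objects, one per metric).
#' @export
compare_metric_tables <- function(tables, metrics = NULL) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need metrics tables from at least 2 methods")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a named list (method names)")
  ids <- Reduce(intersect, lapply(tables, function(t) t$subject_id))
  if (length(ids) < 3L) stop("fewer than 3 subjects shared by all methods")
  tables <- lapply(tables, function(t) t[match(ids, t$subject_id), ])
  if (is.null(metrics)) {
    num_cols <- lapply(tables, function(t)
      names(t)[vapply(t, is.numeric, logical(1))])
    metrics <- Reduce(intersect, num_cols)
  }
  report <- list()
  agreement <- list()
  for (m in metrics) {
    vals <- as.data.frame(lapply(tables, `[[`, m))
    names(vals) <- names(tables)
    if (any(!stats::complete.cases(vals))) next
    if (any(vapply(vals, stats::sd, numeric(1)) == 0)) next
    ag <- paired_method_comparison(vals)
    agreement[[m]] <- ag
    rep_m <- ag$pairs
    rep_m <- cbind(metric = m, rep_m, anova_p = ag$anova_p)
    report[[m]] <- rep_m
  }
  list(report = do.call(rbind, c(report, make.row.names = FALSE)),
       agreement = agreement)
}

#' Read a phantom configuration from YAML
#'
#' The YAML keys mirror the arguments of [phantom_config()]; absent keys
#' take the defaults. `nonlesional` and `lesional_offset` are maps with
#' keys `ad`, `rd`, `md`, `fa`.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's `seed` key.
#' @return A [phantom_config()].
#' @export
phantom_config_from_yaml <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(phantom_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown phantom config key(s): ", paste(unknown, collapse = ", "))
  for (nm in c("nonlesional", "lesional_offset"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(seed)) raw$seed <- seed
  do.call(phantom_config, raw)
}

#' Write a generated phantom cohort to disk
#'
#' Writes per-subject NIfTI volumes (tract, lesions, AD/RD/MD/FA), a
#' manifest CSV ready for [run_pipeline()], and `truth.csv` with the ground
#' truth records.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory, created if needed.
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    pth <- function(what) file.path(dir, paste0(s$subject_id, "_", what,
                                                ".nii.gz"))
    write_volume(s$tract, pth("tract"))
    write_volume(s$lesions, pth("lesions"))
    for (m in c("ad", "rd", "md", "fa"))
      write_volume(s$diffusivity[[m]], pth(m))
    data.frame(subject_id = s$subject_id,
               tract_path = pth("tract"), lesion_path = pth("lesions"),
               ad_path = pth("ad"), rd_path = pth("rd"),
               md_path = pth("md"), fa_path = pth("fa"),
               brain_volume_ml = NA_real_, scaling_factor = 1,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, na = "")
  invisible(man)
}
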