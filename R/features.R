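#' All shape features of one lesion
#'
#' Convenience wrapper running the mesh- and voxel-based shape features for a
#' single lesion and returning them as a one-row data frame matching the
#' lesion table layout. `surface_area_icv` is the mesh surface area in mm^2
#' divided by the intracranial volume in ml (declared unit convention for the
#' ICV correction); it is `NA` when `icv` is not given.
#'
#' @param lesion a `lesion_voxel_set`.
#' @param grid the [volume_grid()] the voxels refer to.
#' @param icv intracranial volume in ml (optional).
#' @param image optional scalar image for the curvature features (defaults to
#'   the lesion's binary mask, see [shape_index_curvedness()]).
#' @param sigma Gaussian scale in voxels for curvature features.
#' @param step_deg angular grid for the orthogonal diameter.
#' @return one-row data frame of features.
#' @export
shape_features <- function(lesion, grid, icv = NULL, image = NULL, sigma = 1,
                           step_deg = 1) {
  mesh <- build_lesion_mesh(lesion, grid)
  md <- max_diameter(mesh)
  mo <- min_orthogonal_diameter(mesh, md$direction, step_deg = step_deg)
  cf <- compactness_features(mesh)
  fd <- fractal_dimension(lesion)
  sc <- shape_index_curvedness(lesion, grid, image = image, sigma = sigma)
  area <- cf$area_mm2
  data.frame(
    lesion_id = lesion$lesion_id,
    n_voxels = lesion$n_voxels,
    volume_ml = cf$volume_mm3 / 1000,
    surface_area_mm2 = area,
    surface_area_icv = if (is.null(icv)) NA_real_ else area / icv,
    eccentricity = md$length / mo,
    compactness1 = cf$compactness1,
    compactness2 = cf$compactness2,
    compactness3 = cf$compactness3,
    fractal_dimension = fd$fd,
    shape_index = sc$shape_index,
    curvedness = sc$curvedness,
    max_diameter_mm = md$length,
    bbox_x_mm = cf$dims_mm[1], bbox_y_mm = cf$dims_mm[2],
    bbox_z_mm = cf$dims_mm[3]
  )
}

# fixed lesion table header (contract of the CSV interface)
lesion_table_columns <- c(
  "subject_id", "lesion_id", "n_voxels", "volume_ml", "surface_area_icv",
  "eccentricity", "compactness1", "compactness2", "compactness3",
  "fractal_dimension", "shape_index", "curvedness", "lesion_class", "lobe",
  "min_ventricle_distance_mm", "max_diameter_mm")

#' Write / read a lesion table
#'
#' CSV with the fixed header columns `subject_id, lesion_id, n_voxels,
#' volume_ml, surface_area_icv, eccentricity, compactness1, compactness2,
#' compactness3, fractal_dimension, shape_index, curvedness, lesion_class,
#' lobe, min_ventricle_distance_mm, max_diameter_mm` (extra columns such as
#' `surface_area_mm2` or `override_applied` are preserved). Missing optional
#' values (e.g. the lobe of a non-punctuate lesion) are written as empty
#' fields, never zero, and read back as `NA`.
#'
#' @param records lesion record data frame.
#' @param path CSV path.
#' @return `path` invisibly (write); the records data frame (read).
#' @export
write_lesion_table <- function(records, path) {
  miss <- setdiff(lesion_table_columns, names(records))
  for (m in miss) records[[m]] <- NA
  first <- lesion_table_columns
  records <- records[, c(first, setdiff(names(records), first)), drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_lesion_table
#' @export
read_lesion_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  miss <- setdiff(lesion_table_columns, names(df))
  if (length(miss) > 0)
    stop("read_lesion_table: malformed header, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("override_applied" %in% names(df))
    df$override_applied <- as.logical(df$override_applied)
  df
}

#' Write / read a subject table
#'
#' CSV with columns `subject_id, group, age, sex, icv` and optional covariates
#' `gm_volume, wm_volume, diabetes_duration` (missing values are empty
#' fields). `group` must be `patient`/`control`, `sex` must be `M`/`F`,
#' `age` and `icv` strictly positive.
#'
#' @param meta subject data frame.
#' @param path CSV path.
#' @return `path` invisibly (write); the validated data frame (read).
#' @export
write_subject_table <- function(meta, path) {
  validate_subject_table(meta)
  utils::write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_subject_table(df)
  df
}

validate_subject_table <- function(meta) {
  need <- c("subject_id", "group", "age", "sex", "icv")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop("subject table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(meta$group %in% c("patient", "control")))
    stop("subject table: group must be 'patient' or 'control'", call. = FALSE)
  if (!all(meta$sex %in% c("M", "F")))
    stop("subject table: sex must be 'M' or 'F'", call. = FALSE)
  if (any(!is.finite(meta$age)) || any(meta$age <= 0))
    stop("subject table: age must be > 0", call. = FALSE)
  if (any(!is.finite(meta$icv)) || any(meta$icv <= 0))
    stop("subject table: icv must be > 0", call. = FALSE)
  invisible(TRUE)
}
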