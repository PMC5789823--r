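#' Extract and characterize all lesions of one subject
#'
#' Runs the full per-subject pipeline: 26-connected component labeling,
#' minimum-size filtering, per-lesion meshing and shape features, ventricle
#' distance, punctuate-deep/non-punctuate classification and (for
#' punctuate-deep lesions) lobe assignment.
#'
#' @param mask binary [volume_grid()] of the WMH segmentation.
#' @param atlas an `atlas_bundle` on the same grid.
#' @param subject_id subject identifier stored in the records.
#' @param icv intracranial volume in ml (for `surface_area_icv`; optional).
#' @param image optional co-registered scalar [volume_grid()] for the
#'   curvature features.
#' @param min_voxels minimum lesion size in voxels (default 5).
#' @param distance_thr_mm,diameter_thr_mm classification thresholds (defaults
#'   10 and 15 mm).
#' @param sigma Gaussian scale in voxels for curvature features.
#' @param step_deg angular grid for the orthogonal diameter.
#' @param features `"all"` for every shape feature, or `"eccentricity"` to
#'   skip the fractal dimension and curvature features (meshing, diameters,
#'   volume and compactness are always computed) -- useful in large
#'   simulation studies.
#' @param dist_map optional precomputed [ventricle_distance_map()] (reuse
#'   across subjects sharing an atlas).
#' @param mesh_all if `FALSE`, lesions within the ventricle-distance
#'   threshold are recorded as non-punctuate without meshing (their class is
#'   already decided by the distance criterion alone); mesh-based feature
#'   columns are `NA` for them. Meant for large simulation studies; the
#'   default meshes every lesion.
#' @param quiet suppress per-stage messages.
#' @return lesion record data frame (one row per retained lesion).
#' @export
extract_subject <- function(mask, atlas, subject_id, icv = NULL, image = NULL,
                            min_voxels = 5, distance_thr_mm = 10,
                            diameter_thr_mm = 15, sigma = 1, step_deg = 1,
                            features = c("all", "eccentricity"),
                            dist_map = NULL, mesh_all = TRUE, quiet = TRUE) {
  features <- match.arg(features)
  stopifnot(inherits(mask, "volume_grid"), inherits(atlas, "atlas_bundle"))
  check_same_grid(mask, atlas$ventricle_mask)
  if (is.null(dist_map)) dist_map <- ventricle_distance_map(atlas)
  lesions <- label_components(mask)
  n_raw <- length(lesions)
  lesions <- filter_small_lesions(lesions, min_voxels = min_voxels,
                                  quiet = quiet)
  if (!quiet)
    message(sprintf("extract_subject[%s]: %d component(s), %d after size filter",
                    subject_id, n_raw, length(lesions)))
  n <- length(lesions)
  if (n == 0) return(empty_lesion_records())

  num <- function() rep(NA_real_, n)
  out <- list(lesion_id = integer(n), n_voxels = integer(n),
              volume_ml = num(), surface_area_mm2 = num(),
              surface_area_icv = num(), eccentricity = num(),
              compactness1 = num(), compactness2 = num(),
              compactness3 = num(), fractal_dimension = num(),
              shape_index = num(), curvedness = num(),
              lesion_class = character(n), lobe = rep(NA_character_, n),
              min_ventricle_distance_mm = num(), max_diameter_mm = num())
  have_icv <- !is.null(icv) && is.finite(icv)
  dmap_data <- dist_map$data
  for (i in seq_len(n)) {
    les <- lesions[[i]]
    out$lesion_id[i] <- les$lesion_id
    out$n_voxels[i] <- les$n_voxels
    dist_mm <- min(dmap_data[les$voxels])
    out$min_ventricle_distance_mm[i] <- dist_mm
    if (!mesh_all && dist_mm <= distance_thr_mm) {
      out$lesion_class[i] <- "non_punctuate"
      next
    }
    mesh <- build_lesion_mesh(les, mask)
    md <- max_diameter(mesh)
    mo <- min_orthogonal_diameter(mesh, md$direction, step_deg = step_deg)
    cf <- compactness_features(mesh)
    out$volume_ml[i] <- cf$volume_mm3 / 1000
    out$surface_area_mm2[i] <- cf$area_mm2
    if (have_icv) out$surface_area_icv[i] <- cf$area_mm2 / icv
    out$eccentricity[i] <- md$length / mo
    out$compactness1[i] <- cf$compactness1
    out$compactness2[i] <- cf$compactness2
    out$compactness3[i] <- cf$compactness3
    out$max_diameter_mm[i] <- md$length
    if (features == "all") {
      out$fractal_dimension[i] <- fractal_dimension(les)$fd
      sc <- shape_index_curvedness(les, mask, image = image, sigma = sigma)
      out$shape_index[i] <- sc$shape_index
      out$curvedness[i] <- sc$curvedness
    }
    cls <- classify_lesion(dist_mm, md$length, distance_thr_mm,
                           diameter_thr_mm)
    out$lesion_class[i] <- cls
    if (cls == "punctuate_deep") out$lobe[i] <- assign_lobe(les, atlas)
  }
  records <- data.frame(subject_id = rep(subject_id, n), out,
                        override_applied = rep(FALSE, n),
                        stringsAsFactors = FALSE)
  records
}

empty_lesion_records <- function() {
  data.frame(subject_id = character(0), lesion_id = integer(0),
             n_voxels = integer(0), volume_ml = numeric(0),
             surface_area_mm2 = numeric(0), surface_area_icv = numeric(0),
             eccentricity = numeric(0), compactness1 = numeric(0),
             compactness2 = numeric(0), compactness3 = numeric(0),
             fractal_dimension = numeric(0), shape_index = numeric(0),
             curvedness = numeric(0), lesion_class = character(0),
             lobe = character(0), min_ventricle_distance_mm = numeric(0),
             max_diameter_mm = numeric(0), override_applied = logical(0),
             stringsAsFactors = FALSE)
}
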