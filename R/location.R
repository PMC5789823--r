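#' Lobe label codes used by the atlas bundle
#'
#' Named integer codes for the lobe label map. The name order (after
#' background) is also the fixed tie-breaking order of [assign_lobe()].
#' @export
lobe_labels <- c(background = 0L, frontal = 1L, parietal = 2L,
                 temporal = 3L, occipital = 4L, basal_ganglia_region = 5L,
                 cerebellum = 6L)

#' Bundle a ventricle mask and a lobe label map
#'
#' Both volumes must share grid geometry with each other (and with the
#' subject masks they will be used on); the ventricle mask must be non-empty.
#'
#' @param ventricle_mask binary [volume_grid()] of the lateral ventricles.
#' @param lobe_labels_vol integer-labelled [volume_grid()] (codes as in
#'   [lobe_labels]).
#' @param labels named integer vector mapping label names to codes.
#' @return an `atlas_bundle`.
#' @export
atlas_bundle <- function(ventricle_mask, lobe_labels_vol,
                         labels = lobe_labels) {
  stopifnot(inherits(ventricle_mask, "volume_grid"),
            inherits(lobe_labels_vol, "volume_grid"))
  check_same_grid(ventricle_mask, lobe_labels_vol)
  if (!ventricle_mask$is_binary)
    stop("atlas_bundle: ventricle mask must be binary", call. = FALSE)
  if (sum(ventricle_mask$data) == 0)
    stop("atlas_bundle: ventricle mask is empty", call. = FALSE)
  present <- unique(as.vector(lobe_labels_vol$data))
  if (!all(present %in% labels))
    stop("atlas_bundle: lobe map contains codes missing from 'labels'",
         call. = FALSE)
  structure(list(ventricle_mask = ventricle_mask,
                 lobe_labels = lobe_labels_vol, labels = labels),
            class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> grid %s, %d ventricle voxels, labels: %s\n",
              paste(dim(x$ventricle_mask$data), collapse = "x"),
              sum(x$ventricle_mask$data),
              paste(names(x$labels), collapse = ", ")))
  invisible(x)
}

#' Euclidean distance map to the ventricles
#'
#' Exact anisotropy-aware Euclidean distance transform: each voxel gets the
#' distance in mm from its center to the nearest ventricle voxel center.
#' Computed once per atlas and reused across subjects.
#'
#' @param atlas an `atlas_bundle`.
#' @return a [volume_grid()] of distances in mm.
#' @export
ventricle_distance_map <- function(atlas) {
  vm <- atlas$ventricle_mask
  d <- cpp_edt(as.integer(vm$data), as.integer(dim(vm$data)), vm$spacing)
  new_volume_grid(d, vm$spacing, vm$affine)
}

#' Minimum lesion-to-ventricle distance
#'
#' The minimum over the lesion's voxels of the distance to the nearest
#' ventricle voxel (whole-lesion reading of "located more than 1 cm from the
#' ventricles"). Zero if the lesion overlaps the ventricle mask.
#'
#' @param lesion a `lesion_voxel_set`.
#' @param atlas an `atlas_bundle`, or a precomputed [ventricle_distance_map()].
#' @return distance in mm (>= 0).
#' @export
ventricle_distance <- function(lesion, atlas) {
  dm <- if (inherits(atlas, "atlas_bundle")) ventricle_distance_map(atlas)
        else atlas
  stopifnot(inherits(dm, "volume_grid"))
  min(dm$data[lesion$voxels])
}

#' Classify a lesion as punctuate-deep or non-punctuate
#'
#' A lesion is punctuate deep exactly when it lies more than
#' `distance_thr_mm` (default 10 mm) from the ventricles AND its maximum
#' diameter is strictly below `diameter_thr_mm` (default 15 mm); everything
#' else (periventricular and confluent lesions) is pooled as non-punctuate.
#' Both inequalities are strict, so a lesion exactly at a threshold is
#' non-punctuate. Vectorized.
#'
#' @param distance_mm minimum ventricle distance(s) in mm.
#' @param max_diameter_mm maximum lesion diameter(s) in mm.
#' @param distance_thr_mm,diameter_thr_mm thresholds in mm.
#' @return character vector: `"punctuate_deep"` or `"non_punctuate"`.
#' @export
classify_lesion <- function(distance_mm, max_diameter_mm,
                            distance_thr_mm = 10, diameter_thr_mm = 15) {
  ifelse(!is.na(distance_mm) & !is.na(max_diameter_mm) &
           distance_mm > distance_thr_mm & max_diameter_mm < diameter_thr_mm,
         "punctuate_deep", "non_punctuate")
}

#' Apply manual classification overrides
#'
#' Mirrors the manual-check step of the automatic classification: listed
#' lesions get their class replaced and `override_applied` set (also when the
#' override equals the current class, recording that the decision was made
#' explicitly). All other fields are untouched.
#'
#' @param records lesion record data frame (columns `subject_id`, `lesion_id`,
#'   `lesion_class`, ...).
#' @param overrides data frame with columns `subject_id`, `lesion_id`,
#'   `lesion_class`.
#' @param quiet suppress the log message.
#' @return the updated records.
#' @export
apply_overrides <- function(records, overrides, quiet = FALSE) {
  if (is.null(overrides) || nrow(overrides) == 0) return(records)
  stopifnot(all(c("subject_id", "lesion_id", "lesion_class") %in%
                  names(overrides)))
  if (!all(overrides$lesion_class %in% c("punctuate_deep", "non_punctuate")))
    stop("apply_overrides: invalid lesion_class in overrides", call. = FALSE)
  rec_key <- paste(records$subject_id, records$lesion_id)
  ov_key <- paste(overrides$subject_id, overrides$lesion_id)
  missing <- setdiff(ov_key, rec_key)
  if (length(missing) > 0)
    stop("apply_overrides: unmatched lesion keys: ",
         paste(missing, collapse = "; "), call. = FALSE)
  if (!"override_applied" %in% names(records))
    records$override_applied <- FALSE
  idx <- match(ov_key, rec_key)
  records$lesion_class[idx] <- overrides$lesion_class
  records$override_applied[idx] <- TRUE
  if (!quiet)
    message(sprintf("apply_overrides: %d override(s) applied", length(idx)))
  records
}

#' Assign a lobe to a punctuate-deep lesion
#'
#' Majority vote of the atlas lobe labels over the lesion's voxels, ignoring
#' background. Ties are broken by the fixed order frontal > parietal >
#' temporal > occipital > basal ganglia region > cerebellum. A lesion lying
#' entirely in background gets the label of the nearest labelled voxel.
#'
#' @param lesion a `lesion_voxel_set`.
#' @param atlas an `atlas_bundle`.
#' @return lobe name (character scalar).
#' @export
assign_lobe <- function(lesion, atlas) {
  stopifnot(inherits(atlas, "atlas_bundle"))
  lab <- atlas$lobe_labels$data
  codes <- lab[lesion$voxels]
  codes <- codes[codes != 0]
  nonbg <- atlas$labels[atlas$labels != 0]
  if (length(nonbg) == 0)
    stop("assign_lobe: atlas has no non-background labels", call. = FALSE)
  if (length(codes) > 0) {
    counts <- vapply(nonbg, function(code) sum(codes == code), integer(1))
    return(names(nonbg)[which.max(counts)])  # which.max: first max = fixed order
  }
  # all-background lesion: expanding search for the nearest labelled voxel
  sp <- atlas$lobe_labels$spacing
  d <- dim(lab)
  cen <- round(colMeans(lesion$voxels))
  for (r_mm in c(5, 10, 20, 40, 80, 160, Inf)) {
    r_vox <- if (is.infinite(r_mm)) d else pmax(1, ceiling(r_mm / sp))
    lo <- pmax(cen - r_vox, 1)
    hi <- pmin(cen + r_vox, d)
    box <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    cand <- which(box != 0, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    gpos <- sweep(cand, 2, lo - 1L, "+")
    best_vox <- NULL
    bestd <- Inf
    for (i in seq_len(nrow(gpos))) {
      di <- min(colSums(((t(lesion$voxels) - gpos[i, ]) * sp)^2))
      if (di < bestd) { bestd <- di; best_vox <- gpos[i, ] }
    }
    return(names(nonbg)[match(lab[matrix(best_vox, 1)], nonbg)])
  }
  stop("assign_lobe: atlas contains no labelled voxels", call. = FALSE)
}

#' Per-voxel mean eccentricity map
#'
#' For every voxel covered by at least one lesion, the eccentricity values of
#' the covering lesions are summed and divided by the covering-lesion count;
#' uncovered voxels are 0. All lesions must live on the shared (atlas) grid.
#'
#' @param lesions list of `lesion_voxel_set` objects on one grid.
#' @param eccentricities numeric vector, one eccentricity per lesion.
#' @param grid the shared [volume_grid()] (geometry template).
#' @return a [volume_grid()] of mean eccentricities, plus attribute
#'   `count` (the per-voxel lesion count array).
#' @export
eccentricity_atlas_map <- function(lesions, eccentricities, grid) {
  stopifnot(inherits(grid, "volume_grid"),
            length(lesions) == length(eccentricities))
  d <- dim(grid$data)
  ssum <- array(0, dim = d)
  cnt <- array(0L, dim = d)
  for (i in seq_along(lesions)) {
    vox <- lesions[[i]]$voxels
    if (any(vox < 1) || any(vox[, 1] > d[1]) || any(vox[, 2] > d[2]) ||
        any(vox[, 3] > d[3]))
      stop("eccentricity_atlas_map: lesion voxels outside the shared grid",
           call. = FALSE)
    ssum[vox] <- ssum[vox] + eccentricities[i]
    cnt[vox] <- cnt[vox] + 1L
  }
  mean_map <- ssum
  mean_map[cnt > 0] <- ssum[cnt > 0] / cnt[cnt > 0]
  out <- volume_grid(mean_map, grid$spacing, grid$affine)
  attr(out, "count") <- cnt
  out
}

#' Read / write an atlas bundle
#'
#' The on-disk form is two NIfTI volumes plus a JSON label-name map.
#'
#' @param dir directory holding (or to hold) `ventricles.nii.gz`,
#'   `lobes.nii.gz` and `labels.json`.
#' @param atlas an `atlas_bundle` (for writing).
#' @return the `atlas_bundle` (read) or `dir` invisibly (write).
#' @export
read_atlas <- function(dir) {
  vm <- read_mask(file.path(dir, "ventricles.nii.gz"))
  lv <- read_volume(file.path(dir, "lobes.nii.gz"))
  lv$data <- array(as.integer(round(lv$data)), dim = dim(lv$data))
  labs <- unlist(jsonlite::read_json(file.path(dir, "labels.json")))
  atlas_bundle(vm, lv, labels = structure(as.integer(labs), names = names(labs)))
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(atlas$ventricle_mask, file.path(dir, "ventricles.nii.gz"))
  write_volume(atlas$lobe_labels, file.path(dir, "lobes.nii.gz"))
  jsonlite::write_json(as.list(atlas$labels), file.path(dir, "labels.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
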