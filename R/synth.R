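# Synthetic phantoms, a toy atlas and two-group cohorts with injected
# effects: all inputs needed to exercise and validate the pipeline with known
# geometric and statistical ground truth, without any patient data.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# voxel-center coordinate vectors in mm (1-based index i -> (i-1) * spacing)
axis_coords <- function(grid_shape, spacing)
  lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1) * spacing[a])

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(qr_dec) %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

#' Generate a binary shape phantom
#'
#' Voxels are included exactly when their center satisfies the analytic
#' inequality of the shape under the given orientation, so each phantom has a
#' known closed-form volume and extent for oracle tests. Shapes: `sphere`
#' (`size_mm` = radius), `ellipsoid` (three semi-axes), `box` (three edge
#' lengths), `rod` (length, radius of a capsule-free cylinder), `blob`
#' (seeded union of spheres around `size_mm[1]` base radius).
#'
#' @param kind shape kind.
#' @param size_mm size parameters in mm (see above).
#' @param grid_shape integer length-3 array shape.
#' @param spacing voxel spacing in mm.
#' @param center_mm shape center in mm (defaults to the grid center).
#' @param orientation 3x3 rotation matrix (default identity).
#' @param seed seed for the `blob` kind.
#' @return a binary [volume_grid()].
#' @export
make_phantom <- function(kind = c("sphere", "ellipsoid", "box", "rod", "blob"),
                         size_mm, grid_shape, spacing = c(1, 1, 1),
                         center_mm = NULL, orientation = NULL, seed = 1) {
  kind <- match.arg(kind)
  grid_shape <- as.integer(grid_shape)
  if (is.null(center_mm)) center_mm <- (grid_shape - 1) * spacing / 2
  if (is.null(orientation)) orientation <- diag(3)
  cc <- axis_coords(grid_shape, spacing)
  # rotated local coordinates p = R^T (x - c), built separably
  n <- prod(grid_shape)
  x <- rep(cc[[1]] - center_mm[1], times = grid_shape[2] * grid_shape[3])
  y <- rep(rep(cc[[2]] - center_mm[2], each = grid_shape[1]),
           times = grid_shape[3])
  z <- rep(cc[[3]] - center_mm[3], each = grid_shape[1] * grid_shape[2])
  rt <- t(orientation)
  p1 <- rt[1, 1] * x + rt[1, 2] * y + rt[1, 3] * z
  p2 <- rt[2, 1] * x + rt[2, 2] * y + rt[2, 3] * z
  p3 <- rt[3, 1] * x + rt[3, 2] * y + rt[3, 3] * z
  inc <- switch(kind,
    sphere = p1^2 + p2^2 + p3^2 <= size_mm[1]^2,
    ellipsoid = (p1 / size_mm[1])^2 + (p2 / size_mm[2])^2 +
      (p3 / size_mm[3])^2 <= 1,
    box = abs(p1) <= size_mm[1] / 2 & abs(p2) <= size_mm[2] / 2 &
      abs(p3) <= size_mm[3] / 2,
    rod = abs(p1) <= size_mm[1] / 2 & p2^2 + p3^2 <= size_mm[2]^2,
    blob = with_seed(seed, {
      k <- 4L
      acc <- rep(FALSE, n)
      for (i in seq_len(k)) {
        off <- stats::runif(3, -0.8, 0.8) * size_mm[1]
        r <- stats::runif(1, 0.6, 1) * size_mm[1]
        acc <- acc | ((p1 - off[1])^2 + (p2 - off[2])^2 +
                        (p3 - off[3])^2 <= r^2)
      }
      acc
    })
  )
  a <- array(as.integer(inc), dim = grid_shape)
  if (sum(a) == 0) stop("make_phantom: phantom contains no voxels",
                        call. = FALSE)
  border <- a
  border[3:(grid_shape[1] - 2), 3:(grid_shape[2] - 2),
         3:(grid_shape[3] - 2)] <- 0L
  if (sum(border) > 0)
    stop("make_phantom: phantom does not fit in the grid with a 2-voxel margin",
         call. = FALSE)
  volume_grid(a, spacing, is_binary = TRUE)
}

#' Generate a toy atlas (ventricles + lobe labels)
#'
#' A simple geometric stand-in for an atlas-space parcellation, synthetic by
#' construction: two paramedian box "ventricles" around the grid center, and
#' lobe labels that partition the remaining volume by fixed planes through the
#' center -- anterior/posterior superior blocks are frontal/parietal,
#' anterior/posterior inferior blocks are temporal/occipital (+y is anterior,
#' +z is superior), with a central basal-ganglia-region box and an
#' inferior-posterior cerebellum block. A 2-voxel background margin rims the
#' grid.
#'
#' @param grid_shape integer length-3, each >= 32.
#' @param spacing voxel spacing in mm.
#' @return an `atlas_bundle`.
#' @export
make_toy_atlas <- function(grid_shape = c(128, 128, 64), spacing = c(1, 1, 3)) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 32))
    stop("make_toy_atlas: grid too small (each dimension must be >= 32)",
         call. = FALSE)
  cc <- axis_coords(grid_shape, spacing)
  cen <- (grid_shape - 1) * spacing / 2
  x <- rep(cc[[1]], times = grid_shape[2] * grid_shape[3]) - cen[1]
  y <- rep(rep(cc[[2]], each = grid_shape[1]), times = grid_shape[3]) - cen[2]
  z <- rep(cc[[3]], each = grid_shape[1] * grid_shape[2]) - cen[3]
  ext <- (grid_shape - 1) * spacing

  vy <- min(30, 0.3 * ext[2])
  vz <- min(12, 0.25 * ext[3])
  vent <- (abs(abs(x) - 9) <= 3) & abs(y) <= vy & abs(z) <= vz

  lab <- integer(length(x))
  lab[y > 0 & z >= 0] <- lobe_labels[["frontal"]]
  lab[y <= 0 & z >= 0] <- lobe_labels[["parietal"]]
  lab[y > 0 & z < 0] <- lobe_labels[["temporal"]]
  lab[y <= 0 & z < 0] <- lobe_labels[["occipital"]]
  lab[abs(x) <= 16 & abs(y) <= 16 & abs(z) <= vz] <-
    lobe_labels[["basal_ganglia_region"]]
  lab[z < -min(45, 0.35 * ext[3]) & y <= -0.2 * ext[2]] <-
    lobe_labels[["cerebellum"]]
  lab[vent] <- 0L

  lab_a <- array(lab, dim = grid_shape)
  vent_a <- array(as.integer(vent), dim = grid_shape)
  # 2-voxel background margin
  margin <- array(TRUE, dim = grid_shape)
  margin[3:(grid_shape[1] - 2), 3:(grid_shape[2] - 2),
         3:(grid_shape[3] - 2)] <- FALSE
  lab_a[margin] <- 0L
  vent_a[margin] <- 0L
  atlas_bundle(volume_grid(vent_a, spacing, is_binary = TRUE),
               volume_grid(lab_a, spacing))
}

#' Cohort generator specification
#'
#' Defaults mirror the thick-slice FLAIR regime (128 x 128 x 64 grid at
#' 1 x 1 x 3 mm) and the direction of the group findings the generator is
#' meant to emulate: a right-skewed (lognormal) elongation distribution for
#' punctuate-deep lesions, shifted additively on the log scale for patients,
#' and a larger non-punctuate lesion count in patients (rate ratio). Null
#' cohorts are obtained with `ecc_shift = 0` and `count_ratio = 1`.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param punct_rate Poisson mean of punctuate-deep lesions per subject.
#' @param nonpunct_rate Poisson mean of non-punctuate lesions per control.
#' @param ecc_shift additive patient shift of log-elongation.
#' @param count_ratio patient/control rate ratio for non-punctuate counts.
#' @param elong_meanlog,elong_sdlog lognormal parameters of lesion elongation.
#' @param grid_shape,spacing grid geometry.
#' @param age_mean,age_sd,age_range,male_prob,icv_mean,icv_sd demographics.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 20, seed = 1, punct_rate = 12,
                        nonpunct_rate = 6, ecc_shift = 0.4,
                        count_ratio = 1.5, elong_meanlog = log(1.75),
                        elong_sdlog = 0.3, grid_shape = c(128, 128, 64),
                        spacing = c(1, 1, 3), age_mean = 71, age_sd = 4.5,
                        age_range = c(65, 80), male_prob = 0.58,
                        icv_mean = 1450, icv_sd = 120) {
  if (n_per_group < 2) stop("cohort_spec: n_per_group must be >= 2",
                            call. = FALSE)
  if (punct_rate <= 0 || nonpunct_rate <= 0 || count_ratio <= 0)
    stop("cohort_spec: rates must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

# rasterize a rotated ellipsoid into voxel rows of the grid
rasterize_ellipsoid <- function(center_mm, semi_mm, rot, grid_shape, spacing) {
  reach <- max(semi_mm)
  lo <- pmax(floor((center_mm - reach) / spacing) + 1L, 1L)
  hi <- pmin(ceiling((center_mm + reach) / spacing) + 1L, grid_shape)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- (ii - 1) * spacing[1] - center_mm[1]
  ys <- (jj - 1) * spacing[2] - center_mm[2]
  zs <- (kk - 1) * spacing[3] - center_mm[3]
  x <- rep(xs, times = length(ys) * length(zs))
  y <- rep(rep(ys, each = length(xs)), times = length(zs))
  z <- rep(zs, each = length(xs) * length(ys))
  rt <- t(rot)
  q <- ((rt[1, 1] * x + rt[1, 2] * y + rt[1, 3] * z) / semi_mm[1])^2 +
       ((rt[2, 1] * x + rt[2, 2] * y + rt[2, 3] * z) / semi_mm[2])^2 +
       ((rt[3, 1] * x + rt[3, 2] * y + rt[3, 3] * z) / semi_mm[3])^2
  keep <- which(q <= 1)
  cbind(rep(ii, times = length(ys) * length(zs))[keep],
        rep(rep(jj, each = length(xs)), times = length(zs))[keep],
        rep(kk, each = length(xs) * length(ys))[keep])
}

#' Generate a synthetic two-group cohort
#'
#' For each subject, punctuate-deep candidates are random-orientation
#' ellipsoids (elongation lognormal, patients shifted by `ecc_shift` on the
#' log scale) placed strictly beyond the ventricle-distance criterion with a
#' safety margin and with maximum extent well below the diameter criterion,
#' so the intended class is guaranteed by construction; non-punctuate lesions
#' are larger sphere-union blobs abutting the ventricles, with
#' group-dependent Poisson counts. Punctuate centers are kept mutually
#' separated so punctuate lesions never merge; blobs may merge with each
#' other (the union keeps a single identity and the per-lesion ground truth
#' of merged units is dropped from count recovery). Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param keep_masks store the per-subject mask volumes in the result
#'   (default `TRUE`; disable for large simulation studies).
#' @param per_subject optional `function(mask, meta_row, atlas, dist_map)`
#'   applied to each subject's mask right after generation; its results are
#'   collected in `$per_subject` (used to stream extraction without holding
#'   all masks in memory).
#' @return list with `masks` (named list of binary [volume_grid()], if kept),
#'   `atlas`, `meta` (subject table), `truth` (`lesions` and per-subject
#'   `counts` data frames), `per_subject`, `spec`.
#' @export
make_cohort <- function(spec, keep_masks = TRUE, per_subject = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    atlas <- make_toy_atlas(spec$grid_shape, spec$spacing)
    dmap <- ventricle_distance_map(atlas)
    gs <- spec$grid_shape
    sp <- spec$spacing

    # eligible centers, precomputed once:
    # punctuate: > 23 mm from ventricles (=> every lesion voxel > 16 mm, well
    # beyond the 10 mm rule), inside one of the four lobes, away from borders
    lobes4 <- lobe_labels[c("frontal", "parietal", "temporal", "occipital")]
    border_ok <- array(FALSE, gs)
    mar <- pmax(ceiling(8.5 / sp) + 2L, 3L)
    border_ok[(mar[1] + 1):(gs[1] - mar[1]), (mar[2] + 1):(gs[2] - mar[2]),
              (mar[3] + 1):(gs[3] - mar[3])] <- TRUE
    elig_p <- which(dmap$data > 23 & border_ok &
                      array(atlas$lobe_labels$data %in% lobes4, gs))
    # non-punctuate: just outside the ventricle wall
    mar2 <- pmax(ceiling(13 / sp) + 2L, 3L)
    border_ok2 <- array(FALSE, gs)
    border_ok2[(mar2[1] + 1):(gs[1] - mar2[1]),
               (mar2[2] + 1):(gs[2] - mar2[2]),
               (mar2[3] + 1):(gs[3] - mar2[3])] <- TRUE
    elig_np <- which(dmap$data > 0 & dmap$data <= 4 & border_ok2)
    if (length(elig_p) < 100 || length(elig_np) < 20)
      stop("make_cohort: unsatisfiable placement; use a larger grid",
           call. = FALSE)

    n_tot <- 2L * spec$n_per_group
    groups <- rep(c("patient", "control"), each = spec$n_per_group)
    meta <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n_tot)),
      group = groups,
      age = round(pmin(pmax(stats::rnorm(n_tot, spec$age_mean, spec$age_sd),
                            spec$age_range[1]), spec$age_range[2]), 1),
      sex = ifelse(stats::runif(n_tot) < spec$male_prob, "M", "F"),
      icv = round(stats::rnorm(n_tot, spec$icv_mean, spec$icv_sd), 1),
      stringsAsFactors = FALSE
    )

    masks <- if (keep_masks) vector("list", n_tot) else NULL
    results <- if (!is.null(per_subject)) vector("list", n_tot) else NULL
    lesion_truth <- list()
    count_truth <- list()

    for (s in seq_len(n_tot)) {
      a <- array(0L, gs)
      is_patient <- groups[s] == "patient"
      n_p <- stats::rpois(1, spec$punct_rate)
      n_np <- stats::rpois(1, spec$nonpunct_rate *
                             if (is_patient) spec$count_ratio else 1)
      centers <- matrix(numeric(0), 0, 3)
      placed_p <- 0L
      for (l in seq_len(n_p)) {
        ok <- FALSE
        for (try in 1:200) {
          cand_idx <- elig_p[sample.int(length(elig_p), 1)]
          cand <- (arrayInd(cand_idx, gs) - 1) * sp
          if (nrow(centers) == 0 ||
              min(sqrt(rowSums(sweep(centers, 2, as.numeric(cand))^2))) >= 16) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("make_cohort: unsatisfiable punctuate placement; ",
                      "use a larger grid", call. = FALSE)
        centers <- rbind(centers, as.numeric(cand))
        elong <- max(1, exp(stats::rnorm(1, spec$elong_meanlog +
                                           if (is_patient) spec$ecc_shift else 0,
                                         spec$elong_sdlog)))
        # keep the major diameter clear of the 15 mm rule even after the
        # half-voxel inflation of voxelized surfaces (up to 1.5 mm per end on
        # 3 mm slices); shrink the minor axis rather than clamping the
        # elongation so the injected shape effect survives intact
        minor <- stats::runif(1, 4.5, 6.5)
        if (minor * elong > 11.5) minor <- max(11.5 / elong, 3.2)
        major <- min(minor * elong, 11.5)
        rot <- random_rotation()
        vox <- rasterize_ellipsoid(as.numeric(cand),
                                   c(major, minor, minor) / 2, rot, gs, sp)
        a[vox] <- 1L
        placed_p <- placed_p + 1L
        lesion_truth[[length(lesion_truth) + 1]] <- data.frame(
          subject_id = meta$subject_id[s], kind = "punctuate_deep",
          center_x_mm = cand[1], center_y_mm = cand[2], center_z_mm = cand[3],
          elongation = major / minor, major_mm = major, minor_mm = minor)
      }
      for (l in seq_len(n_np)) {
        cand_idx <- elig_np[sample.int(length(elig_np), 1)]
        cand <- as.numeric((arrayInd(cand_idx, gs) - 1) * sp)
        for (b in 1:3) {
          off <- stats::runif(3, -3, 3)
          r <- stats::runif(1, 3, 5)
          vox <- rasterize_ellipsoid(cand + off, rep(r, 3), diag(3), gs, sp)
          a[vox] <- 1L
        }
        lesion_truth[[length(lesion_truth) + 1]] <- data.frame(
          subject_id = meta$subject_id[s], kind = "non_punctuate",
          center_x_mm = cand[1], center_y_mm = cand[2], center_z_mm = cand[3],
          elongation = NA_real_, major_mm = NA_real_, minor_mm = NA_real_)
      }
      count_truth[[s]] <- data.frame(
        subject_id = meta$subject_id[s], group = groups[s],
        n_punctuate = placed_p, n_non_punctuate = n_np)
      mask <- new_volume_grid(a, sp, atlas$ventricle_mask$affine,
                              is_binary = TRUE)
      if (keep_masks) masks[[s]] <- mask
      if (!is.null(per_subject))
        results[[s]] <- per_subject(mask, meta[s, ], atlas, dmap)
    }
    if (keep_masks) names(masks) <- meta$subject_id
    if (!is.null(results)) names(results) <- meta$subject_id
    list(masks = masks, atlas = atlas, meta = meta,
         truth = list(lesions = do.call(rbind, lesion_truth),
                      counts = do.call(rbind, count_truth)),
         per_subject = results, spec = spec)
  })
}
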