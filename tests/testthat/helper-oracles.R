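# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive (enumeration / flood fill / dense grids) so it cannot
# share failure modes with the implementation it checks.

# digital ball on an isotropic grid, returned as a volume_grid
ball_phantom <- function(r_vox, spacing = c(1, 1, 1), odd_grid = TRUE) {
  n <- 2 * ceiling(r_vox) + if (odd_grid) 7L else 6L
  make_phantom("sphere", r_vox * spacing[1], grid_shape = rep(n, 3),
               spacing = spacing)
}

first_lesion <- function(vol) label_components(vol)[[1]]

# voxel set object from an index matrix
voxset <- function(vox, id = 1L) {
  structure(list(lesion_id = id, voxels = vox, n_voxels = nrow(vox)),
            class = "lesion_voxel_set")
}

mask_from_voxels <- function(vox, dims, spacing = c(1, 1, 1)) {
  a <- array(0L, dims)
  a[vox] <- 1L
  volume_grid(a, spacing, is_binary = TRUE)
}

# brute-force 26-connected flood fill (pure R)
flood_fill_26 <- function(a) {
  d <- dim(a)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx <- which(a != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (lab[matrix(idx[r, ], 1)] != 0L) next
    nxt <- nxt + 1L
    queue <- list(idx[r, ])
    lab[matrix(idx[r, ], 1)] <- nxt
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        m <- matrix(nb, 1)
        if (a[m] != 0 && lab[m] == 0L) {
          lab[m] <- nxt
          queue <- c(queue, list(nb))
        }
      }
    }
  }
  lab
}

# brute-force nearest-target-voxel distance in mm
brute_edt <- function(target, spacing) {
  d <- dim(target)
  tv <- which(target != 0, arr.ind = TRUE)
  out <- array(Inf, d)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (r in seq_len(nrow(all_idx))) {
    dv <- sweep(tv, 2, all_idx[r, ])
    dv <- sweep(dv, 2, spacing, "*")
    out[matrix(all_idx[r, ], 1)] <- sqrt(min(rowSums(dv^2)))
  }
  out
}

# brute-force exhaustive vertex-pair diameter
brute_diameter <- function(v) {
  best <- 0
  for (i in seq_len(nrow(v) - 1))
    for (j in (i + 1):nrow(v)) {
      d <- sqrt(sum((v[i, ] - v[j, ])^2))
      if (d > best) best <- d
    }
  best
}

# rotation matrix around a unit axis by angle (Rodrigues)
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * kx + (1 - cos(angle)) * kx %*% kx
}

rotate_mesh <- function(mesh, rot) {
  mesh$vertices <- mesh$vertices %*% t(rot)
  mesh
}

scale_mesh <- function(mesh, s) {
  mesh$vertices <- mesh$vertices * s
  mesh
}

# deterministic 'random-looking' rotation for parameterised cases
random_rotation_test <- function(k = 1) {
  rotation_about(c(sin(k), cos(2 * k) + 1.3, 0.4 * k + 0.1), 0.9 + 0.37 * k)
}

# float (non-binary) copy of a mask, usable as a scalar image
new_img <- function(mask) {
  volume_grid(array(as.numeric(mask$data), dim = dim(mask$data)),
              mask$spacing, mask$affine)
}

# run extraction on a generated cohort and pair measured eccentricities with
# the generator's intended elongations (matched through each intended lesion's
# center voxel)
measured_vs_intended <- function(spec) {
  co <- make_cohort(spec)
  dmap <- ventricle_distance_map(co$atlas)
  measured <- intended <- numeric(0)
  recovered <- total <- 0
  for (s in seq_len(nrow(co$meta))) {
    id <- co$meta$subject_id[s]
    rec <- extract_subject(co$masks[[id]], co$atlas, id,
                           features = "eccentricity", dist_map = dmap)
    tr <- co$truth$lesions[co$truth$lesions$subject_id == id &
                             co$truth$lesions$kind == "punctuate_deep", ]
    lesions <- filter_small_lesions(label_components(co$masks[[id]]),
                                    quiet = TRUE)
    sp <- co$masks[[id]]$spacing
    total <- total + nrow(tr)
    for (r in seq_len(nrow(tr))) {
      cvox <- round(c(tr$center_x_mm[r] / sp[1], tr$center_y_mm[r] / sp[2],
                      tr$center_z_mm[r] / sp[3])) + 1
      hit <- which(vapply(lesions, function(l)
        any(l$voxels[, 1] == cvox[1] & l$voxels[, 2] == cvox[2] &
              l$voxels[, 3] == cvox[3]), logical(1)))
      if (length(hit) == 1) {
        row <- rec[rec$lesion_id == lesions[[hit]]$lesion_id, ]
        if (nrow(row) == 1) {
          if (row$lesion_class == "punctuate_deep") recovered <- recovered + 1
          measured <- c(measured, row$eccentricity)
          intended <- c(intended, tr$elongation[r])
        }
      }
    }
  }
  list(measured = measured, intended = intended, recovered = recovered,
       total = total, cohort = co)
}

# small synthetic cohort demographics table for regression tests
fake_cohort <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("patient", "control"), length.out = n),
    age = round(runif(n, 65, 80), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    icv = rnorm(n, 1450, 100),
    stringsAsFactors = FALSE
  )
}
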