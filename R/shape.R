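#' Largest 3D lesion diameter (mesh caliper)
#'
#' Maximum pairwise Euclidean distance between mesh vertices, found by
#' exhaustive search; ties are broken by the lexicographically smallest vertex
#' index pair, and the direction points from the lower- to the higher-index
#' vertex of that pair. For very large meshes the search is restricted to the
#' extreme vertices over a dense direction grid (a standard reduction: the
#' diameter is attained at extreme points), which keeps the cost bounded while
#' leaving small meshes exact.
#'
#' @param mesh a `lesion_mesh` with at least 4 vertices.
#' @param exact_max_vertices exhaustive search is used up to this vertex
#'   count (default 2000); beyond it the extreme-point reduction applies.
#' @return list with `length` (mm), `direction` (unit vector) and `pair`
#'   (vertex indices).
#' @export
max_diameter <- function(mesh, exact_max_vertices = 2000) {
  v <- mesh$vertices
  if (nrow(v) < 4) stop("max_diameter: mesh needs >= 4 vertices", call. = FALSE)
  if (nrow(v) > exact_max_vertices) {
    dirs <- fibonacci_directions(1000)
    tp <- t(v %*% t(dirs))
    idx <- sort(unique(c(max.col(tp, ties.method = "first"),
                         max.col(-tp, ties.method = "first"))))
    res <- cpp_max_pair(v[idx, , drop = FALSE])
    pair <- c(idx[res$i], idx[res$j])
  } else {
    res <- cpp_max_pair(v)
    pair <- c(res$i, res$j)
  }
  d <- v[pair[2], ] - v[pair[1], ]
  list(length = res$length, direction = d / sqrt(sum(d^2)), pair = pair)
}

# quasi-uniform unit directions (spherical Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Smallest lesion diameter orthogonal to an axis
#'
#' Vertices are projected onto the plane orthogonal to `axis`; the extent
#' (max minus min of scalar projections) is evaluated on a grid of in-plane
#' directions and the minimum is returned. This is the rotation-invariant
#' "minimal orthogonal width" reading of the smallest diameter orthogonal to
#' the maximum diameter.
#'
#' @param mesh a `lesion_mesh`.
#' @param axis unit vector (the maximum-diameter direction).
#' @param step_deg angular grid step in degrees (default 1).
#' @return minimal orthogonal extent in mm.
#' @export
min_orthogonal_diameter <- function(mesh, axis, step_deg = 1) {
  v <- mesh$vertices
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal in-plane basis
  seed <- diag(3)[, which.min(abs(axis))]
  u <- seed - sum(seed * axis) * axis
  u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  p <- v %*% cbind(u, w)
  if (max(abs(p - matrix(colMeans(p), nrow(p), 2, byrow = TRUE))) < 1e-9)
    stop("min_orthogonal_diameter: degenerate lesion (vertices collinear with axis)",
         call. = FALSE)
  theta <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  proj <- p %*% rbind(cos(theta), sin(theta))
  tp <- t(proj)
  k <- seq_along(theta)
  extents <- tp[cbind(k, max.col(tp, ties.method = "first"))] -
             tp[cbind(k, max.col(-tp, ties.method = "first"))]
  min(extents)
}

#' Lesion eccentricity
#'
#' Ratio of the largest 3D diameter to the smallest diameter orthogonal to it;
#' 1 for a sphere, large values for elongated (ellipsoidal) lesions. The ratio
#' is translation-, scale- and rotation-invariant.
#'
#' @param mesh a `lesion_mesh`.
#' @param step_deg angular grid for the orthogonal diameter (default 1
#'   degree).
#' @return eccentricity (>= 1 up to discretization).
#' @export
eccentricity <- function(mesh, step_deg = 1) {
  md <- max_diameter(mesh)
  mo <- min_orthogonal_diameter(mesh, md$direction, step_deg = step_deg)
  md$length / mo
}

#' Compactness measures of a lesion
#'
#' Three scale-related compactness ratios:
#' \itemize{
#' \item `compactness1 = volume^2 / area^3` (volume in mm^3, area in mm^2);
#'   bounded above by the isoperimetric constant `1/(36*pi)` attained by a
#'   sphere;
#' \item `compactness2 = volume / (dim_x * dim_y * dim_z)` with the bounding
#'   box extents along the image axes; 1 for an axis-aligned box;
#' \item `compactness3 = volume / dim_max^3` with `dim_max` the largest of the
#'   three axis extents.
#' }
#'
#' @param mesh a `lesion_mesh`.
#' @return list with `compactness1..3`, the axis extents `dims_mm` and the
#'   mesh `volume_mm3` and `area_mm2`.
#' @export
compactness_features <- function(mesh) {
  vol <- mesh_volume(mesh, check = FALSE) * 1000  # mm^3
  area <- mesh_surface_area(mesh)
  dims <- apply(mesh$vertices, 2, max) - apply(mesh$vertices, 2, min)
  if (any(dims <= 0))
    stop("compactness_features: zero bounding-box extent", call. = FALSE)
  list(compactness1 = vol^2 / area^3,
       compactness2 = vol / prod(dims),
       compactness3 = vol / max(dims)^3,
       dims_mm = dims, volume_mm3 = vol, area_mm2 = area)
}

#' Box-counting fractal dimension of the lesion boundary
#'
#' Boundary voxels (lesion voxels with at least one 6-connected background
#' neighbour) are covered by grids of cubic boxes of side 1, 2, 4, ... voxels
#' strictly below half the maximum bounding-box extent (coarser boxes carry no
#' information: essentially every box is hit), anchored at the bounding-box
#' corner. The dimension is the least-squares slope of `log N(s)` versus
#' `log(1/s)`. With fewer than 3 usable scales the value is flagged
#' undefined rather than raising an error.
#'
#' @param lesion a `lesion_voxel_set` (>= 5 voxels for a meaningful value).
#' @return list with `fd` (NA when undefined), `defined`, `n_scales`, and the
#'   per-scale counts.
#' @export
fractal_dimension <- function(lesion) {
  vox <- lesion$voxels
  lo <- c(min(vox[, 1]), min(vox[, 2]), min(vox[, 3]))
  hi <- c(max(vox[, 1]), max(vox[, 2]), max(vox[, 3]))
  bvox <- sweep(lesion_boundary_voxels(lesion), 2, lo, "-")  # 0-based in bbox
  max_ext <- max(hi - lo + 1L)
  scales <- c()
  s <- 1L
  while (s < max_ext / 2) {  # boxes stay small against the lesion extent
    scales <- c(scales, s)
    s <- s * 2L
  }
  if (length(scales) < 3)
    return(list(fd = NA_real_, defined = FALSE, n_scales = length(scales),
                scales = scales, counts = integer(0)))
  counts <- vapply(scales, function(s) {
    boxes <- bvox %/% s
    nrow(unique(boxes))
  }, integer(1))
  fit <- stats::lm.fit(cbind(1, log(1 / scales)), log(counts))
  list(fd = unname(fit$coefficients[2]), defined = TRUE,
       n_scales = length(scales), scales = scales, counts = counts)
}

#' Boundary voxels of a lesion
#'
#' The lesion voxels with at least one 6-connected (face-adjacent) background
#' neighbour: the digital surface used by the box-counting fractal dimension
#' and convenient for evaluating curvature features at the lesion surface.
#'
#' @param lesion a `lesion_voxel_set`.
#' @return matrix of 1-based voxel indices (subset of `lesion$voxels`).
#' @export
lesion_boundary_voxels <- function(lesion) {
  vox <- lesion$voxels
  lo <- c(min(vox[, 1]), min(vox[, 2]), min(vox[, 3]))
  hi <- c(max(vox[, 1]), max(vox[, 2]), max(vox[, 3]))
  sub <- array(FALSE, dim = hi - lo + 3L)
  loc <- cbind(vox[, 1] - lo[1] + 2L, vox[, 2] - lo[2] + 2L,
               vox[, 3] - lo[3] + 2L)
  sub[loc] <- TRUE
  nb <- !sub[cbind(loc[, 1] - 1L, loc[, 2], loc[, 3])] |
        !sub[cbind(loc[, 1] + 1L, loc[, 2], loc[, 3])] |
        !sub[cbind(loc[, 1], loc[, 2] - 1L, loc[, 3])] |
        !sub[cbind(loc[, 1], loc[, 2] + 1L, loc[, 3])] |
        !sub[cbind(loc[, 1], loc[, 2], loc[, 3] - 1L)] |
        !sub[cbind(loc[, 1], loc[, 2], loc[, 3] + 1L)]
  vox[nb, , drop = FALSE]
}
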