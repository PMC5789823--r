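# Separable Gaussian-derivative filtering and isophote principal curvatures.
#
# Derivatives are taken in index space (sigma in voxels), so curvature units
# are 1/voxel; this mirrors the "scale sigma = 1 voxel" convention and means
# anisotropic spacing is deliberately not corrected here.

# correlate `a` along `axis` with kernel `k` (zero padding)
conv_axis <- function(a, k, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  n <- d[1]
  m <- prod(d[-1])
  dim(ap) <- c(n, m)
  r <- (length(k) - 1L) %/% 2L
  pad <- matrix(0, r, m)
  p <- rbind(pad, ap, pad)
  out <- matrix(0, n, m)
  for (t in seq_along(k))
    out <- out + k[t] * p[t:(t + n - 1L), , drop = FALSE]
  dim(out) <- d
  aperm(out, order(perm))
}

gaussian_kernels <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g0 <- exp(-x^2 / (2 * sigma^2))
  g0 <- g0 / sum(g0)
  list(g0 = g0,
       g1 = x / sigma^2 * g0,                     # first derivative (correlation form)
       g2 = (x^2 / sigma^4 - 1 / sigma^2) * g0)   # second derivative
}

# Gaussian-derivative gradient and Hessian of a 3D array, evaluated at
# 1-based voxel rows `at` (n x 3). Returns a list of per-voxel vectors.
derivative_stack <- function(a, at, sigma) {
  k <- gaussian_kernels(sigma)
  dv <- function(kx, ky, kz)
    conv_axis(conv_axis(conv_axis(a, kx, 1), ky, 2), kz, 3)[at]
  list(gx = dv(k$g1, k$g0, k$g0), gy = dv(k$g0, k$g1, k$g0),
       gz = dv(k$g0, k$g0, k$g1),
       hxx = dv(k$g2, k$g0, k$g0), hyy = dv(k$g0, k$g2, k$g0),
       hzz = dv(k$g0, k$g0, k$g2),
       hxy = dv(k$g1, k$g1, k$g0), hxz = dv(k$g1, k$g0, k$g1),
       hyz = dv(k$g0, k$g1, k$g1))
}

# principal isophote curvatures at given voxels of array `a`
curvature_field <- function(a, at, sigma = 1, grad_tol = 1e-8) {
  s <- derivative_stack(a, at, sigma)
  g2 <- s$gx^2 + s$gy^2 + s$gz^2
  gn <- sqrt(g2)
  tr_h <- s$hxx + s$hyy + s$hzz
  ghg <- s$gx^2 * s$hxx + s$gy^2 * s$hyy + s$gz^2 * s$hzz +
    2 * (s$gx * s$gy * s$hxy + s$gx * s$gz * s$hxz + s$gy * s$gz * s$hyz)
  a11 <- s$hyy * s$hzz - s$hyz^2
  a22 <- s$hxx * s$hzz - s$hxz^2
  a33 <- s$hxx * s$hyy - s$hxy^2
  a12 <- s$hxz * s$hyz - s$hxy * s$hzz
  a13 <- s$hxy * s$hyz - s$hyy * s$hxz
  a23 <- s$hxy * s$hxz - s$hxx * s$hyz
  gag <- s$gx^2 * a11 + s$gy^2 * a22 + s$gz^2 * a33 +
    2 * (s$gx * s$gy * a12 + s$gx * s$gz * a13 + s$gy * s$gz * a23)
  km <- (ghg - g2 * tr_h) / (2 * gn^3)   # mean curvature
  kg <- gag / g2^2                        # Gaussian curvature
  disc <- sqrt(pmax(km^2 - kg, 0))
  k1 <- km + disc
  k2 <- km - disc
  undef <- gn < grad_tol
  k1[undef] <- NA_real_
  k2[undef] <- NA_real_
  list(k1 = k1, k2 = k2, defined = !undef)
}

#' Principal isophote curvatures at a voxel
#'
#' Curvatures of the image iso-surface through a voxel, from the gradient and
#' Hessian of the image blurred with a Gaussian of scale `sigma` voxels
#' (standard implicit-surface formulas for mean and Gaussian curvature;
#' `k1 >= k2`). Units are 1/voxel because derivatives are taken in index
#' space. A voxel with (near-)zero gradient has no defined iso-surface and is
#' flagged undefined (`NA` curvatures).
#'
#' @param image a scalar [volume_grid()].
#' @param at 1-based voxel index, length 3.
#' @param sigma Gaussian scale in voxels (default 1).
#' @return list with `k1`, `k2` (`k1 >= k2`, `NA` when undefined) and
#'   `defined`.
#' @export
principal_curvatures <- function(image, at, sigma = 1) {
  stopifnot(inherits(image, "volume_grid"), length(at) == 3)
  d <- dim(image$data)
  if (any(at < 1) || any(at > d))
    stop("principal_curvatures: voxel outside image", call. = FALSE)
  r <- max(1L, ceiling(4 * sigma)) + 1L
  lo <- pmax(at - r, 1L)
  hi <- pmin(at + r, d)
  sub <- image$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cf <- curvature_field(sub, matrix(at - lo + 1L, 1), sigma)
  list(k1 = cf$k1[1], k2 = cf$k2[1], defined = cf$defined[1])
}

#' Median shape index and curvedness of a lesion
#'
#' Shape index `(2/pi) * atan((k1 + k2) / (k1 - k2))` (local cup/saddle/cap
#' continuum in `[-1, 1]`) and curvedness `sqrt(k1^2 + k2^2)` (bending
#' magnitude, 1/voxel) are evaluated at every lesion voxel with defined
#' curvatures and summarized by their medians. At umbilic points
#' (`k1 == k2`) the shape index is the analytic limit `sign(k1)`, or 0 when
#' both curvatures vanish.
#'
#' By default the curvatures are computed on the lesion's own binary mask
#' blurred at scale `sigma`, which keeps the pipeline self-contained; a
#' co-registered scalar image on the same grid can be supplied instead.
#'
#' @param lesion a `lesion_voxel_set`.
#' @param grid the [volume_grid()] the voxels refer to.
#' @param image optional scalar [volume_grid()] to use instead of the binary
#'   mask.
#' @param sigma Gaussian scale in voxels (default 1).
#' @param at optional voxel subset (matrix of 1-based indices, e.g.
#'   [lesion_boundary_voxels()]) to evaluate instead of all lesion voxels.
#' @return list with `shape_index`, `curvedness` (medians; `NA` when no voxel
#'   has defined curvature), `n_defined`, and per-voxel values.
#' @export
shape_index_curvedness <- function(lesion, grid, image = NULL, sigma = 1,
                                   at = NULL) {
  vox <- lesion$voxels
  eval_vox <- if (is.null(at)) vox else at
  r <- max(1L, ceiling(4 * sigma)) + 1L
  lo <- pmax(c(min(vox[, 1]), min(vox[, 2]), min(vox[, 3])) - r, 1L)
  if (is.null(image)) {
    hi <- c(max(vox[, 1]), max(vox[, 2]), max(vox[, 3])) + r
    sub <- array(0, dim = hi - lo + 1L)
    sub[cbind(vox[, 1] - lo[1] + 1L, vox[, 2] - lo[2] + 1L,
              vox[, 3] - lo[3] + 1L)] <- 1
  } else {
    stopifnot(inherits(image, "volume_grid"))
    check_same_grid(grid, image)
    d <- dim(image$data)
    hi <- pmin(c(max(vox[, 1]), max(vox[, 2]), max(vox[, 3])) + r, d)
    sub <- image$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  }
  pos <- cbind(eval_vox[, 1] - lo[1] + 1L, eval_vox[, 2] - lo[2] + 1L,
               eval_vox[, 3] - lo[3] + 1L)
  cf <- curvature_field(sub, pos, sigma)
  k1 <- cf$k1[cf$defined]
  k2 <- cf$k2[cf$defined]
  if (length(k1) == 0)
    return(list(shape_index = NA_real_, curvedness = NA_real_,
                n_defined = 0L, si = numeric(0), cv = numeric(0)))
  si <- numeric(length(k1))
  eq <- (k1 - k2) < 1e-12
  si[!eq] <- (2 / pi) * atan((k1[!eq] + k2[!eq]) / (k1[!eq] - k2[!eq]))
  si[eq] <- sign(k1[eq])
  si[eq & abs(k1) < 1e-8 & abs(k2) < 1e-8] <- 0
  cv <- sqrt(k1^2 + k2^2)
  list(shape_index = stats::median(si), curvedness = stats::median(cv),
       n_defined = length(k1), si = si, cv = cv)
}
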