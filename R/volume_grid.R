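#' 3D image volume with grid metadata
#'
#' A `volume_grid` bundles a 3D array with its voxel spacing in mm and a 4x4
#' grid-to-world affine. Voxel indices are 1-based in R; world coordinates are
#' voxel-center positions under the affine (voxel `(i, j, k)` maps to
#' `affine %*% c(i - 1, j - 1, k - 1, 1)`). Binary volumes (masks) carry
#' `is_binary = TRUE` and contain only 0 and 1.
#'
#' @param data numeric, integer or logical 3D array.
#' @param spacing length-3 positive numeric, voxel size in mm per axis.
#' @param affine optional 4x4 grid-to-world matrix; defaults to
#'   `diag(c(spacing, 1))`.
#' @param is_binary logical; if `TRUE` the data must contain only 0 and 1.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing, affine = NULL, is_binary = FALSE) {
  if (length(dim(data)) != 3L)
    stop("volume_grid: 'data' must be a 3D array, got ",
         length(dim(data)), " dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume_grid: 'spacing' must be 3 strictly positive values",
         call. = FALSE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("volume_grid: 'affine' must be a 4x4 matrix", call. = FALSE)
  if (is.logical(data)) {
    data <- array(as.integer(data), dim = dim(data))
    is_binary <- TRUE
  }
  if (is_binary) {
    vals <- unique(as.vector(data))
    if (!all(vals %in% c(0, 1)))
      stop("volume_grid: binary volume contains values other than 0/1",
           call. = FALSE)
    data <- array(as.integer(data), dim = dim(data))
  }
  structure(
    list(data = data, spacing = spacing, affine = affine,
         is_binary = isTRUE(is_binary)),
    class = "volume_grid"
  )
}

# internal fast constructor: caller guarantees the invariants
new_volume_grid <- function(data, spacing, affine = NULL, is_binary = FALSE) {
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = spacing, affine = affine,
                 is_binary = is_binary), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, spacing %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = " x "),
              if (x$is_binary) sprintf(", binary (%d foreground)",
                                       sum(x$data != 0)) else ""))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Check that two volumes share grid geometry
#'
#' Compares shape exactly and spacing/affine within a tolerance; used to
#' enforce that all volumes of one subject (mask, image, atlas) live on the
#' same grid.
#'
#' @param a,b `volume_grid` objects.
#' @param tol numeric tolerance on spacing and affine entries.
#' @return `TRUE` invisibly, or an error describing the mismatch.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
  if (!all(dim(a$data) == dim(b$data)))
    stop("grid mismatch: shapes ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"), call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > tol)
    stop("grid mismatch: spacings differ beyond tolerance", call. = FALSE)
  if (max(abs(a$affine - b$affine)) > tol)
    stop("grid mismatch: affines differ beyond tolerance", call. = FALSE)
  invisible(TRUE)
}

#' Read a 3D scalar volume from NIfTI
#'
#' Reads a NIfTI-1 file into a [volume_grid()]. 4D inputs with a singleton
#' last dimension are squeezed; other non-3D inputs are rejected. Voxel
#' spacing is taken from the header `pixdim`, the affine from the NIfTI
#' xform.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), dim = d)
  } else {
    stop("read_volume: expected a 3D single-channel image, got dimensions ",
         paste(d, collapse = "x"), call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("read_volume: missing or invalid voxel spacing in header",
         call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume_grid(img2, spacing = sp, affine = aff)
}

#' Read a binary mask from NIfTI
#'
#' Like [read_volume()] but binarizes the data at `threshold` (values strictly
#' greater become 1) and marks the result binary. Masks are held as integer
#' 0/1.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param threshold binarization threshold; default 0.5.
#' @return a binary [volume_grid()].
#' @export
read_mask <- function(path, threshold = 0.5) {
  v <- read_volume(path)
  v$data <- array(as.integer(v$data > threshold), dim = dim(v$data))
  v$is_binary <- TRUE
  v
}

#' Write a volume to NIfTI
#'
#' @param vol a [volume_grid()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
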