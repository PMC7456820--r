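#' Voxel grid geometry
#'
#' A voxel grid describes the common volumetric space that every lesion mask,
#' statistic map and parcellation in an analysis shares: the array dimensions,
#' the physical voxel size in millimetres, and the affine matrix mapping
#' 0-based voxel indices to world coordinates (mm).
#'
#' @param shape Integer vector of length 3, voxels per axis (each >= 1).
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm
#'   (each > 0). Ignored when `affine` is supplied (then derived from it).
#' @param affine Optional 4x4 numeric matrix mapping 0-based voxel indices to
#'   world mm. Defaults to a diagonal affine built from `voxel_size`. Must be
#'   invertible.
#'
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' voxel_grid(c(10, 10, 10), voxel_size = c(2, 2, 2))
voxel_grid <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    abort("`shape` must be 3 positive integers.")
  }
  if (is.null(affine)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
        any(voxel_size <= 0)) {
      abort("`voxel_size` must be 3 positive reals (mm).")
    }
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine))) {
      abort("`affine` must be a finite 4x4 matrix.")
    }
    if (abs(det(affine)) < .Machine$double.eps * 100) {
      abort("`affine` must be invertible.")
    }
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$shape, collapse = " x "),
      " voxels; voxel size ",
      paste(signif(x$voxel_size, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

#' Compare two voxel grids
#'
#' Grids are considered equal when shapes match exactly and affines agree
#' element-wise within `tol`. Registered cohorts often carry float jitter in
#' their headers, so a small tolerance is the practical definition of "same
#' grid".
#'
#' @param a,b `voxel_grid` objects.
#' @param tol Maximum element-wise absolute affine difference (default 1e-4).
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

#' Volume of one voxel in cubic centimetres
#' @param grid A `voxel_grid`.
#' @return Numeric scalar, cm^3 per voxel.
#' @export
voxel_volume_cm3 <- function(grid) {
  abs(det(grid$affine[1:3, 1:3])) / 1000
}
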