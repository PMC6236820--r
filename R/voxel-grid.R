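#' Voxel grid geometry
#'
#' A `voxel_grid` is the shared geometric frame for structure masks and dose
#' grids: an origin (the center of voxel `(0,0,0)`) in patient coordinates,
#' a per-axis voxel pitch, and the voxel counts. The center of voxel
#' `(i,j,k)` (0-based) lies at `origin + c(i,j,k) * spacing`.
#'
#' @param origin Numeric length 3; position of the first voxel center, mm.
#' @param spacing Numeric length 3; voxel pitch, mm. May be anisotropic; all
#'   values must be positive.
#' @param dims Integer length 3; voxel counts per axis, all >= 1.
#' @return An object of class `voxel_grid`.
#' @examples
#' voxel_grid(origin = c(-100, -100, -50), spacing = c(1, 1, 2.5), dims = c(200, 200, 40))
#' @export
voxel_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(!is.finite(origin))) stop("voxel_grid: origin must be finite")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel_grid: all spacing values must be positive")
  }
  if (any(is.na(dims)) || any(dims < 1L)) stop("voxel_grid: all dims must be >= 1")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("%dx%dx%d @ (%g,%g,%g) mm", x$dims[1], x$dims[2], x$dims[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

#' Volume of one voxel in cubic centimetres
#' @param grid A [voxel_grid()].
#' @return Voxel volume in cc.
#' @export
voxel_volume_cc <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing) / 1000
}

#' Voxel-center coordinates along each axis
#' @param grid A [voxel_grid()].
#' @return List of three numeric vectors (x, y, z voxel-center positions, mm).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing[a])
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Binary structure mask on a voxel grid
#'
#' Represents one structure (PTV, lung, ...) as voxel occupancy: a voxel is
#' part of the structure iff its center lies inside the contoured surface.
#'
#' @param grid A [voxel_grid()].
#' @param occupancy Logical array with `dim == grid$dims` (or a logical vector
#'   of matching length, filled in column-major order: x fastest).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, occupancy) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- array(as.logical(occupancy), dim = grid$dims)
  if (length(occ) != prod(grid$dims)) stop("binary_mask: occupancy length does not match grid dims")
  if (anyNA(occ)) stop("binary_mask: occupancy must not contain NA")
  structure(list(grid = grid, occupancy = occ), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s, %d voxels true (%.2f cc)\n",
              format(x$grid), sum(x$occupancy), mask_volume_cc(x)))
  invisible(x)
}

#' Structure volume in cubic centimetres
#' @param mask A [binary_mask()].
#' @return Volume in cc (true-voxel count times voxel volume).
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$occupancy) * voxel_volume_cc(mask$grid)
}

stop_if_grid_mismatch <- function(a, b, what = "masks") {
  if (!same_grid(a$grid, b$grid)) {
    stop(sprintf("grid mismatch: %s must share the same voxel grid", what))
  }
  invisible(TRUE)
}
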