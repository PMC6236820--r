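#' @name nifti_io
#' @title NIfTI import/export of masks and dose grids
#'
#' @description
#' Volumetric round trip of structures and dose through NIfTI-1 files. The
#' voxel grid is carried in the sform affine (axis-aligned, voxel-center
#' origin); masks are stored as 8-bit 0/1 volumes, dose as float64 with the
#' prescription recorded in the NIfTI description field (`rx=<Gy(RBE)>`).
#' Only axis-aligned affines with positive spacing are supported; the world
#' frame is the package's patient frame (mm).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param mask A [binary_mask()] (for `write_mask_nifti`).
#' @param dose A [dose_grid()] (for `write_dose_nifti`).
#' @return Readers return a [binary_mask()] / [dose_grid()]; writers return
#'   the path invisibly.
NULL

grid_to_affine <- function(grid) {
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  aff
}

affine_to_grid <- function(aff, dims) {
  rot <- aff[1:3, 1:3]
  if (any(abs(rot[upper.tri(rot) | lower.tri(rot)]) > 1e-6)) {
    stop("unsupported orientation: only axis-aligned NIfTI affines are supported")
  }
  spacing <- diag(rot)
  if (any(spacing <= 0)) {
    stop("unsupported orientation: NIfTI affine must have positive diagonal spacing")
  }
  voxel_grid(aff[1:3, 4], spacing, dims)
}

nifti_with_grid <- function(arr, grid, datatype) {
  img <- RNifti::asNifti(arr, datatype = datatype, internal = FALSE)
  aff <- grid_to_affine(grid)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  img
}

nifti_grid <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  dims <- dim(img)
  if (length(dims) != 3L) stop("expected a 3-D NIfTI volume")
  affine_to_grid(unclass(aff), dims)
}

#' @rdname nifti_io
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- nifti_with_grid(array(as.integer(mask$occupancy), dim = mask$grid$dims),
                         mask$grid, "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- nifti_grid(img)
  vals <- as.array(img)
  if (!all(vals %in% c(0, 1))) {
    stop("invalid mask: NIfTI volume contains values other than 0 and 1")
  }
  binary_mask(grid, vals == 1)
}

#' @rdname nifti_io
#' @export
write_dose_nifti <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  img <- nifti_with_grid(dose$dose, dose$grid, "double")
  img$descrip <- sprintf("rx=%.10g", dose$prescription)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @param prescription Prescription override in Gy(RBE); by default taken
#'   from the `rx=` tag written by `write_dose_nifti`.
#' @export
read_dose_nifti <- function(path, prescription = NULL) {
  img <- RNifti::readNifti(path)
  grid <- nifti_grid(img)
  if (is.null(prescription)) {
    descrip <- RNifti::niftiHeader(img)$descrip
    m <- regmatches(descrip, regexec("rx=([0-9.eE+-]+)", descrip))[[1]]
    if (length(m) == 2L) prescription <- as.numeric(m[2])
  }
  if (is.null(prescription) || is.na(prescription)) {
    stop("read_dose_nifti: no prescription found; pass `prescription=`")
  }
  dose_grid(grid, as.array(img), prescription)
}
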