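#' Signed Euclidean distance map of a structure
#'
#' For every voxel center, the Euclidean distance (mm) to the nearest voxel
#' center of the opposite occupancy class, negative inside the structure and
#' positive outside. Anisotropic spacing is honoured: distances are geometric
#' millimetres, not voxel counts, because CT slices are usually thicker than
#' in-plane pixels.
#'
#' @param mask A nonempty, not-all-true [binary_mask()].
#' @return An object of class `signed_distance_map` with fields `grid` and
#'   `distance` (numeric array, mm).
#' @seealso [expand_mask()] which thresholds this map at a margin.
#' @export
signed_distance_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  occ <- mask$occupancy
  nt <- sum(occ)
  if (nt == 0L) stop("degenerate mask: no surface (mask is all false)")
  if (nt == length(occ)) stop("degenerate mask: no surface (mask is all true)")
  d <- signed_distance_values(mask)
  structure(list(grid = mask$grid, distance = array(d, dim = mask$grid$dims)),
            class = "signed_distance_map")
}

#' @export
print.signed_distance_map <- function(x, ...) {
  cat(sprintf("<signed_distance_map> %s, range [%.2f, %.2f] mm\n",
              format(x$grid), min(x$distance), max(x$distance)))
  invisible(x)
}

# Raw signed distances (vector, column-major). Outside voxels carry the
# distance to the nearest true center; inside voxels minus the distance to
# the nearest false center. All-true masks yield -Inf-free results only when
# guarded by callers; all-false yields +Inf outside values.
signed_distance_values <- function(mask) {
  occ <- mask$occupancy
  dims <- mask$grid$dims
  sp <- mask$grid$spacing
  d_to_true <- sqrt(.edt_sq(as.logical(occ), dims, sp))
  d_to_false <- sqrt(.edt_sq(!as.logical(occ), dims, sp))
  ifelse(as.logical(occ), -d_to_false, d_to_true)
}

#' Enlarge a mask's grid with empty voxels
#'
#' Pads the grid by `voxels` empty voxels on every side (per axis), shifting
#' the origin accordingly. Use before [expand_mask()] when an expansion would
#' not fit the current field of view.
#'
#' @param mask A [binary_mask()].
#' @param voxels Integer length 1 or 3; voxels to add per side on each axis.
#' @return A [binary_mask()] on the enlarged grid.
#' @export
pad_grid <- function(mask, voxels) {
  stopifnot(inherits(mask, "binary_mask"))
  p <- as.integer(rep(voxels, length.out = 3))
  if (any(p < 0L)) stop("pad_grid: voxels must be non-negative")
  g <- mask$grid
  ng <- voxel_grid(g$origin - p * g$spacing, g$spacing, g$dims + 2L * p)
  occ <- array(FALSE, dim = ng$dims)
  occ[p[1] + seq_len(g$dims[1]), p[2] + seq_len(g$dims[2]), p[3] + seq_len(g$dims[3])] <-
    mask$occupancy
  binary_mask(ng, occ)
}

#' Isotropic margin expansion (or erosion) of a structure
#'
#' Returns the set of voxels whose signed distance to the original structure
#' is `<= m` millimetres. Positive margins expand, `m = 0` reproduces the
#' input exactly, negative margins erode. The threshold is applied to the
#' distance map of the *original* mask, so expansions compose exactly:
#' `expand(mask, a + b)` never drifts from a two-step expansion.
#'
#' The mask is padded internally so the computation is never clipped; if the
#' expansion would extend beyond the mask's own grid the function signals an
#' error rather than silently truncating (enlarge the field of view with
#' [pad_grid()] in that case).
#'
#' @param mask A nonempty [binary_mask()].
#' @param m Margin in mm (scalar; may be negative).
#' @return A [binary_mask()] on the same grid as the input.
#' @export
expand_mask <- function(mask, m) {
  stopifnot(inherits(mask, "binary_mask"), is.numeric(m), length(m) == 1L, is.finite(m))
  if (sum(mask$occupancy) == 0L) stop("expand_mask: mask is empty")
  g <- mask$grid
  # pad enough that the m-expansion of the structure fits the working grid
  p <- pmax(as.integer(ceiling(max(m, 0) / g$spacing)) + 1L, 1L)
  padded <- pad_grid(mask, p)
  d <- signed_distance_values(padded)
  occ <- array(d <= m, dim = padded$grid$dims)
  core <- list(p[1] + seq_len(g$dims[1]), p[2] + seq_len(g$dims[2]), p[3] + seq_len(g$dims[3]))
  outside <- occ
  outside[core[[1]], core[[2]], core[[3]]] <- FALSE
  if (any(outside)) {
    stop("insufficient padding: expansion exceeds the mask's grid; enlarge it with pad_grid()")
  }
  binary_mask(g, occ[core[[1]], core[[2]], core[[3]]])
}

#' Fraction of an organ covered by an expansion
#'
#' The fractional volume `|expansion ∩ organ| / |organ|` by voxel count;
#' the quantity V(m) when the expansion is `expand_mask(ptv, m)`. Multiply by
#' 100 for the percent values used in reports.
#'
#' @param expansion,organ [binary_mask()] objects on the same grid; the organ
#'   must be nonempty.
#' @return Fraction in `[0, 1]`.
#' @export
fractional_volume <- function(expansion, organ) {
  stopifnot(inherits(expansion, "binary_mask"), inherits(organ, "binary_mask"))
  stop_if_grid_mismatch(expansion, organ)
  n_organ <- sum(organ$occupancy)
  if (n_organ == 0L) stop("fractional_volume: organ mask is empty")
  sum(expansion$occupancy & organ$occupancy) / n_organ
}

#' Overlap curve V(m): organ fraction inside the PTV expanded by each margin
#'
#' Evaluates `fractional_volume(expand_mask(ptv, m), organ)` over an
#' ascending grid of margins. Implemented by thresholding the organ voxels'
#' signed distances to the PTV, which is voxel-identical to expanding and
#' intersecting margin by margin (the organ lies inside the grid, so field-of-
#' view clipping of an expansion can never change its overlap with the organ)
#' and costs a single distance transform for the whole curve.
#'
#' @param ptv,organ [binary_mask()] objects on the same grid; both nonempty.
#' @param m_values Ascending numeric vector of margins, mm.
#' @return A data.frame with columns `m` (mm) and `V` (fraction in `[0, 1]`,
#'   non-decreasing).
#' @export
v_of_m_curve <- function(ptv, organ, m_values) {
  stopifnot(inherits(ptv, "binary_mask"), inherits(organ, "binary_mask"))
  stop_if_grid_mismatch(ptv, organ)
  m_values <- as.numeric(m_values)
  if (length(m_values) == 0L) stop("v_of_m_curve: m_values is empty")
  if (is.unsorted(m_values, strictly = FALSE)) stop("v_of_m_curve: m_values must be ascending")
  if (sum(ptv$occupancy) == 0L) stop("v_of_m_curve: ptv mask is empty")
  n_organ <- sum(organ$occupancy)
  if (n_organ == 0L) stop("v_of_m_curve: organ mask is empty")
  d_organ <- organ_distances_to_structure(ptv, organ)
  V <- vapply(m_values, function(m) mean(d_organ <= m), numeric(1))
  data.frame(m = m_values, V = V)
}

# Signed distances of the organ's voxels to the structure surface; the basis
# of every V(m) evaluation. Handles the all-true corner (then every organ
# voxel is inside at depth -Inf-free 0) via the usual two-transform form.
organ_distances_to_structure <- function(structure_mask, organ) {
  occ <- structure_mask$occupancy
  dims <- structure_mask$grid$dims
  sp <- structure_mask$grid$spacing
  sel <- as.logical(organ$occupancy)
  if (all(occ)) return(rep(0, sum(sel)))  # degenerate: structure fills grid
  d_to_true <- sqrt(.edt_sq(as.logical(occ), dims, sp))
  if (!any(occ)) stop("structure mask is empty")
  d_to_false <- sqrt(.edt_sq(!as.logical(occ), dims, sp))
  d <- ifelse(as.logical(occ), -d_to_false, d_to_true)
  d[sel]
}
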