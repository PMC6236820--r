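#' Dose grid
#'
#' Per-voxel absorbed dose in Gy(RBE) on a [voxel_grid()], together with the
#' plan's prescription dose. The prescription is what [rescale_to_reference()]
#' uses to bring plans delivered at different dose levels into a common
#' analysis frame.
#'
#' @param grid A [voxel_grid()].
#' @param dose Numeric array with `dim == grid$dims` (or vector of matching
#'   length, column-major); all values must be >= 0.
#' @param prescription Prescription dose in Gy(RBE), > 0.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, dose, prescription) {
  stopifnot(inherits(grid, "voxel_grid"))
  dose <- array(as.numeric(dose), dim = grid$dims)
  if (length(dose) != prod(grid$dims)) stop("dose_grid: dose length does not match grid dims")
  if (anyNA(dose)) stop("dose_grid: dose must not contain NA")
  if (any(dose < 0)) stop("dose_grid: dose values must be non-negative")
  if (!is.numeric(prescription) || length(prescription) != 1L || !is.finite(prescription) ||
      prescription <= 0) {
    stop("invalid prescription: must be a single positive dose in Gy(RBE)")
  }
  structure(list(grid = grid, dose = dose, prescription = as.numeric(prescription)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s, prescription %g Gy(RBE), max %0.2f Gy(RBE)\n",
              format(x$grid), x$prescription, max(x$dose)))
  invisible(x)
}

#' Rescale a plan to the reference prescription
#'
#' Multiplies every voxel by `reference / prescription` so plans prescribed at
#' different dose levels can share one calibrated model. The default reference
#' is 50.4 Gy(RBE), the standard breast prescription the model is calibrated
#' at; e.g. a 20 Gy(RBE) isodose under a 45 Gy(RBE) prescription corresponds
#' to 20 x 45 / 50.4 ~= 18 Gy(RBE) in the reference frame.
#'
#' @param dose A [dose_grid()].
#' @param reference Reference prescription in Gy(RBE) (default 50.4).
#' @return A [dose_grid()] whose prescription equals `reference`.
#' @export
rescale_to_reference <- function(dose, reference = 50.4) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!is.numeric(reference) || length(reference) != 1L || !is.finite(reference) ||
      reference <= 0) {
    stop("invalid prescription: reference must be a single positive dose")
  }
  if (dose$prescription == reference) {
    return(dose_grid(dose$grid, dose$dose, reference))
  }
  dose_grid(dose$grid, dose$dose * (reference / dose$prescription), reference)
}

#' Resample a dose grid onto a structure grid
#'
#' Trilinear interpolation of the dose at the target grid's voxel centers.
#' Positions outside the dose grid's voxel-center hull receive 0 dose. Dose
#' is always brought onto the structure grid (never the reverse): structure
#' grids define the voxel-counting frame for every volume fraction.
#'
#' @param dose A [dose_grid()].
#' @param target A [voxel_grid()] spatially overlapping the dose grid.
#' @return A [dose_grid()] on `target` with the same prescription.
#' @export
resample_dose_to_grid <- function(dose, target) {
  stopifnot(inherits(dose, "dose_grid"), inherits(target, "voxel_grid"))
  if (same_grid(dose$grid, target)) {
    return(dose_grid(target, dose$dose, dose$prescription))
  }
  dg <- dose$grid
  # continuous (0-based) indices of target voxel centers in the dose frame
  ax <- grid_axes(target)
  fx <- (ax[[1]] - dg$origin[1]) / dg$spacing[1]
  fy <- (ax[[2]] - dg$origin[2]) / dg$spacing[2]
  fz <- (ax[[3]] - dg$origin[3]) / dg$spacing[3]
  inx <- fx >= 0 & fx <= dg$dims[1] - 1L
  iny <- fy >= 0 & fy <= dg$dims[2] - 1L
  inz <- fz >= 0 & fz <= dg$dims[3] - 1L
  if (!any(inx) || !any(iny) || !any(inz)) {
    stop("no overlap: target grid lies outside the dose grid")
  }
  out <- array(0, dim = target$dims)
  gx <- expand.grid(i = which(inx), j = which(iny), k = which(inz))
  x <- fx[gx$i]; y <- fy[gx$j]; z <- fz[gx$k]
  x0 <- pmin(floor(x), dg$dims[1] - 2L); y0 <- pmin(floor(y), dg$dims[2] - 2L)
  z0 <- pmin(floor(z), dg$dims[3] - 2L)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  tx <- x - x0; ty <- y - y0; tz <- z - z0
  dd <- dose$dose
  val8 <- function(ox, oy, oz) {
    dd[cbind(x0 + ox + 1L, y0 + oy + 1L, z0 + oz + 1L)]
  }
  v <- (1 - tx) * (1 - ty) * (1 - tz) * val8(0L, 0L, 0L) +
       tx       * (1 - ty) * (1 - tz) * val8(1L, 0L, 0L) +
       (1 - tx) * ty       * (1 - tz) * val8(0L, 1L, 0L) +
       tx       * ty       * (1 - tz) * val8(1L, 1L, 0L) +
       (1 - tx) * (1 - ty) * tz       * val8(0L, 0L, 1L) +
       tx       * (1 - ty) * tz       * val8(1L, 0L, 1L) +
       (1 - tx) * ty       * tz       * val8(0L, 1L, 1L) +
       tx       * ty       * tz       * val8(1L, 1L, 1L)
  out[cbind(gx$i, gx$j, gx$k)] <- pmax(v, 0)
  dose_grid(target, out, dose$prescription)
}

#' Volume receiving at least a dose: V_D
#'
#' Fraction of the organ's voxels whose dose is `>= D` (closed threshold, the
#' same convention as the `<=` margin threshold in [expand_mask()], so that a
#' conformal dose built from PTV distances is self-consistent with expansion
#' overlap).
#'
#' @param dose A [dose_grid()] on the organ's grid (resample first if needed).
#' @param organ A nonempty [binary_mask()].
#' @param D Dose threshold in Gy(RBE), >= 0.
#' @return Fraction in `[0, 1]`.
#' @export
volume_at_dose <- function(dose, organ, D) {
  stopifnot(inherits(dose, "dose_grid"), inherits(organ, "binary_mask"),
            is.numeric(D), length(D) == 1L, is.finite(D), D >= 0)
  stop_if_grid_mismatch(dose, organ, "dose and organ")
  sel <- organ$occupancy
  if (!any(sel)) stop("volume_at_dose: organ mask is empty")
  mean(dose$dose[sel] >= D)
}

#' Dose received by at least a volume fraction: D_V
#'
#' The largest dose D such that `volume_at_dose(dose, organ, D) >= V`, read
#' off the empirical (step) DVH of the organ's voxel doses. With `n` organ
#' voxels this is the `ceiling(V * n)`-th largest voxel dose; no interpolation
#' is applied by default, which keeps the query exactly invertible on the
#' achieved DVH steps. Set `interpolate = TRUE` for a linearly interpolated
#' quantile instead.
#'
#' @param dose A [dose_grid()] on the organ's grid.
#' @param organ A nonempty [binary_mask()].
#' @param V Volume fraction in `(0, 1]`.
#' @param interpolate Use linear interpolation between DVH steps
#'   (default `FALSE`).
#' @return Dose in Gy(RBE).
#' @export
dose_at_volume <- function(dose, organ, V, interpolate = FALSE) {
  stopifnot(inherits(dose, "dose_grid"), inherits(organ, "binary_mask"),
            is.numeric(V), length(V) == 1L, is.finite(V))
  stop_if_grid_mismatch(dose, organ, "dose and organ")
  if (V <= 0 || V > 1) stop("undefined query: V must lie in (0, 1]")
  sel <- organ$occupancy
  if (!any(sel)) stop("dose_at_volume: organ mask is empty")
  d <- sort(dose$dose[sel], decreasing = TRUE)
  n <- length(d)
  if (interpolate) {
    return(as.numeric(stats::quantile(d, probs = 1 - V, type = 7, names = FALSE)))
  }
  d[ceiling(V * n)]
}

#' Cumulative DVH of an organ
#'
#' @param dose A [dose_grid()] on the organ's grid.
#' @param organ A nonempty [binary_mask()].
#' @param dose_levels Dose thresholds in Gy(RBE); defaults to an even grid
#'   from 0 to the organ maximum.
#' @return A data.frame with columns `dose_Gy_RBE` and `fractional_volume`.
#' @export
dvh_curve <- function(dose, organ, dose_levels = NULL) {
  stopifnot(inherits(dose, "dose_grid"), inherits(organ, "binary_mask"))
  stop_if_grid_mismatch(dose, organ, "dose and organ")
  sel <- organ$occupancy
  if (!any(sel)) stop("dvh_curve: organ mask is empty")
  d <- dose$dose[sel]
  if (is.null(dose_levels)) {
    dose_levels <- seq(0, max(d), length.out = 201L)
  }
  v <- vapply(dose_levels, function(D) mean(d >= D), numeric(1))
  data.frame(dose_Gy_RBE = dose_levels, fractional_volume = v)
}

#' Margin-indexed dose falloff width around a target
#'
#' Measures the average distance over which the dose around the PTV drops
#' from `hi` to `lo` of prescription (default the 80%-20% falloff). The dose
#' is averaged over successive expansion shells
#' `expand(ptv, m) \ expand(ptv, m - delta)`; the falloff width is
#' `m_lo - m_hi`, where `m_x` is the first margin whose shell mean drops
#' below `x * prescription`.
#'
#' @param dose A [dose_grid()] on the PTV grid, already in the reference
#'   frame.
#' @param ptv A nonempty [binary_mask()].
#' @param hi,lo Fractions of prescription bounding the falloff window
#'   (`hi > lo`).
#' @param delta Shell thickness / scan step in mm (default 1).
#' @param m_max Largest margin scanned, mm (default 60).
#' @return Falloff width in mm.
#' @export
falloff_width <- function(dose, ptv, hi = 0.8, lo = 0.2, delta = 1, m_max = 60) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ptv, "binary_mask"))
  stop_if_grid_mismatch(dose, ptv, "dose and ptv")
  if (!(hi > lo) || lo < 0 || hi > 1) stop("falloff_width: need 0 <= lo < hi <= 1")
  if (delta <= 0) stop("falloff_width: delta must be positive")
  d_vox <- array(signed_distance_values(ptv), dim = ptv$grid$dims)
  ms <- seq(delta, m_max, by = delta)
  m_hi <- NA_real_; m_lo <- NA_real_
  for (m in ms) {
    shell <- d_vox <= m & d_vox > m - delta
    if (!any(shell)) next
    mu <- mean(dose$dose[shell])
    if (is.na(m_hi) && mu < hi * dose$prescription) m_hi <- m
    if (mu < lo * dose$prescription) { m_lo <- m; break }
  }
  if (is.na(m_hi) || is.na(m_lo)) {
    stop("falloff not found: shell-mean dose never dropped below the window within m_max")
  }
  m_lo - m_hi
}
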