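#' Synthetic thoracic phantom specification
#'
#' Parameterises the synthetic geometry every simulation study in this
#' package runs on: an ellipsoidal lung, a curved spherical-shell-sector PTV
#' wrapped around its anterior surface across a chest-wall gap, and a
#' conformal dose whose isodose surfaces are exact uniform expansions of the
#' PTV with a piecewise-linear falloff.
#'
#' The default falloff anchors place the 20 Gy(RBE) isodose exactly 11 mm and
#' the 5 Gy(RBE) isodose exactly 22 mm outside the PTV at the 50.4 Gy(RBE)
#' reference prescription, so margin calibration on default phantoms has a
#' known ground truth.
#'
#' @param spacing Voxel pitch, mm (length 3; default 2 mm isotropic).
#' @param lung_semiaxes Lung ellipsoid semi-axes, mm (x anterior, y lateral,
#'   z cranio-caudal).
#' @param lung_center Lung center in patient coordinates, mm.
#' @param sector_half_angle_deg Angular half-extent of the PTV shell sector
#'   about the +x (anterior) axis, degrees.
#' @param gap_mm Chest-wall gap: minimum radial clearance between the lung
#'   surface and the PTV inner surface, mm.
#' @param shell_thickness_mm Radial thickness of the PTV shell, mm.
#' @param falloff Data.frame with columns `distance_mm` (ascending from 0)
#'   and `fraction` (of prescription, strictly decreasing from 1).
#' @param prescription Prescription dose, Gy(RBE).
#' @param jitter_mm Per-case Gaussian perturbation scale for the geometric
#'   parameters in [make_cohort()], mm (0 = identical cases).
#' @param dose_jitter_mm Per-case perturbation scale for the interior falloff
#'   anchor distances, mm; produces case-to-case conformality variation and
#'   hence a nonzero calibration RMSE.
#' @param seed Random seed used by [make_cohort()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = c(2, 2, 2),
                         lung_semiaxes = c(62, 64, 66),
                         lung_center = c(0, 0, 0),
                         sector_half_angle_deg = 65,
                         gap_mm = 4,
                         shell_thickness_mm = 24,
                         falloff = data.frame(
                           distance_mm = c(0, 11, 22, 32),
                           fraction = c(1, 20 / 50.4, 5 / 50.4, 0)),
                         prescription = 50.4,
                         jitter_mm = 1.5,
                         dose_jitter_mm = 1,
                         seed = 1L) {
  spec <- structure(list(spacing = as.numeric(rep(spacing, length.out = 3)),
                         lung_semiaxes = as.numeric(lung_semiaxes),
                         lung_center = as.numeric(lung_center),
                         sector_half_angle_deg = as.numeric(sector_half_angle_deg),
                         gap_mm = as.numeric(gap_mm),
                         shell_thickness_mm = as.numeric(shell_thickness_mm),
                         falloff = falloff,
                         prescription = as.numeric(prescription),
                         jitter_mm = as.numeric(jitter_mm),
                         dose_jitter_mm = as.numeric(dose_jitter_mm),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(spacing <= 0)) stop("degenerate spec: spacing must be positive")
    if (length(lung_semiaxes) != 3 || any(lung_semiaxes <= 0)) {
      stop("degenerate spec: lung semi-axes must be 3 positive lengths")
    }
    if (sector_half_angle_deg <= 0 || sector_half_angle_deg >= 90) {
      stop("degenerate spec: sector half-angle must lie in (0, 90) degrees")
    }
    if (gap_mm < 0) stop("degenerate spec: gap must be >= 0")
    if (shell_thickness_mm <= 0) stop("degenerate spec: shell thickness must be positive")
    if (prescription <= 0) stop("degenerate spec: prescription must be positive")
  })
  validate_falloff(spec$falloff)
  invisible(spec)
}

validate_falloff <- function(falloff) {
  if (!is.data.frame(falloff) || !all(c("distance_mm", "fraction") %in% names(falloff))) {
    stop("invalid falloff: need columns distance_mm and fraction")
  }
  d <- falloff$distance_mm; f <- falloff$fraction
  if (nrow(falloff) < 2L) stop("invalid falloff: need at least two anchors")
  if (d[1] != 0 || f[1] != 1) stop("invalid falloff: anchors must start at (0, 1.0)")
  if (is.unsorted(d, strictly = TRUE)) stop("invalid falloff: distances must be strictly ascending")
  if (any(diff(f) >= 0)) stop("invalid falloff: fractions must be strictly decreasing")
  if (any(f < 0) || any(f > 1)) stop("invalid falloff: fractions must lie in [0, 1]")
  invisible(falloff)
}

# Largest ellipsoid radius over directions within the sector cone, by dense
# angular scan; sets the PTV inner radius r_in = gap + rho_max.
sector_max_radius <- function(semiaxes, half_angle_deg) {
  th <- seq(0, half_angle_deg * pi / 180, length.out = 181L)
  ph <- seq(0, 2 * pi, length.out = 361L)
  g <- expand.grid(th = th, ph = ph)
  ux <- cos(g$th); uy <- sin(g$th) * cos(g$ph); uz <- sin(g$th) * sin(g$ph)
  rho <- 1 / sqrt((ux / semiaxes[1])^2 + (uy / semiaxes[2])^2 + (uz / semiaxes[3])^2)
  max(rho)
}

#' Build the phantom structures
#'
#' Rasterises the lung ellipsoid and the PTV shell sector of a
#' [phantom_spec()] onto a voxel grid sized to leave room for the dose
#' falloff region and the margin expansions used by the model. The PTV inner
#' radius is `gap_mm` beyond the largest lung radius within the sector cone,
#' so the two structures are disjoint with (up to voxelisation) the requested
#' minimum clearance.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `ptv`, `lung` ([binary_mask()]s on a shared
#'   grid), `grid`, and `geometry` (resolved `r_in` / `r_out`, mm).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  sp <- spec$spacing
  ctr <- spec$lung_center
  theta <- spec$sector_half_angle_deg * pi / 180
  rho_max <- sector_max_radius(spec$lung_semiaxes, spec$sector_half_angle_deg)
  r_in <- rho_max + spec$gap_mm
  r_out <- r_in + spec$shell_thickness_mm

  headroom <- max(spec$falloff$distance_mm) + 4
  ext_x_lo <- spec$lung_semiaxes[1] + 3 * sp[1]
  ext_x_hi <- r_out + headroom
  ext_y <- max(spec$lung_semiaxes[2], r_out * sin(theta)) + headroom
  ext_z <- max(spec$lung_semiaxes[3], r_out * sin(theta)) + headroom
  ax_x <- seq(-ceiling(ext_x_lo / sp[1]), ceiling(ext_x_hi / sp[1])) * sp[1] + ctr[1]
  ax_y <- seq(-ceiling(ext_y / sp[2]), ceiling(ext_y / sp[2])) * sp[2] + ctr[2]
  ax_z <- seq(-ceiling(ext_z / sp[3]), ceiling(ext_z / sp[3])) * sp[3] + ctr[3]
  grid <- voxel_grid(c(ax_x[1], ax_y[1], ax_z[1]), sp,
                     c(length(ax_x), length(ax_y), length(ax_z)))

  dx <- ax_x - ctr[1]; dy <- ax_y - ctr[2]; dz <- ax_z - ctr[3]
  nx <- length(dx); ny <- length(dy); nz <- length(dz)
  X <- array(dx, dim = c(nx, ny, nz))
  Y <- array(rep(dy, each = nx), dim = c(nx, ny, nz))
  Z <- array(rep(dz, each = nx * ny), dim = c(nx, ny, nz))

  a <- spec$lung_semiaxes
  lung_occ <- (X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2 <= 1
  r <- sqrt(X^2 + Y^2 + Z^2)
  ptv_occ <- r >= r_in & r <= r_out & X >= r * cos(theta)

  if (!any(ptv_occ)) stop("degenerate spec: PTV rasterised to an empty mask")
  if (!any(lung_occ)) stop("degenerate spec: lung rasterised to an empty mask")
  list(ptv = binary_mask(grid, ptv_occ),
       lung = binary_mask(grid, lung_occ),
       grid = grid,
       geometry = list(r_in = r_in, r_out = r_out))
}

# Piecewise-linear falloff evaluated at distances (mm) beyond the PTV
# surface; flat at prescription inside, at the last anchor's fraction beyond.
falloff_fraction <- function(falloff, distance_mm) {
  validate_falloff(falloff)
  stats::approx(falloff$distance_mm, falloff$fraction, xout = pmax(distance_mm, 0),
                method = "linear", rule = 2)$y
}

#' Distance at which the falloff reaches a dose fraction
#'
#' Inverse of the phantom falloff: the distance beyond the PTV surface at
#' which the dose first drops to `fraction` of prescription. At the anchor
#' fractions this is exact, so e.g. the default anchors give 11 mm at
#' 20/50.4.
#'
#' @param falloff Anchor data.frame (see [phantom_spec()]).
#' @param fraction Dose fraction(s) of prescription, within the anchor range.
#' @return Distance(s) in mm.
#' @export
falloff_inverse <- function(falloff, fraction) {
  validate_falloff(falloff)
  if (any(fraction > 1) || any(fraction < min(falloff$fraction))) {
    stop("falloff_inverse: fraction outside the anchor range")
  }
  stats::approx(rev(falloff$fraction), rev(falloff$distance_mm), xout = fraction,
                method = "linear", rule = 2)$y
}

#' Conformal dose field around a PTV
#'
#' Builds the idealised dose of a perfectly conformal plan: prescription
#' everywhere inside the PTV, and `prescription * f(d)` at distance `d`
#' outside it, with `f` the piecewise-linear falloff. By construction the
#' `D` isodose region (dose `>= D`) is exactly the PTV expanded by
#' `falloff_inverse(falloff, D / prescription)` millimetres.
#'
#' @param ptv A nonempty [binary_mask()].
#' @param falloff Anchor data.frame (see [phantom_spec()]).
#' @param prescription Prescription dose, Gy(RBE).
#' @return A [dose_grid()] on the PTV grid.
#' @export
conformal_dose <- function(ptv, falloff, prescription) {
  stopifnot(inherits(ptv, "binary_mask"))
  if (sum(ptv$occupancy) == 0L) stop("conformal_dose: ptv mask is empty")
  validate_falloff(falloff)
  d <- signed_distance_values(ptv)
  dose <- prescription * falloff_fraction(falloff, pmax(d, 0))
  dose_grid(ptv$grid, dose, prescription)
}

#' Generate a synthetic cohort
#'
#' Draws `n` cases from the phantom family: geometric parameters (lung
#' semi-axes, chest-wall gap, shell thickness) perturbed by independent
#' Gaussians of scale `jitter_mm`, interior falloff anchor distances by
#' `dose_jitter_mm` (conformality variation), all truncated to keep the spec
#' valid. Laterality alternates left/right. Each case carries its conformal
#' dose. Fixed seed gives bit-reproducible output.
#'
#' @param n Number of cases, >= 1.
#' @param spec A [phantom_spec()]; its `seed`, `jitter_mm` and
#'   `dose_jitter_mm` control the draw.
#' @return List of `n` [cohort_record()]s.
#' @export
make_cohort <- function(n, spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("make_cohort: n must be >= 1")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  lapply(seq_len(n), function(i) {
    s <- spec
    if (spec$jitter_mm > 0) {
      s$lung_semiaxes <- pmax(spec$lung_semiaxes + stats::rnorm(3, 0, spec$jitter_mm), 20)
      s$gap_mm <- max(spec$gap_mm + stats::rnorm(1, 0, spec$jitter_mm), 0)
      s$shell_thickness_mm <- max(spec$shell_thickness_mm + stats::rnorm(1, 0, spec$jitter_mm), 4)
    }
    if (spec$dose_jitter_mm > 0 && nrow(spec$falloff) > 2L) {
      idx <- seq(2L, nrow(spec$falloff))
      d <- spec$falloff$distance_mm
      d[idx] <- d[idx] + stats::rnorm(length(idx), 0, spec$dose_jitter_mm)
      for (k in idx) d[k] <- max(d[k], d[k - 1] + 0.5)   # keep strictly ascending
      s$falloff$distance_mm <- d
    }
    ph <- make_phantom(s)
    dose <- conformal_dose(ph$ptv, s$falloff, s$prescription)
    cohort_record(case_id = sprintf("phantom-%03d", i),
                  laterality = if (i %% 2L == 1L) "left" else "right",
                  ptv = ph$ptv, ipsilateral_lung = ph$lung,
                  dose = dose, prescription = s$prescription)
  })
}

#' Cold-spot variant of a dose field
#'
#' Caps the dose at `floor_gy` inside a region, emulating a plan whose
#' conformality is deliberately compromised (e.g. heart sparing underdosing
#' the medial PTV). The contour-only prediction cannot see the cold spot, so
#' it overestimates the lung dose of such plans.
#'
#' @param dose A [dose_grid()].
#' @param region A [binary_mask()] on the same grid (may be empty, in which
#'   case the dose is returned unchanged).
#' @param floor_gy Cap in Gy(RBE), >= 0.
#' @return A [dose_grid()]: `min(dose, floor_gy)` inside the region,
#'   unchanged elsewhere.
#' @export
cold_spot_variant <- function(dose, region, floor_gy) {
  stopifnot(inherits(dose, "dose_grid"), inherits(region, "binary_mask"))
  stop_if_grid_mismatch(dose, region, "dose and region")
  if (!is.numeric(floor_gy) || length(floor_gy) != 1L || !is.finite(floor_gy) || floor_gy < 0) {
    stop("cold_spot_variant: floor must be a single non-negative dose")
  }
  d <- dose$dose
  sel <- region$occupancy
  d[sel] <- pmin(d[sel], floor_gy)
  dose_grid(dose$grid, d, dose$prescription)
}

#' Axis-aligned box region on a grid
#'
#' Convenience constructor for cold-spot regions and other axis-aligned
#' selections: voxels whose centers fall inside `[lo, hi]` (mm, patient
#' coordinates; use -Inf/Inf for half-spaces).
#'
#' @param grid A [voxel_grid()].
#' @param lo,hi Numeric length 3, mm.
#' @return A [binary_mask()].
#' @export
box_mask <- function(grid, lo = c(-Inf, -Inf, -Inf), hi = c(Inf, Inf, Inf)) {
  stopifnot(inherits(grid, "voxel_grid"))
  lo <- rep(as.numeric(lo), length.out = 3)
  hi <- rep(as.numeric(hi), length.out = 3)
  ax <- grid_axes(grid)
  inx <- ax[[1]] >= lo[1] & ax[[1]] <= hi[1]
  iny <- ax[[2]] >= lo[2] & ax[[2]] <= hi[2]
  inz <- ax[[3]] >= lo[3] & ax[[3]] <= hi[3]
  occ <- array(FALSE, dim = grid$dims)
  occ[inx, iny, inz] <- TRUE
  binary_mask(grid, occ)
}
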