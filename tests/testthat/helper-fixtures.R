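# Shared fixtures. The small phantom keeps unit tests fast (~0.3 Mvoxel
# grids); the calibration anchors stay at 11 / 22 mm so margin-recovery tests
# target the shipped model's ground truth.

small_spec <- function(gap_mm = 4, jitter_mm = 0, dose_jitter_mm = 0, ...) {
  phantom_spec(lung_semiaxes = c(30, 32, 34),
               gap_mm = gap_mm,
               shell_thickness_mm = 12,
               falloff = data.frame(distance_mm = c(0, 11, 22, 26),
                                    fraction = c(1, 20 / 50.4, 5 / 50.4, 0)),
               jitter_mm = jitter_mm, dose_jitter_mm = dose_jitter_mm,
               ...)
}

small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- small_spec()
      ph <- make_phantom(spec)
      ph$spec <- spec
      ph$dose <- conformal_dose(ph$ptv, spec$falloff, spec$prescription)
      cache <<- ph
    }
    cache
  }
})

# A small random mask on an anisotropic grid, reproducible.
random_mask <- function(dims = c(9L, 8L, 7L), spacing = c(1, 1.5, 2),
                        p = 0.2, seed = 7) {
  set.seed(seed)
  g <- voxel_grid(c(0, 0, 0), spacing, dims)
  binary_mask(g, array(stats::runif(prod(dims)) < p, dim = dims))
}

# Exhaustive all-pairs signed-distance oracle (voxel centers, mm).
brute_force_signed_distance <- function(mask) {
  g <- mask$grid
  ax <- grid_axes(g)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  occ <- as.logical(mask$occupancy)
  to_true <- t(pts[occ, , drop = FALSE])
  to_false <- t(pts[!occ, , drop = FALSE])
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    if (occ[i]) -sqrt(min(colSums((to_false - p)^2)))
    else sqrt(min(colSums((to_true - p)^2)))
  }, numeric(1))
}

# Digitized sphere of radius r (mm) centered on a voxel center.
sphere_mask <- function(r, spacing = c(1, 1, 1), headroom = 12) {
  n <- ceiling((r + headroom) / spacing)
  ax <- lapply(1:3, function(a) seq(-n[a], n[a]) * spacing[a])
  g <- voxel_grid(c(ax[[1]][1], ax[[2]][1], ax[[3]][1]), spacing,
                  c(length(ax[[1]]), length(ax[[2]]), length(ax[[3]])))
  X <- array(ax[[1]], dim = g$dims)
  Y <- array(rep(ax[[2]], each = g$dims[1]), dim = g$dims)
  Z <- array(rep(ax[[3]], each = g$dims[1] * g$dims[2]), dim = g$dims)
  binary_mask(g, X^2 + Y^2 + Z^2 <= r^2)
}
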