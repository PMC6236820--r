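test_that("signed distances honour anisotropic spacing on simple shapes", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(5L, 5L, 5L))
  occ <- array(FALSE, dim = g$dims)
  occ[3, 3, 3] <- TRUE
  sdm <- signed_distance_map(binary_mask(g, occ))
  # face neighbour along the thick axis is one slice = 2 mm away
  expect_equal(sdm$distance[3, 3, 4], 2)
  expect_equal(sdm$distance[3, 3, 2], 2)
  expect_equal(sdm$distance[4, 3, 3], 1)
  expect_equal(sdm$distance[3, 3, 3], -1)  # only voxel inside: nearest outside center

  # solid block: face voxels one step inside, the center two steps
  occ <- array(FALSE, dim = g$dims)
  occ[2:4, 2:4, 2:4] <- TRUE
  sdm <- signed_distance_map(binary_mask(g, occ))
  expect_equal(sdm$distance[2, 3, 3], -1)          # surface voxel, 1 mm to outside
  expect_equal(sdm$distance[3, 3, 3], -2)          # center: two in-plane steps
  expect_true(all(sdm$distance[occ] < 0))
  expect_true(all(sdm$distance[!occ] > 0))
})

test_that("signed distances match the exhaustive all-pairs oracle", {
  for (seed in c(7, 19)) {
    m <- random_mask(dims = c(12L, 12L, 12L), spacing = c(1, 1.5, 2), seed = seed)
    sdm <- signed_distance_map(m)
    expect_lt(max(abs(as.numeric(sdm$distance) - brute_force_signed_distance(m))), 1e-9)
  }
})

test_that("degenerate masks are rejected", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(3L, 3L, 3L))
  expect_error(signed_distance_map(binary_mask(g, array(FALSE, g$dims))), "degenerate")
  expect_error(signed_distance_map(binary_mask(g, array(TRUE, g$dims))), "degenerate")
})

test_that("expansion is the identity at m = 0 and nests with the margin", {
  m <- pad_grid(random_mask(seed = 11), 4)   # room for the expansions below
  e0 <- expand_mask(m, 0)
  expect_identical(e0$occupancy, m$occupancy)
  prev <- expand_mask(m, -2)
  for (mm in c(-1, 0, 1, 2.5)) {
    cur <- expand_mask(m, mm)
    expect_true(all(cur$occupancy | !prev$occupancy))  # prev subset of cur, every voxel
    prev <- cur
  }
})

test_that("sphere expansion volume approaches the analytic closed form", {
  s <- sphere_mask(20)
  vol_cc <- function(mask, mm) sum(expand_mask(mask, mm)$occupancy)  # 1 mm voxels
  analytic <- function(r) 4 / 3 * pi * r^3
  expect_lt(abs(vol_cc(s, 10) / analytic(30) - 1), 0.02)
  # the center-to-center convention shifts the digitized surface by up to
  # half a voxel, so other margins are bracketed by that radius uncertainty
  for (mm in c(5, -5)) {
    expect_gt(vol_cc(s, mm), analytic(20 + mm - 0.5))
    expect_lt(vol_cc(s, mm), analytic(20 + mm + 0.5))
  }
})

test_that("erosion beyond the inradius empties the mask", {
  s <- sphere_mask(5, headroom = 4)
  expect_equal(sum(expand_mask(s, -6)$occupancy), 0)
})

test_that("expansion that would leave the grid is refused, and padding fixes it", {
  s <- sphere_mask(5, headroom = 2)
  expect_error(expand_mask(s, 6), "insufficient padding")
  padded <- pad_grid(s, 6)
  e <- expand_mask(padded, 6)
  expect_lt(abs(sum(e$occupancy) / sum(s$occupancy) / (11 / 5)^3 - 1), 0.06)
})

test_that("fractional volume matches the voxel-count oracle exactly", {
  a <- random_mask(dims = c(20L, 20L, 20L), spacing = c(1, 1, 1), p = 0.3, seed = 3)
  b_occ <- local({ set.seed(4); array(runif(8000) < 0.4, dim = c(20, 20, 20)) })
  b <- binary_mask(a$grid, b_occ)
  expect_identical(fractional_volume(a, b), sum(a$occupancy & b$occupancy) / sum(b$occupancy))

  # trivial cases: disjoint masks and containment
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(6L, 6L, 6L))
  left <- array(FALSE, g$dims); left[1:2, , ] <- TRUE
  right <- array(FALSE, g$dims); right[5:6, , ] <- TRUE
  expect_equal(fractional_volume(binary_mask(g, left), binary_mask(g, right)), 0)
  inner <- array(FALSE, g$dims); inner[2, 2, 2] <- TRUE
  expect_equal(fractional_volume(binary_mask(g, left), binary_mask(g, inner)), 1)
})

test_that("grid mismatches and empty organs are reported", {
  a <- random_mask(seed = 5)
  other <- binary_mask(voxel_grid(c(1, 0, 0), a$grid$spacing, a$grid$dims), a$occupancy)
  expect_error(fractional_volume(a, other), "grid mismatch")
  empty <- binary_mask(a$grid, array(FALSE, a$grid$dims))
  expect_error(fractional_volume(a, empty), "empty")
})

test_that("V(m) curve is monotone, bounded, and equals expand-then-intersect", {
  ph <- small_phantom()
  ms <- seq(-4, 24, by = 4)
  curve <- v_of_m_curve(ph$ptv, ph$lung, ms)
  expect_true(all(curve$V >= 0 & curve$V <= 1))
  expect_true(all(diff(curve$V) >= 0))
  expect_equal(curve$V[curve$m == 0],
               fractional_volume(ph$ptv, ph$lung))
  # per-margin independent oracle on a subset
  for (mm in c(4, 12, 20)) {
    expect_identical(curve$V[curve$m == mm],
                     fractional_volume(expand_mask(ph$ptv, mm), ph$lung))
  }
  # disjoint beyond reach: shrink far enough and nothing overlaps
  expect_equal(v_of_m_curve(ph$ptv, ph$lung, c(-40, -30))$V, c(0, 0))
})

test_that("mask volume accounting is spacing-aware", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1.5, 2), c(4L, 4L, 4L))
  occ <- array(FALSE, g$dims); occ[1:2, 1, 1] <- TRUE
  expect_equal(mask_volume_cc(binary_mask(g, occ)), 2 * 3 / 1000)
  expect_equal(mask_volume_cc(binary_mask(g, array(FALSE, g$dims))), 0)
})
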