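make_uniform_dose <- function(value, prescription = 50.4, dims = c(4L, 4L, 4L)) {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), dims)
  dose_grid(g, array(value, dims), prescription)
}

full_mask <- function(grid) binary_mask(grid, array(TRUE, grid$dims))

test_that("prescription rescaling is exact arithmetic and an identity at the reference", {
  d <- make_uniform_dose(20, prescription = 45)
  r <- rescale_to_reference(d)
  expect_equal(r$dose[1, 1, 1], 20 * 50.4 / 45)  # 22.4
  expect_equal(r$prescription, 50.4)
  same <- rescale_to_reference(make_uniform_dose(33, prescription = 50.4))
  expect_identical(same$dose, make_uniform_dose(33)$dose)
  # the query direction: a 20 Gy(RBE) isodose of a 45 Gy(RBE) plan sits near
  # 18 Gy(RBE) in the reference frame
  expect_equal(20 * 45 / 50.4, 17.857, tolerance = 1e-4)
  expect_error(dose_grid(d$grid, d$dose, 0), "prescription")
})

test_that("rescaling equivariance of V_D holds", {
  set.seed(21)
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(8L, 8L, 8L))
  d <- dose_grid(g, array(runif(512) * 60, g$dims), 45)
  organ <- full_mask(g)
  for (D in c(5, 20, 35)) {
    expect_equal(volume_at_dose(rescale_to_reference(d), organ, D),
                 volume_at_dose(d, organ, D * 45 / 50.4))
  }
})

test_that("trilinear resampling reproduces identity, constants and linear ramps", {
  g <- voxel_grid(c(0, 0, 0), c(2, 2, 2), c(6L, 6L, 6L))
  ramp <- outer(seq(0, 10, by = 2), rep(1, 6)) |> array(dim = c(6, 6, 6))
  d <- dose_grid(g, ramp, 50.4)
  expect_identical(resample_dose_to_grid(d, g)$dose, d$dose)

  const <- dose_grid(g, array(7, g$dims), 50.4)
  tgt <- voxel_grid(c(1, 1, 1), c(2, 2, 2), c(4L, 4L, 4L))
  expect_equal(unique(as.numeric(resample_dose_to_grid(const, tgt)$dose)), 7)

  # linear field is exact under trilinear interpolation at half-voxel offsets
  res <- resample_dose_to_grid(d, tgt)
  expect_equal(res$dose[, 2, 2], c(1, 3, 5, 7))  # dose equals x at target centers

  far <- voxel_grid(c(100, 100, 100), c(2, 2, 2), c(3L, 3L, 3L))
  expect_error(resample_dose_to_grid(d, far), "no overlap")
})

test_that("V_D and D_V answer the hand-computable queries", {
  d <- make_uniform_dose(30)
  organ <- full_mask(d$grid)
  expect_equal(volume_at_dose(d, organ, 20), 1)
  expect_equal(volume_at_dose(make_uniform_dose(3), organ, 5), 0)
  expect_equal(dose_at_volume(d, organ, 0.37), 30)

  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(4L, 1L, 1L))
  d4 <- dose_grid(g, array(c(10, 20, 30, 40), g$dims), 50.4)
  o4 <- full_mask(g)
  expect_equal(dose_at_volume(d4, o4, 0.5), 30)
  expect_equal(dose_at_volume(d4, o4, 1), 10)    # full-volume query = minimum dose
  expect_equal(dose_at_volume(d4, o4, 0.25), 40)
  expect_error(dose_at_volume(d4, o4, 0), "undefined")
})

test_that("V_D matches the voxel-count oracle on a random field", {
  set.seed(9)
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(15L, 15L, 15L))
  vals <- array(runif(15^3) * 50, g$dims)
  d <- dose_grid(g, vals, 50.4)
  organ <- binary_mask(g, array(runif(15^3) < 0.5, g$dims))
  oracle <- sum(vals >= 10 & organ$occupancy) / sum(organ$occupancy)
  expect_identical(volume_at_dose(d, organ, 10), oracle)
})

test_that("DVH identities: monotone in D and V, total volume at zero dose, round trip", {
  set.seed(31)
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(10L, 10L, 10L))
  d <- dose_grid(g, array(rexp(1000, rate = 1 / 15), g$dims), 50.4)
  organ <- binary_mask(g, array(runif(1000) < 0.6, g$dims))
  Ds <- seq(0, 60, by = 5)
  v <- vapply(Ds, function(D) volume_at_dose(d, organ, D), numeric(1))
  expect_true(all(diff(v) <= 0))
  expect_equal(v[1], 1)  # strictly positive dose field
  Vs <- c(0.9, 0.5, 0.2)
  dv <- vapply(Vs, function(V) dose_at_volume(d, organ, V), numeric(1))
  expect_true(all(diff(dv) >= 0))  # smaller volume fraction -> higher dose
  # round trip on achieved DVH steps
  for (D in sample(d$dose[organ$occupancy], 5)) {
    expect_equal(dose_at_volume(d, organ, volume_at_dose(d, organ, D)), D)
  }
})

test_that("falloff width recovers the constructed dose gradient", {
  ph <- small_phantom()
  # piecewise-linear anchors: analytic 80%-20% distance
  analytic <- falloff_inverse(ph$spec$falloff, 0.2) - falloff_inverse(ph$spec$falloff, 0.8)
  expect_lt(abs(falloff_width(ph$dose, ph$ptv) - analytic), 1)

  # pure linear falloff over L = 30 mm: analytic 80%-20% width is 0.6 L = 18
  lin <- data.frame(distance_mm = c(0, 30), fraction = c(1, 0))
  sph <- sphere_mask(8, spacing = c(2, 2, 2), headroom = 36)
  lin_dose <- conformal_dose(sph, lin, 50.4)
  expect_lt(abs(falloff_width(lin_dose, sph) - 18), 1.01)

  # step dose: prescription inside the PTV, zero outside -> width <= delta
  step <- dose_grid(ph$grid, array(ifelse(ph$ptv$occupancy, 50.4, 0), ph$grid$dims), 50.4)
  expect_lte(falloff_width(step, ph$ptv), 1)

  # narrow window degenerates toward zero width
  expect_lte(falloff_width(ph$dose, ph$ptv, hi = 0.5, lo = 0.45), 3)

  flat <- dose_grid(ph$grid, array(50.4, ph$grid$dims), 50.4)
  expect_error(falloff_width(flat, ph$ptv), "falloff not found")
})
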