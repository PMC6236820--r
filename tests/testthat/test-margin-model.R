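# A tiny two-case cohort with hand-computable errors: uniform doses and
# simple slab geometry so V(m) and V_D are exact fractions.
slab_case <- function(id, v_m_frac, v_d_frac, n = 10L) {
  g <- voxel_grid(c(0.5, 0.5, 0.5), c(1, 1, 1), c(n, n, n))
  lung <- array(FALSE, g$dims); lung[, , 1:5] <- TRUE          # 500 voxels
  n_lung <- sum(lung)
  # PTV slab sized so that V(0) = v_m_frac of the lung is inside it
  # first k voxels in column-major order all lie inside the lung slab
  ptv <- array(FALSE, g$dims)
  k <- round(v_m_frac * n_lung)
  if (k > 0) ptv[seq_len(k)] <- TRUE
  # dose: exactly v_d_frac of lung voxels at 30 Gy, rest 0
  dd <- array(0, g$dims)
  idx <- which(lung)
  dd[idx[seq_len(round(v_d_frac * n_lung))]] <- 30
  cohort_record(id, "left", binary_mask(g, ptv), binary_mask(g, lung),
                dose_grid(g, dd, 50.4))
}

test_that("rmse and mean error reproduce hand-computed values", {
  # errors +2 pp and -4 pp at m = 0, D = 20
  coh <- list(slab_case("a", v_m_frac = 0.12, v_d_frac = 0.10),
              slab_case("b", v_m_frac = 0.06, v_d_frac = 0.10))
  pe <- prediction_errors(coh, m = 0, D = 20)
  expect_equal(pe$per_case_errors$error_pct, c(2, -4))
  expect_equal(pe$rmse, sqrt((2^2 + 4^2) / 2))  # sqrt(10)
  expect_equal(pe$me, -1)
  expect_gte(pe$rmse, abs(pe$me))
  # perfect prediction
  pe0 <- prediction_errors(list(slab_case("c", 0.2, 0.2)), m = 0, D = 20)
  expect_equal(pe0$rmse, 0)
  expect_equal(pe0$me, 0)
})

test_that("rmse >= |me| across random error configurations", {
  set.seed(13)
  for (i in 1:8) {
    fracs <- runif(3, 0.05, 0.4)
    vd <- pmin(pmax(fracs + rnorm(3, 0, 0.05), 0.02), 0.5)
    coh <- Map(slab_case, paste0("c", 1:3, "_", i), fracs, vd)
    pe <- prediction_errors(coh, m = 0, D = 20)
    expect_gte(pe$rmse + 1e-12, abs(pe$me))
  }
})

test_that("calibration returns the grid-search optimum with smallest-margin ties", {
  ph <- small_phantom()
  rec <- cohort_record("p1", "left", ph$ptv, ph$lung, ph$dose)
  fit <- calibrate_margin(list(rec), 20, m_grid = seq(0, 24, by = 0.5))
  # exhaustive re-evaluation oracle
  rmses <- vapply(seq(0, 24, by = 0.5), function(m) prediction_errors(list(rec), m, 20)$rmse,
                  numeric(1))
  expect_equal(fit$rmse, min(rmses))
  expect_equal(fit$margin_mm, seq(0, 24, by = 0.5)[which.min(rmses)])
  expect_true(all(fit$rmse <= fit$rmse_by_margin$rmse))

  # tie-breaking: a flat-error region picks the smallest margin
  flat <- slab_case("flat", 0.2, 0.2)
  # V(m) for m in [0, 0.4] is constant on a unit grid (next voxel layer at 1 mm)
  fit_flat <- calibrate_margin(list(flat), 20, m_grid = c(0, 0.2, 0.4))
  expect_equal(fit_flat$margin_mm, 0)
})

test_that("noiseless conformal phantoms recover the construction margins", {
  ph <- small_phantom()
  rec <- cohort_record("p1", "left", ph$ptv, ph$lung, ph$dose)
  fit20 <- calibrate_margin(list(rec), 20, m_grid = seq(5, 30, by = 0.5))
  fit5 <- calibrate_margin(list(rec), 5, m_grid = seq(5, 30, by = 0.5))
  expect_lte(abs(fit20$margin_mm - 11), max(ph$grid$spacing))
  expect_lte(abs(fit5$margin_mm - 22), max(ph$grid$spacing))
  expect_lt(fit20$rmse, 0.5)
  expect_lt(fit5$rmse, 0.5)
})

test_that("predictions are geometric, monotone in the margin, and dose-free", {
  ph <- small_phantom()
  model <- default_margin_model()
  p20 <- predict_volume(ph$ptv, ph$lung, model, 20)
  p5 <- predict_volume(ph$ptv, ph$lung, model, 5)
  expect_equal(p20, fractional_volume(expand_mask(ph$ptv, 11), ph$lung))
  expect_gte(p5, p20)  # larger margin, lower dose level: no smaller volume
  expect_error(predict_volume(ph$ptv, ph$lung, model, 30), "unknown dose level")

  # PTV further than the margin from the lung predicts zero
  g <- voxel_grid(c(0.5, 0.5, 0.5), c(1, 1, 1), c(30L, 6L, 6L))
  ptv <- array(FALSE, g$dims); ptv[1:3, , ] <- TRUE
  lung <- array(FALSE, g$dims); lung[20:30, , ] <- TRUE    # 16 mm clearance
  expect_equal(predict_volume(binary_mask(g, ptv), binary_mask(g, lung),
                              margin_model(c("20" = 11)), 20), 0)

  # a calibration result serves as a single-level model
  rec <- cohort_record("p1", "left", ph$ptv, ph$lung, ph$dose)
  fit <- calibrate_margin(list(rec), 20, m_grid = seq(9, 13, by = 1))
  expect_equal(predict_volume(ph$ptv, ph$lung, fit, 20),
               fractional_volume(expand_mask(ph$ptv, fit$margin_mm), ph$lung))
  expect_error(predict_volume(ph$ptv, ph$lung, fit, 5), "unknown dose level")
})

test_that("convergence declares at the cohort-size floor for zero-variance streams", {
  rec <- slab_case("r", 0.2, 0.15)
  stream <- rep(list(rec), 12)
  for (i in seq_along(stream)) stream[[i]]$case_id <- paste0("r", i)
  conv <- convergence_run(stream, 20, m = 0)
  expect_true(conv$converged)
  expect_equal(conv$n_converged, 10L)
  expect_equal(length(unique(round(conv$trace$rmse, 10))), 1L)  # constant rmse
})

test_that("strict tolerance on a noisy stream does not converge", {
  set.seed(17)
  fracs <- runif(12, 0.1, 0.3)
  vd <- pmin(pmax(fracs + rnorm(12, 0, 0.08), 0.02), 0.5)
  stream <- Map(slab_case, paste0("n", 1:12), fracs, vd)
  conv <- convergence_run(stream, 20, m = 0, tol = 0)
  expect_false(conv$converged)
  expect_true(is.na(conv$n_converged))
  expect_equal(nrow(conv$trace), 12)
})

test_that("records without dose are rejected for calibration", {
  ph <- small_phantom()
  no_dose <- cohort_record("nd", "right", ph$ptv, ph$lung, prescription = 50.4)
  expect_error(prediction_errors(list(no_dose), 11, 20), "without dose")
  expect_error(calibrate_margin(list(), 20), "nonempty")
})
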