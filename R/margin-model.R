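#' One cohort case: structures, laterality, and (optionally) planned dose
#'
#' A calibration case carries the planned dose; a prediction-only case omits
#' it. A patient treated bilaterally is represented as two records, one per
#' side, each paired with its own ipsilateral lung.
#'
#' @param case_id Unique identifier.
#' @param laterality `"left"` or `"right"` (treated side).
#' @param ptv PTV [binary_mask()].
#' @param ipsilateral_lung Lung [binary_mask()] on the same grid as the PTV.
#' @param dose Optional [dose_grid()] of the clinical plan.
#' @param prescription Prescription in Gy(RBE); defaults to the dose grid's
#'   prescription when a dose is supplied.
#' @return An object of class `cohort_record`.
#' @export
cohort_record <- function(case_id, laterality, ptv, ipsilateral_lung,
                          dose = NULL, prescription = NULL) {
  laterality <- match.arg(laterality, c("left", "right"))
  stopifnot(inherits(ptv, "binary_mask"), inherits(ipsilateral_lung, "binary_mask"))
  stop_if_grid_mismatch(ptv, ipsilateral_lung, "ptv and ipsilateral lung")
  if (!is.null(dose)) {
    stopifnot(inherits(dose, "dose_grid"))
    if (is.null(prescription)) prescription <- dose$prescription
  }
  if (is.null(prescription) || !is.numeric(prescription) || prescription <= 0) {
    stop("cohort_record: a positive prescription in Gy(RBE) is required")
  }
  structure(list(case_id = as.character(case_id), laterality = laterality,
                 ptv = ptv, ipsilateral_lung = ipsilateral_lung,
                 dose = dose, prescription = as.numeric(prescription)),
            class = "cohort_record")
}

#' @export
print.cohort_record <- function(x, ...) {
  cat(sprintf("<cohort_record> %s (%s), %s, prescription %g Gy(RBE)\n",
              x$case_id, x$laterality,
              if (is.null(x$dose)) "contours only" else "with planned dose",
              x$prescription))
  invisible(x)
}

# Planned V_D of one record's ipsilateral lung in the reference frame:
# rescale the plan to the reference prescription, bring it onto the structure
# grid, and threshold.
case_planned_vd <- function(record, D, reference = 50.4) {
  if (is.null(record$dose)) {
    stop(sprintf("incomplete record: case %s has no dose grid", record$case_id))
  }
  dose <- rescale_to_reference(record$dose, reference)
  dose <- resample_dose_to_grid(dose, record$ptv$grid)
  volume_at_dose(dose, record$ipsilateral_lung, D)
}

# V(m) for one record over a margin vector, via a single distance transform.
case_v_of_m <- function(record, m_values) {
  d <- organ_distances_to_structure(record$ptv, record$ipsilateral_lung)
  vapply(m_values, function(m) mean(d <= m), numeric(1))
}

#' Prediction errors of V(m) against planned V_D over a cohort
#'
#' For each case the error is `V(m) - V_D` in percentage points of
#' ipsilateral-lung volume, with the planned dose rescaled to the reference
#' prescription before the DVH query. Returns the root-mean-square error (the
#' calibration objective), the mean error (a measure of systematic bias), and
#' the per-case table.
#'
#' @param cohort List of [cohort_record()]s, all with doses.
#' @param m Margin in mm.
#' @param D Dose level in Gy(RBE), in the reference frame.
#' @param reference Reference prescription in Gy(RBE) (default 50.4).
#' @return List with `rmse`, `me` (percentage points), and `per_case_errors`
#'   (data.frame: `case_id`, `v_m_pct`, `v_d_pct`, `error_pct`).
#' @export
prediction_errors <- function(cohort, m, D, reference = 50.4) {
  check_cohort(cohort, need_dose = TRUE)
  v_m <- vapply(cohort, function(r) case_v_of_m(r, m), numeric(1))
  v_d <- vapply(cohort, function(r) case_planned_vd(r, D, reference), numeric(1))
  err <- (v_m - v_d) * 100
  list(rmse = sqrt(mean(err^2)), me = mean(err),
       per_case_errors = data.frame(
         case_id = vapply(cohort, function(r) r$case_id, character(1)),
         v_m_pct = v_m * 100, v_d_pct = v_d * 100, error_pct = err))
}

#' Calibrate the margin for a dose level by RMSE minimisation
#'
#' Grid search for the margin `m_D` minimising the root-mean-square error of
#' the contour predictor V(m) against the planned `V_D` across the cohort.
#' Ties are broken toward the smallest margin (the most conservative
#' lung-sparing prediction).
#'
#' @param cohort List of [cohort_record()]s with doses.
#' @param D Dose level in Gy(RBE) (reference frame).
#' @param m_grid Ascending margins to search, mm (default -10 to 40 by 0.5;
#'   negative margins shrink the PTV).
#' @param reference Reference prescription in Gy(RBE) (default 50.4).
#' @return A `calibration_result`: `dose_level`, `margin_mm`, `rmse`, `me`
#'   (percentage points), `per_case_errors`, `rmse_by_margin` (the searched
#'   grid) and `trace` (empty; filled by [convergence_run()]).
#' @export
calibrate_margin <- function(cohort, D, m_grid = seq(-10, 40, by = 0.5),
                             reference = 50.4) {
  check_cohort(cohort, need_dose = TRUE)
  m_grid <- as.numeric(m_grid)
  if (length(m_grid) == 0L) stop("invalid input: m_grid is empty")
  if (is.unsorted(m_grid, strictly = TRUE)) stop("invalid input: m_grid must be strictly ascending")
  v_m <- vapply(cohort, function(r) case_v_of_m(r, m_grid), numeric(length(m_grid)))
  v_m <- t(matrix(v_m, nrow = length(m_grid)))   # cases x margins
  v_d <- vapply(cohort, function(r) case_planned_vd(r, D, reference), numeric(1))
  err <- (v_m - v_d) * 100                     # cases x margins, percentage points
  rmse_by_m <- sqrt(colMeans(err^2))
  best <- which.min(rmse_by_m)                 # which.min takes the first (smallest m) tie
  structure(list(
    dose_level = D,
    margin_mm = m_grid[best],
    rmse = rmse_by_m[[best]],
    me = mean(err[, best]),
    per_case_errors = data.frame(
      case_id = vapply(cohort, function(r) r$case_id, character(1)),
      v_m_pct = v_m[, best] * 100, v_d_pct = v_d * 100, error_pct = err[, best]),
    rmse_by_margin = data.frame(m = m_grid, rmse = unname(rmse_by_m)),
    reference = reference,
    trace = data.frame(n = integer(0), rmse = numeric(0))
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> D = %g Gy(RBE): m = %g mm, RMSE %.2f pp, ME %+.2f pp (n = %d)\n",
              x$dose_level, x$margin_mm, x$rmse, x$me, nrow(x$per_case_errors)))
  invisible(x)
}

#' Cohort-growth convergence of the calibration RMSE
#'
#' Re-evaluates the RMSE of V(m) against planned V_D as cases are added one
#' by one in the supplied order, and declares convergence at the first cohort
#' size `n >= n_floor` at which the RMSE differs by at most `tol` percentage
#' points from each of the previous `window` cohort sizes. This mirrors the
#' practice of growing the calibration cohort until the estimated prediction
#' uncertainty stops changing.
#'
#' @param cohort_stream Ordered list of [cohort_record()]s with doses.
#' @param D Dose level in Gy(RBE) (reference frame).
#' @param m Margin in mm (typically a calibrated `margin_mm`).
#' @param window Number of preceding cohort sizes compared (default 3).
#' @param tol Tolerance in percentage points (default 0.25).
#' @param n_floor Smallest cohort size at which convergence may be declared
#'   (default 10, the size of the initial calibration subset).
#' @param reference Reference prescription in Gy(RBE) (default 50.4).
#' @return List with `trace` (data.frame `n`, `rmse`), `converged` (logical)
#'   and `n_converged` (NA when the stream ends unconverged).
#' @export
convergence_run <- function(cohort_stream, D, m, window = 3L, tol = 0.25,
                            n_floor = 10L, reference = 50.4) {
  check_cohort(cohort_stream, need_dose = TRUE)
  window <- as.integer(window)
  if (window < 1L) stop("invalid input: window must be >= 1")
  if (length(cohort_stream) < window + 1L) {
    stop("invalid input: stream shorter than window + 1")
  }
  err <- vapply(cohort_stream, function(r) {
    (case_v_of_m(r, m) - case_planned_vd(r, D, reference)) * 100
  }, numeric(1))
  n_all <- seq_along(err)
  rmse <- sqrt(cumsum(err^2) / n_all)
  converged <- FALSE
  n_converged <- NA_integer_
  for (n in n_all) {
    if (n < max(n_floor, window + 1L)) next
    if (max(abs(rmse[n] - rmse[n - seq_len(window)])) <= tol) {
      converged <- TRUE
      n_converged <- n
      break
    }
  }
  list(trace = data.frame(n = n_all, rmse = rmse),
       converged = converged, n_converged = n_converged)
}

#' Dose-level to margin lookup table
#'
#' A margin model maps reference-frame dose levels (Gy(RBE)) to calibrated
#' expansion margins (mm). The shipped defaults are 11 mm for the
#' 20 Gy(RBE) level and 22 mm for the 5 Gy(RBE) level, at a reference
#' prescription of 50.4 Gy(RBE).
#'
#' @param margins_mm Named numeric vector; names are dose levels in Gy(RBE),
#'   values positive margins in mm.
#' @param reference Reference prescription in Gy(RBE).
#' @return An object of class `margin_model`.
#' @export
margin_model <- function(margins_mm, reference = 50.4) {
  if (length(margins_mm) == 0L || is.null(names(margins_mm)) ||
      any(!nzchar(names(margins_mm)))) {
    stop("margin_model: margins_mm must be a named numeric vector (names = dose levels)")
  }
  if (anyNA(suppressWarnings(as.numeric(names(margins_mm))))) {
    stop("margin_model: names must be numeric dose levels in Gy(RBE)")
  }
  structure(list(margins_mm = margins_mm, reference = reference),
            class = "margin_model")
}

#' @export
print.margin_model <- function(x, ...) {
  cat(sprintf("<margin_model> reference %g Gy(RBE)\n", x$reference))
  for (nm in names(x$margins_mm)) {
    cat(sprintf("  V_%s Gy(RBE)  <-  V(%g mm)\n", nm, x$margins_mm[[nm]]))
  }
  invisible(x)
}

#' The shipped default margin model
#'
#' Loads the packaged calibration: 11 mm for V_20Gy(RBE) and 22 mm for
#' V_5Gy(RBE) at the 50.4 Gy(RBE) reference prescription.
#'
#' @return A [margin_model()].
#' @export
default_margin_model <- function() {
  read_model_json(system.file("extdata", "default_model.json",
                              package = "margindose", mustWork = TRUE))
}

# Margin for a dose level from either model object.
margin_for_level <- function(model, D) {
  if (inherits(model, "calibration_result")) {
    if (!isTRUE(all.equal(model$dose_level, D))) {
      stop(sprintf("unknown dose level: calibration is for D = %g Gy(RBE), not %g",
                   model$dose_level, D))
    }
    return(model$margin_mm)
  }
  if (inherits(model, "margin_model")) {
    lev <- suppressWarnings(as.numeric(names(model$margins_mm)))
    hit <- which(abs(lev - D) < 1e-9)
    if (length(hit) != 1L) {
      stop(sprintf("unknown dose level: %g Gy(RBE) is not in the model (levels: %s)",
                   D, paste(lev, collapse = ", ")))
    }
    return(as.numeric(model$margins_mm[[hit]]))
  }
  stop("predict_volume: model must be a margin_model or calibration_result")
}

#' Predict a lung dose-volume metric from contours alone
#'
#' The contour-only prediction of `V_D`: the fraction of the ipsilateral lung
#' inside the PTV expanded by the model's calibrated margin for `D`. No dose
#' grid is consulted, so the prediction is available before any treatment
#' plan exists.
#'
#' @param ptv PTV [binary_mask()].
#' @param lung Ipsilateral lung [binary_mask()] on the same grid.
#' @param model A [margin_model()] or [calibrate_margin()] result containing
#'   the dose level `D`.
#' @param D Dose level in Gy(RBE) (reference frame).
#' @return Predicted `V_D` as a fraction in `[0, 1]`.
#' @export
predict_volume <- function(ptv, lung, model, D) {
  stopifnot(inherits(ptv, "binary_mask"), inherits(lung, "binary_mask"))
  stop_if_grid_mismatch(ptv, lung, "ptv and lung")
  m <- margin_for_level(model, D)
  d <- organ_distances_to_structure(ptv, lung)
  mean(d <= m)
}

check_cohort <- function(cohort, need_dose = FALSE) {
  if (!is.list(cohort) || length(cohort) == 0L) {
    stop("invalid input: cohort must be a nonempty list of cohort_record objects")
  }
  ok <- vapply(cohort, inherits, logical(1), what = "cohort_record")
  if (!all(ok)) stop("invalid input: cohort must contain only cohort_record objects")
  if (need_dose) {
    missing <- vapply(cohort, function(r) is.null(r$dose), logical(1))
    if (any(missing)) {
      stop(sprintf("incomplete record: case(s) without dose: %s",
                   paste(vapply(cohort[missing], function(r) r$case_id, character(1)),
                         collapse = ", ")))
    }
  }
  invisible(TRUE)
}
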