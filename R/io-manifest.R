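#' Cohort manifest
#'
#' A YAML file listing the cases of a cohort: id, treated side, prescription,
#' and the structure (and optionally dose) volumes on disk. A bilaterally
#' treated patient appears as two entries, one per side, each with its own
#' ipsilateral lung.
#'
#' @param path Manifest path (YAML).
#' @return `read_manifest` returns a data.frame with columns `case_id`,
#'   `laterality`, `prescription_Gy_RBE`, `ptv_path`, `lung_path`,
#'   `dose_path` (NA when absent), with relative paths resolved against the
#'   manifest's directory.
#' @export
read_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  entries <- if (!is.null(doc$cases)) doc$cases else doc
  if (length(entries) == 0L) stop("manifest: no cases")
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(NA_character_)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  df <- do.call(rbind, lapply(entries, function(e) {
    data.frame(case_id = as.character(e$case_id),
               laterality = as.character(e$laterality),
               prescription_Gy_RBE = as.numeric(e$prescription_Gy_RBE),
               ptv_path = resolve(e$ptv), lung_path = resolve(e$lung),
               dose_path = resolve(e$dose %||% NA),
               stringsAsFactors = FALSE)
  }))
  validate_manifest(df)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_manifest <- function(df) {
  if (anyDuplicated(df$case_id)) stop("manifest: case_ids must be unique")
  if (!all(df$laterality %in% c("left", "right"))) {
    stop("manifest: laterality must be 'left' or 'right'")
  }
  if (any(!is.finite(df$prescription_Gy_RBE)) || any(df$prescription_Gy_RBE <= 0)) {
    stop("manifest: prescriptions must be positive")
  }
  invisible(df)
}

#' @rdname read_manifest
#' @param entries Data.frame as returned by `read_manifest` (paths may be
#'   relative; they are written as given).
#' @export
write_manifest <- function(entries, path) {
  validate_manifest(entries)
  cases <- lapply(seq_len(nrow(entries)), function(i) {
    e <- as.list(entries[i, ])
    out <- list(case_id = e$case_id, laterality = e$laterality,
                prescription_Gy_RBE = e$prescription_Gy_RBE,
                ptv = e$ptv_path, lung = e$lung_path)
    if (!is.na(e$dose_path)) out$dose <- e$dose_path
    out
  })
  yaml::write_yaml(list(cases = cases), path)
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' Reads each entry's PTV and lung (NIfTI masks) and, when present, the dose
#' (NIfTI, or DICOM RT-DOSE for `.dcm` paths) into [cohort_record()]s. Dose
#' grids keep their native geometry; they are resampled onto the structure
#' grid at DVH time.
#'
#' @param manifest Path to a manifest, or the data.frame from
#'   [read_manifest()].
#' @return List of [cohort_record()]s.
#' @export
load_cohort <- function(manifest) {
  df <- if (is.character(manifest)) read_manifest(manifest) else validate_manifest(manifest)
  lapply(seq_len(nrow(df)), function(i) {
    e <- df[i, ]
    ptv <- read_mask_nifti(e$ptv_path)
    lung <- read_mask_nifti(e$lung_path)
    dose <- NULL
    if (!is.na(e$dose_path)) {
      dose <- if (grepl("\\.dcm$", e$dose_path, ignore.case = TRUE)) {
        read_rtdose(e$dose_path, prescription = e$prescription_Gy_RBE)
      } else {
        read_dose_nifti(e$dose_path, prescription = e$prescription_Gy_RBE)
      }
    }
    cohort_record(e$case_id, e$laterality, ptv, lung, dose = dose,
                  prescription = e$prescription_Gy_RBE)
  })
}

#' Margin-model JSON round trip
#'
#' The model asset format: reference prescription, dose-level to margin map,
#' and a format version. The packaged default model ships in this format.
#'
#' @param model A [margin_model()].
#' @param path JSON path.
#' @return `read_model_json` returns a [margin_model()]; the writer returns
#'   the path invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "margin_model"))
  jsonlite::write_json(
    list(format_version = "1",
         reference_rx_Gy_RBE = model$reference,
         margins_mm = as.list(model$margins_mm)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$margins_mm)) stop("model JSON: missing margins_mm")
  margin_model(unlist(doc$margins_mm), reference = doc$reference_rx_Gy_RBE %||% 50.4)
}

#' Serialise a calibration result as JSON
#'
#' Writes the dose level, calibrated margin, RMSE and mean error (percentage
#' points), the per-case error table, and the convergence trace if one has
#' been attached.
#'
#' @param result A `calibration_result` from [calibrate_margin()].
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(dose_level_Gy_RBE = result$dose_level,
         margin_mm = result$margin_mm,
         rmse_pct = result$rmse,
         me_pct = result$me,
         reference_rx_Gy_RBE = result$reference,
         per_case = result$per_case_errors,
         trace = result$trace),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Write a DVH or V(m) curve as CSV
#'
#' @param curve Data.frame from [dvh_curve()] or [v_of_m_curve()].
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
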