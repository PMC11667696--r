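# The cohort container: three linked data frames (patients, WSIs, ROIs)
# with referential integrity and controlled vocabularies enforced.

.patient_required <- c("patient_id", "site_id", "age", "sex", "race",
                       "ethnicity", "bc_stage")
.patient_optional <- c("tnm_t", "tnm_n", "tnm_m", "tumor_size_cm")
.wsi_required <- c("wsi_id", "patient_id")
.wsi_optional <- c("scanner_make_model", "image_resolution_um_per_px",
                   "objective_magnification", "numerical_aperture")
.roi_required <- c("roi_id", "wsi_id", "evaluable", "stils_density_pct")
.roi_optional <- c("tumor_region_type", "stroma_pct", "pitfalls")

#' Construct a cohort of patients, WSIs and ROI annotations
#'
#' Bundles the three tables of an annotation-study cohort into a validated
#' `cohort` object. Each whole slide image (WSI) belongs to one patient (a
#' patient may contribute several sequential sections); each region of
#' interest (ROI) belongs to one WSI and is either evaluable for the sTILs
#' assessment — in which case it carries an sTILs density in \[0, 100\] — or
#' not evaluable, in which case it carries none.
#'
#' Missing values are plain `NA` throughout (written as empty fields on
#' disk). The `pitfalls` column of `rois` holds zero or more pitfall labels
#' joined by `";"`.
#'
#' @param patients Data frame with columns `patient_id`, `site_id`, `age`,
#'   `sex`, `race`, `ethnicity`, `bc_stage` and optionally `tnm_t`, `tnm_n`,
#'   `tnm_m`, `tumor_size_cm` plus any extra attributes.
#' @param wsis Data frame with columns `wsi_id`, `patient_id` and optional
#'   scanner metadata.
#' @param rois Data frame with columns `roi_id`, `wsi_id`, `evaluable`,
#'   `stils_density_pct` and optionally `tumor_region_type`, `stroma_pct`,
#'   `pitfalls`.
#' @param validate Run [validate_cohort()] (default `TRUE`).
#' @return An object of class `cohort`: a list with elements `patients`,
#'   `wsis`, `rois`.
#' @seealso [harmonize_cohort()] to build a cohort from raw tables,
#'   [generate_cohort()] for synthetic cohorts.
#' @export
cohort <- function(patients, wsis, rois, validate = TRUE) {
  fill <- function(df, optional, template) {
    for (col in optional) {
      if (!col %in% names(df)) df[[col]] <- rep(template, nrow(df))
    }
    df
  }
  patients <- fill(as.data.frame(patients), .patient_optional, NA_character_)
  if (!is.numeric(patients$tumor_size_cm))
    patients$tumor_size_cm <- as.numeric(patients$tumor_size_cm)
  wsis <- fill(as.data.frame(wsis), .wsi_optional, NA)
  rois <- fill(as.data.frame(rois), .roi_optional, NA)
  if (!"pitfalls" %in% names(rois)) rois$pitfalls <- NA_character_
  rois$pitfalls <- as.character(rois$pitfalls)
  rownames(patients) <- rownames(wsis) <- rownames(rois) <- NULL
  obj <- structure(list(patients = patients, wsis = wsis, rois = rois),
                   class = "cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' Validate a cohort's invariants
#'
#' Checks required columns, identifier uniqueness, referential integrity
#' (WSI to patient, ROI to WSI), controlled vocabularies, value ranges, and
#' the evaluability contract: an ROI has an sTILs density if and only if it
#' is evaluable. All violations are collected and reported together.
#'
#' @param x A `cohort` object (or plain list with the three tables).
#' @return `x`, invisibly; stops with a message listing every violation
#'   (with offending identifiers) otherwise.
#' @export
validate_cohort <- function(x) {
  p <- x$patients; w <- x$wsis; r <- x$rois
  errs <- character()
  add <- function(...) errs[[length(errs) + 1L]] <<- sprintf(...)

  miss <- setdiff(.patient_required, names(p))
  if (length(miss)) add("patients: missing columns %s", toString(miss))
  miss <- setdiff(.wsi_required, names(w))
  if (length(miss)) add("wsis: missing columns %s", toString(miss))
  miss <- setdiff(.roi_required, names(r))
  if (length(miss)) add("rois: missing columns %s", toString(miss))
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  dup <- function(ids, what) {
    d <- unique(ids[duplicated(ids)])
    if (length(d)) add("duplicate %s: %s", what, toString(d))
  }
  dup(p$patient_id, "patient_id")
  dup(w$wsi_id, "wsi_id")
  dup(r$roi_id, "roi_id")

  orphan <- setdiff(w$patient_id, p$patient_id)
  if (length(orphan))
    add("wsis reference unknown patient_id: %s", toString(orphan))
  orphan <- setdiff(r$wsi_id, w$wsi_id)
  if (length(orphan))
    add("rois reference unknown wsi_id: %s", toString(orphan))

  if (any(!is.na(p$age) & p$age < 0))
    add("negative age for patient(s): %s",
        toString(p$patient_id[!is.na(p$age) & p$age < 0]))
  check_vocab <- function(values, allowed, field) {
    bad <- !is.na(values) & !values %in% allowed
    if (any(bad))
      add("patients.%s outside vocabulary: %s", field,
          toString(unique(values[bad])))
  }
  check_vocab(p$sex, .sex_levels, "sex")
  check_vocab(p$race, .race_levels, "race")
  check_vocab(p$ethnicity, .ethnicity_levels, "ethnicity")
  check_vocab(p$bc_stage, .stage_levels, "bc_stage")

  if (!is.logical(r$evaluable) || anyNA(r$evaluable))
    add("rois.evaluable must be TRUE/FALSE with no missing values")
  rng <- function(values, field) {
    bad <- !is.na(values) & (values < 0 | values > 100)
    if (any(bad))
      add("rois.%s outside [0,100] for roi(s): %s", field,
          toString(r$roi_id[bad]))
  }
  rng(r$stils_density_pct, "stils_density_pct")
  rng(r$stroma_pct, "stroma_pct")
  if (is.logical(r$evaluable) && !anyNA(r$evaluable)) {
    bad <- !r$evaluable & !is.na(r$stils_density_pct)
    if (any(bad))
      add("sTILs density present on not-evaluable roi(s): %s",
          toString(r$roi_id[bad]))
    bad <- r$evaluable & is.na(r$stils_density_pct)
    if (any(bad))
      add("sTILs density missing on evaluable roi(s): %s",
          toString(r$roi_id[bad]))
  }

  if (length(errs))
    stop("cohort validation failed:\n", paste("-", errs, collapse = "\n"),
         call. = FALSE)
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  n_eval <- sum(x$rois$evaluable)
  cat(sprintf(
    "<cohort> %d patients at %d site(s), %d WSIs, %d ROIs (%d evaluable)\n",
    nrow(x$patients), length(unique(x$patients$site_id)),
    nrow(x$wsis), nrow(x$rois), n_eval))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  structure(list(
    n_patients = nrow(object$patients),
    n_wsis = nrow(object$wsis),
    n_rois = nrow(object$rois),
    n_evaluable = sum(object$rois$evaluable),
    missingness = missingness_table(object),
    demographics = demographic_summary(object),
    stages = stage_distribution(object)
  ), class = "summary.cohort")
}

#' @export
print.summary.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d WSIs, %d ROIs (%d evaluable)\n\n",
              x$n_patients, x$n_wsis, x$n_rois, x$n_evaluable))
  cat("Missingness (% of patients):\n")
  print(x$missingness, row.names = FALSE)
  cat("\nStage distribution:\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

# Closed decade bins [1-10], [11-20], ... used for reporting and retention.
age_decade_bin <- function(age) {
  a <- floor(age)
  lo <- pmax((a - 1) %/% 10, 0) * 10 + 1
  ifelse(is.na(a), NA_character_, sprintf("%d-%d", lo, lo + 9))
}
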