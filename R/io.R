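# On-disk layout: a cohort directory holds patients.csv, wsis.csv and
# rois.csv (UTF-8, comma-separated, header row, empty field = missing —
# never a literal "NA"). Batch plans export as a delimited table plus a
# JSON sidecar; every CLI run writes a JSON manifest.

.cohort_files <- c(patients = "patients.csv", wsis = "wsis.csv",
                   rois = "rois.csv")

.numeric_cols <- list(
  patients = c("age", "tumor_size_cm"),
  wsis = c("image_resolution_um_per_px", "objective_magnification",
           "numerical_aperture"),
  rois = c("stils_density_pct", "stroma_pct"))

#' Write a cohort to a directory of delimited tables
#'
#' Writes `patients.csv`, `wsis.csv` and `rois.csv` (comma-separated,
#' UTF-8, header row); missing values become empty fields. `write_cohort()`
#' followed by [read_cohort()] is the identity on harmonized cohorts.
#'
#' @param cohort A [cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(.cohort_files)) {
    utils::write.csv(cohort[[tab]], file.path(dir, .cohort_files[[tab]]),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Read a cohort from a directory of delimited tables
#'
#' Reads the three-table layout written by [write_cohort()]. Required
#' headers are checked by name; numeric columns must hold bare decimals
#' (a unit-bearing value like `"25.0%"` is a format error reported with
#' file, line and column). Empty fields are the missing sentinel.
#'
#' @param dir Directory holding `patients.csv`, `wsis.csv`, `rois.csv`.
#' @param validate Run [validate_cohort()] on the result (default `TRUE`).
#' @return A `cohort`.
#' @export
read_cohort <- function(dir, validate = TRUE) {
  tabs <- lapply(names(.cohort_files), function(tab) {
    path <- file.path(dir, .cohort_files[[tab]])
    if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
    df <- utils::read.csv(path, colClasses = "character", na.strings = "",
                          fileEncoding = "UTF-8", check.names = TRUE)
    required <- switch(tab, patients = .patient_required,
                       wsis = .wsi_required, rois = .roi_required)
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop(sprintf("%s: missing required header(s): %s", path,
                   toString(miss)), call. = FALSE)
    for (col in intersect(.numeric_cols[[tab]], names(df))) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & is.na(num))
      if (length(bad))
        stop(sprintf(
          "%s, line %d, column %s: cannot parse '%s' as a bare number",
          path, bad[1] + 1L, col, df[[col]][bad[1]]), call. = FALSE)
      df[[col]] <- num
    }
    if (tab == "rois" && "evaluable" %in% names(df)) {
      ev <- toupper(trimws(df$evaluable))
      val <- rep(NA, nrow(df))
      val[ev %in% "TRUE"] <- TRUE
      val[ev %in% "FALSE"] <- FALSE
      bad <- which(!is.na(df$evaluable) & is.na(val))
      if (length(bad))
        stop(sprintf(
          "%s, line %d, column evaluable: expected TRUE/FALSE, got '%s'",
          path, bad[1] + 1L, df$evaluable[bad[1]]), call. = FALSE)
      df$evaluable <- val
    }
    df
  })
  names(tabs) <- names(.cohort_files)
  cohort(tabs$patients, tabs$wsis, tabs$rois, validate = validate)
}

#' Export a batch plan
#'
#' Writes the ranked, batched cases as a delimited table with columns
#' `rank`, `wsi_id`, `patient_id`, the four scores and `batch`, plus a
#' JSON sidecar (`<stem>.json`) echoing the configuration, the full
#' ranking and the deduplication exclusion list.
#'
#' @param plan A [prioritize_cases()] batch plan.
#' @param path Output CSV path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_batch_plan <- function(plan, path) {
  cols <- c("rank", "wsi_id", "patient_id", .score_cols, "batch")
  utils::write.csv(plan$batches[, cols], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  sidecar <- sub("\\.[^.]*$", "", path)
  sidecar <- paste0(sidecar, ".json")
  cfg <- unclass(plan$config)
  cfg$binning <- list(low_max_pct = cfg$binning$low_max_pct,
                      medium_max_pct = cfg$binning$medium_max_pct)
  jsonlite::write_json(
    list(config = cfg,
         excluded_duplicates = plan$excluded_duplicates,
         ranked = plan$ranked),
    sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the subcommand, the fully
#' resolved configuration (defaults included), MD5 digests of the input
#' files, the tool version, the seed(s) and a timestamp.
#'
#' @param dir Directory to write `run_manifest.json` into.
#' @param command Subcommand name.
#' @param config Fully resolved configuration object (list-like).
#' @param inputs Character vector of input file paths (digested).
#' @param seed Integer seed(s) used, or `NULL` for deterministic commands.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, config = NULL,
                               inputs = character(), seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- inputs[file.exists(inputs)]
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else stats::setNames(list(), character())
  cfg <- if (!is.null(config)) unclass(config) else NULL
  if (!is.null(cfg$binning))
    cfg$binning <- list(low_max_pct = cfg$binning$low_max_pct,
                        medium_max_pct = cfg$binning$medium_max_pct)
  manifest <- list(
    command = command,
    tool = "stilsort",
    version = as.character(utils::packageVersion("stilsort")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_digests = digests,
    config = cfg)
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read or write a synthetic-cohort configuration as JSON
#'
#' @param path Path to a JSON file.
#' @param config A [synthetic_config()].
#' @return `read_synthetic_config()` returns a `synthetic_config`;
#'   `write_synthetic_config()` returns `path` invisibly.
#' @export
read_synthetic_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$n_patients_per_site <- unlist(raw$n_patients_per_site)
  for (key in c("sex_probs", "stage_probs", "density_mixture",
                "pitfall_rates", "stage_missing_prob", "race_missing_prob",
                "ethnicity_missing_prob", "multi_wsi_fraction")) {
    if (is.list(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  for (key in c("race_probs", "ethnicity_probs")) {
    if (is.list(raw[[key]])) raw[[key]] <- lapply(raw[[key]], unlist)
  }
  if (!is.null(raw$age_model)) {
    am <- raw$age_model
    raw$age_model <- if (all(c("mean", "sd", "min", "max") %in% names(am)))
      as.list(am) else lapply(am, as.list)
  }
  do.call(synthetic_config, raw[intersect(names(raw),
                                          names(formals(synthetic_config)))])
}

#' @rdname read_synthetic_config
#' @export
write_synthetic_config <- function(config, path) {
  jsonlite::write_json(listify_named(unclass(config)), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
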