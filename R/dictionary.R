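# Controlled vocabularies and the default data dictionary.
# Raw values coded as unknown ({Unknown, NA, N/A, ""} and case variants) all
# normalize to the single missing sentinel, which is R's NA and is rendered
# as an empty field on disk.

.missing_tokens <- c("", "na", "n/a", "unknown", "unk", "not available",
                     "not reported", "missing", "nan", "null")

.race_levels <- c("White", "Black or African American", "Asian",
                  "American Indian or Alaska Native",
                  "Native Hawaiian or Other Pacific Islander", "Other")

.ethnicity_levels <- c("Hispanic or Latino", "Not Hispanic or Latino")

.sex_levels <- c("F", "M")

.stage_levels <- c("I", "II", "III", "IV")

.density_bins <- c("low", "medium", "high")

is_missing_token <- function(x) {
  is.na(x) | tolower(trimws(as.character(x))) %in% .missing_tokens
}

#' Default data dictionary for cohort harmonization
#'
#' Describes, for each of the three input tables (`patients`, `wsis`,
#' `rois`), the expected columns: their type (`id`, `numeric`, `logical`,
#' `categorical`, `tnm`, `pitfall_list`, `character`), the allowed values of
#' categoricals, and alias maps from raw spellings to dictionary terms.
#' `column_aliases` maps raw header names onto canonical column names.
#' Values coded as unknown (`Unknown`, `NA`, `N/A`, empty, and case
#' variants) are always normalized to the missing sentinel, regardless of
#' type. Columns not described by the dictionary are carried through
#' untouched (the open "extra" attributes of a patient record).
#'
#' The returned object is a plain nested list and can be serialized to/from
#' JSON with [read_data_dictionary()] to replace any vocabulary or alias.
#'
#' @return A nested list with elements `patients`, `wsis`, `rois`.
#' @seealso [harmonize_cohort()]
#' @export
default_data_dictionary <- function() {
  list(
    patients = list(
      column_aliases = list(pid = "patient_id", subject_id = "patient_id",
                            site = "site_id", institution = "site_id",
                            stage = "bc_stage", bcs = "bc_stage"),
      fields = list(
        patient_id = list(type = "id"),
        site_id = list(type = "id"),
        age = list(type = "numeric", min = 0),
        sex = list(type = "categorical", allowed = .sex_levels,
                   aliases = list("female" = "F", "f" = "F",
                                  "male" = "M", "m" = "M")),
        race = list(type = "categorical", allowed = .race_levels,
                    aliases = list(
                      "aa" = "Black or African American",
                      "black" = "Black or African American",
                      "african american" = "Black or African American",
                      "black or african-american" = "Black or African American",
                      "caucasian" = "White", "w" = "White",
                      "other race" = "Other")),
        ethnicity = list(type = "categorical", allowed = .ethnicity_levels,
                         aliases = list(
                           "hispanic" = "Hispanic or Latino",
                           "latino" = "Hispanic or Latino",
                           "non-hispanic" = "Not Hispanic or Latino",
                           "not hispanic" = "Not Hispanic or Latino",
                           "non hispanic or latino" = "Not Hispanic or Latino")),
        tnm_t = list(type = "tnm"),
        tnm_n = list(type = "tnm"),
        tnm_m = list(type = "tnm"),
        bc_stage = list(type = "categorical", allowed = .stage_levels,
                        aliases = list("1" = "I", "2" = "II", "3" = "III",
                                       "4" = "IV", "ia" = "I", "ib" = "I",
                                       "iia" = "II", "iib" = "II",
                                       "iiia" = "III", "iiib" = "III",
                                       "iiic" = "III")),
        tumor_size_cm = list(type = "numeric", min = 0)
      )
    ),
    wsis = list(
      column_aliases = list(slide_id = "wsi_id", image_id = "wsi_id",
                            pid = "patient_id", subject_id = "patient_id",
                            scanner = "scanner_make_model",
                            resolution = "image_resolution_um_per_px",
                            magnification = "objective_magnification"),
      fields = list(
        wsi_id = list(type = "id"),
        patient_id = list(type = "id"),
        scanner_make_model = list(type = "character"),
        image_resolution_um_per_px = list(type = "numeric", min = 0,
                                          exclusive_min = TRUE),
        objective_magnification = list(type = "numeric", min = 0,
                                       exclusive_min = TRUE),
        numerical_aperture = list(type = "numeric", min = 0,
                                  exclusive_min = TRUE)
      )
    ),
    rois = list(
      column_aliases = list(region_id = "roi_id", slide_id = "wsi_id",
                            image_id = "wsi_id",
                            stils = "stils_density_pct",
                            stils_density = "stils_density_pct",
                            density = "stils_density_pct",
                            stroma = "stroma_pct"),
      fields = list(
        roi_id = list(type = "id"),
        wsi_id = list(type = "id"),
        evaluable = list(type = "logical",
                         aliases = list("evaluable" = TRUE, "yes" = TRUE,
                                        "1" = TRUE, "not evaluable" = FALSE,
                                        "no" = FALSE, "0" = FALSE)),
        stils_density_pct = list(type = "numeric", min = 0, max = 100),
        tumor_region_type = list(type = "character"),
        stroma_pct = list(type = "numeric", min = 0, max = 100),
        pitfalls = list(type = "pitfall_list",
                        allowed = names(default_rarity_map()),
                        aliases = list(
                          "cis" = "Carcinoma In Situ",
                          "dcis" = "Carcinoma In Situ",
                          "necrosis" = "Necrosis/Fibrin",
                          "fibrin" = "Necrosis/Fibrin",
                          "vessels" = "Nerves/Vessels",
                          "nerves" = "Nerves/Vessels",
                          "fat" = "Adipocytes"))
      )
    )
  )
}

#' Read or write a data dictionary as JSON
#'
#' @param path Path to a JSON file.
#' @param dictionary A dictionary list as returned by
#'   [default_data_dictionary()].
#' @return `read_data_dictionary()` returns the dictionary list;
#'   `write_data_dictionary()` returns `path` invisibly.
#' @export
read_data_dictionary <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' @rdname read_data_dictionary
#' @export
write_data_dictionary <- function(dictionary, path) {
  jsonlite::write_json(dictionary, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# Split a semicolon-joined pitfall field into a character vector of labels.
parse_pitfalls <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(trimws(x))) return(character())
  out <- trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1L]])
  out[nzchar(out)]
}
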