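# Harmonize raw site exports onto the data dictionary: rename columns,
# map value aliases to controlled terms, coerce types, normalize every
# unknown-coded value to the missing sentinel, and log each substitution.

#' Harmonize raw cohort tables to the data dictionary
#'
#' Takes raw patient / WSI / ROI tables (as read from each site's delimited
#' export) and produces a validated [cohort()]. For every dictionary-described
#' column the raw values are: mapped through the alias table (e.g. `"AA"` to
#' `"Black or African American"`), coerced to the expected type, or — when
#' they are unknown-coded or cannot be resolved — set to the missing
#' sentinel. Unrecognized categorical values become missing rather than
#' erroring, so vocabulary drift surfaces in the log, not as a hard stop;
#' structural problems (duplicate or dangling identifiers, densities on
#' not-evaluable ROIs) do stop with a validation error.
#'
#' When `bc_stage` is missing but the TNM triple is present, the stage is
#' filled in via [map_tnm_to_stage()].
#'
#' Harmonization is idempotent: applied to its own output it changes nothing
#' and logs nothing.
#'
#' @param patients,wsis,rois Raw data frames (headers included).
#' @param dictionary Data dictionary, default [default_data_dictionary()].
#' @return A validated `cohort`; the character vector of substitutions is
#'   attached as `attr(, "harmonization_log")` (one line per substitution,
#'   `table[row].column: 'raw' -> 'new'`).
#' @examples
#' raw <- data.frame(patient_id = "P1", site_id = "A", age = 61,
#'                   sex = "Female", race = "AA", ethnicity = "Unknown",
#'                   bc_stage = "")
#' w <- data.frame(wsi_id = "W1", patient_id = "P1")
#' r <- data.frame(roi_id = "R1", wsi_id = "W1", evaluable = "Evaluable",
#'                 stils_density_pct = 12)
#' coh <- harmonize_cohort(raw, w, r)
#' attr(coh, "harmonization_log")
#' @export
harmonize_cohort <- function(patients, wsis, rois,
                             dictionary = default_data_dictionary()) {
  log_env <- new.env(parent = emptyenv())
  log_env$lines <- character()

  p <- harmonize_table(as.data.frame(patients), dictionary$patients,
                       "patients", log_env)
  w <- harmonize_table(as.data.frame(wsis), dictionary$wsis, "wsis", log_env)
  r <- harmonize_table(as.data.frame(rois), dictionary$rois, "rois", log_env)

  # Fill aggregated stage from TNM where absent.
  if (all(c("tnm_t", "tnm_n", "tnm_m") %in% names(p))) {
    need <- is.na(p$bc_stage)
    if (any(need)) {
      mapped <- map_tnm_to_stage(p$tnm_t[need], p$tnm_n[need], p$tnm_m[need])
      got <- !is.na(mapped)
      if (any(got)) {
        rows <- which(need)[got]
        p$bc_stage[rows] <- mapped[got]
        log_env$lines <- c(log_env$lines, sprintf(
          "patients[%d].bc_stage: TNM (%s,%s,%s) -> '%s'",
          rows, p$tnm_t[rows], p$tnm_n[rows], p$tnm_m[rows], mapped[got]))
      }
    }
  }

  out <- cohort(p, w, r, validate = TRUE)
  attr(out, "harmonization_log") <- log_env$lines
  out
}

harmonize_table <- function(df, spec, table_name, log_env) {
  note <- function(rows, field, raw, new) {
    raw <- as.character(raw); new <- as.character(new)
    log_env$lines <- c(log_env$lines, sprintf(
      "%s[%d].%s: '%s' -> %s", table_name, rows, field,
      ifelse(is.na(raw), "", raw),
      ifelse(is.na(new), "<missing>", sQuote(new))))
  }

  # Canonicalize column names via aliases (case-insensitive).
  aliases <- spec$column_aliases
  if (length(aliases)) {
    lower <- tolower(names(df))
    for (i in seq_along(aliases)) {
      hit <- lower == tolower(names(aliases)[i])
      if (any(hit) && !aliases[[i]] %in% names(df))
        names(df)[hit] <- aliases[[i]]
    }
  }

  for (field in names(spec$fields)) {
    fs <- spec$fields[[field]]
    if (!field %in% names(df)) {
      df[[field]] <- switch(fs$type, numeric = NA_real_, logical = NA,
                            NA_character_)
      next
    }
    raw <- df[[field]]
    raw_chr <- trimws(as.character(raw))
    missing <- is_missing_token(raw)
    # Log explicit unknown-codings (non-empty tokens) collapsing to missing.
    coded <- missing & !is.na(raw) & nzchar(raw_chr)
    if (any(coded)) note(which(coded), field, raw[coded], NA)

    new <- switch(fs$type,
      id = ,
      character = {
        v <- raw_chr
        v[missing] <- NA_character_
        changed <- !missing & !is.na(raw) & v != as.character(raw)
        if (any(changed)) note(which(changed), field, raw[changed], v[changed])
        v
      },
      numeric = {
        v <- suppressWarnings(as.numeric(raw_chr))
        v[missing] <- NA_real_
        bad <- !missing & is.na(v)           # unparseable (e.g. "25.0%")
        oob <- rep(FALSE, length(v))
        if (!is.null(fs$min)) {
          oob <- oob | (!is.na(v) &
            if (isTRUE(fs$exclusive_min)) v <= fs$min else v < fs$min)
        }
        if (!is.null(fs$max)) oob <- oob | (!is.na(v) & v > fs$max)
        bad <- bad | oob
        if (any(bad)) {
          note(which(bad), field, raw[bad], NA)
          v[bad] <- NA_real_
        }
        v
      },
      logical = {
        v <- rep(NA, length(raw))
        if (is.logical(raw)) v <- raw
        else {
          key <- tolower(raw_chr)
          amap <- fs$aliases
          v[key %in% c("true", "t")] <- TRUE
          v[key %in% c("false", "f")] <- FALSE
          for (a in names(amap)) v[key == a] <- isTRUE(amap[[a]])
          changed <- !missing & !is.na(v) &
            tolower(as.character(v)) != key
          if (any(changed)) note(which(changed), field, raw[changed],
                                 v[changed])
        }
        v[missing] <- NA
        unres <- !missing & is.na(v)
        if (any(unres)) note(which(unres), field, raw[unres], NA)
        v
      },
      categorical = {
        v <- map_categorical(raw_chr, fs)
        v[missing] <- NA_character_
        changed <- !missing & (is.na(v) | v != as.character(raw))
        if (any(changed)) note(which(changed), field, raw[changed],
                               v[changed])
        v
      },
      tnm = {
        v <- toupper(raw_chr)
        v[missing] <- NA_character_
        changed <- !missing & v != as.character(raw)
        if (any(changed)) note(which(changed), field, raw[changed], v[changed])
        v
      },
      pitfall_list = {
        v <- vapply(seq_along(raw), function(i) {
          if (missing[i]) return(NA_character_)
          labels <- parse_pitfalls(raw_chr[i])
          if (!length(labels)) return(NA_character_)
          mapped <- map_categorical(labels, fs)
          mapped[is.na(mapped)] <- labels[is.na(mapped)]  # keep unlisted labels
          paste(mapped, collapse = ";")
        }, character(1))
        changed <- !missing & !is.na(raw) & v != as.character(raw) &
          !is.na(v)
        if (any(changed)) note(which(changed), field, raw[changed], v[changed])
        v
      },
      stop("unknown dictionary type: ", fs$type))
    df[[field]] <- new
  }
  df
}

# Map raw categorical strings onto allowed terms: exact term, case-variant
# of a term, or alias (case-insensitive). Unresolved values become NA.
map_categorical <- function(x, fs) {
  allowed <- fs$allowed
  out <- rep(NA_character_, length(x))
  exact <- x %in% allowed
  out[exact] <- x[exact]
  lower_allowed <- stats::setNames(allowed, tolower(allowed))
  ci <- !exact & tolower(x) %in% names(lower_allowed)
  out[ci] <- unname(lower_allowed[tolower(x[ci])])
  if (length(fs$aliases)) {
    amap <- stats::setNames(unlist(fs$aliases, use.names = FALSE),
                            tolower(names(fs$aliases)))
    hit <- is.na(out) & tolower(x) %in% names(amap)
    out[hit] <- unname(amap[tolower(x[hit])])
  }
  out
}

#' Write the harmonization log to a file
#'
#' @param cohort A cohort returned by [harmonize_cohort()].
#' @param path Output path; one substitution per line.
#' @return `path`, invisibly.
#' @export
write_harmonization_log <- function(cohort, path) {
  writeLines(attr(cohort, "harmonization_log") %||% character(), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
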