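# TNM category -> aggregated anatomic breast-cancer stage (I-IV).
# The lookup follows the AJCC 8th-edition anatomic stage groups, collapsed
# to their roman-numeral main stage. It is exposed as a data frame so a
# deployment can ship a replacement table via `stage_table=`.

#' Anatomic stage-group lookup table
#'
#' One row per (T, N, M) combination of the main TNM categories, with the
#' aggregated anatomic stage it maps to. Subcategories (T1a, N1mi, pT2, ...)
#' are normalized onto main categories before lookup. Stage 0 disease
#' (Tis N0 M0) has no aggregated stage in the I-IV set and maps to missing,
#' as does the undefined combination T0 N0 M0.
#'
#' @return A data frame with columns `t`, `n`, `m`, `stage`.
#' @export
anatomic_stage_table <- function() {
  grid <- expand.grid(t = c("T0", "T1", "T2", "T3", "T4", "TIS"),
                      n = c("N0", "N1", "N2", "N3"),
                      m = c("M0", "M1"),
                      stringsAsFactors = FALSE)
  stage_m0 <- function(t, n) {
    if (t == "TIS") return(if (n == "N0") NA_character_ else NA_character_)
    switch(n,
      N0 = switch(t, T0 = NA_character_, T1 = "I", T2 = "II", T3 = "II",
                  T4 = "III"),
      N1 = switch(t, T0 = "II", T1 = "II", T2 = "II", T3 = "III",
                  T4 = "III"),
      N2 = "III",
      N3 = "III")
  }
  grid$stage <- ifelse(grid$m == "M1", "IV",
                       mapply(stage_m0, grid$t, grid$n))
  grid
}

# Normalize one vector of raw T/N/M strings to main categories.
# Strips clinical/pathologic prefixes (c, p, y, yc, yp), uppercases, and
# drops subcategory suffixes (a/b/c/d/mi). Unrecognized non-missing values
# raise an error naming the string.
normalize_tnm <- function(x, axis = c("t", "n", "m")) {
  axis <- match.arg(axis)
  raw <- as.character(x)
  out <- rep(NA_character_, length(raw))
  keep <- !is_missing_token(raw)
  if (!any(keep)) return(out)
  v <- toupper(trimws(raw[keep]))
  v <- sub("^Y?[CP]?", "", v)
  pattern <- switch(axis,
                    t = "^T(IS|[0-4])([A-D]|MI)?$",
                    n = "^N([0-3])(MI|[A-C])?$",
                    m = "^M([01])$")
  ok <- grepl(pattern, v)
  if (any(!ok)) {
    stop(sprintf("unrecognized %s category: %s", toupper(axis),
                 paste(sQuote(unique(raw[keep][!ok])), collapse = ", ")),
         call. = FALSE)
  }
  main <- sub(pattern, "\\1", v)
  out[keep] <- paste0(toupper(axis), main)
  out
}

#' Map TNM categories to aggregated anatomic breast-cancer stage
#'
#' Collapses T/N/M categories to the aggregated anatomic stages I-IV using
#' [anatomic_stage_table()]. Distant metastasis (`M1`) always yields stage
#' IV, whatever T and N are (including missing). Otherwise a missing
#' indispensable component yields the missing stage. The function is
#' vectorized and total on valid categories plus missing.
#'
#' @param t,n,m Character vectors of T, N and M categories (e.g. `"T1"`,
#'   `"pT2b"`, `"N1mi"`, `"M0"`); unknown-coded values count as missing.
#' @param stage_table Replacement lookup table with columns `t`, `n`, `m`,
#'   `stage` (defaults to [anatomic_stage_table()]).
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"` or `NA`.
#' @examples
#' map_tnm_to_stage("T1", "N0", "M0")   # "I"
#' map_tnm_to_stage("T3", "N2", "M0")   # "III"
#' map_tnm_to_stage(NA, NA, "M1")       # "IV"
#' @export
map_tnm_to_stage <- function(t, n, m, stage_table = anatomic_stage_table()) {
  len <- max(length(t), length(n), length(m))
  t <- normalize_tnm(rep_len(t, len), "t")
  n <- normalize_tnm(rep_len(n, len), "n")
  m <- normalize_tnm(rep_len(m, len), "m")
  out <- rep(NA_character_, len)
  out[!is.na(m) & m == "M1"] <- "IV"
  need <- is.na(out) & !is.na(t) & !is.na(n) & !is.na(m)
  if (any(need)) {
    key <- paste(t[need], n[need], m[need])
    tab <- stats::setNames(stage_table$stage,
                           paste(stage_table$t, stage_table$n, stage_table$m))
    out[need] <- unname(tab[key])
  }
  out
}
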