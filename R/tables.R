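# Patient-level summary tables: missingness, demographics, stage
# distribution — overall and per site. Percentages use the full patient
# denominator and are rounded to one decimal place for display columns.

site_levels <- function(cohort) sort(unique(cohort$patients$site_id))

#' Missingness of selected patient fields
#'
#' Percentage of patients missing each field, overall and per site.
#' Unknown-coded raw values were already normalized to missing by
#' harmonization, so they count here.
#'
#' @param cohort A [cohort()].
#' @param fields Patient columns to report (default: the five fields used
#'   by the rank-sort).
#' @return Data frame with one row per (field, site) pair plus an
#'   `"overall"` row per field; columns `field`, `site`, `n_missing`,
#'   `n_patients`, `pct_missing` (one decimal place).
#' @export
missingness_table <- function(cohort,
                              fields = c("age", "sex", "race", "ethnicity",
                                         "bc_stage")) {
  p <- cohort$patients
  if (nrow(p) == 0L) stop("empty cohort", call. = FALSE)
  bad <- setdiff(fields, names(p))
  if (length(bad))
    stop("unknown patient field(s): ", toString(bad), call. = FALSE)
  groups <- c(list(overall = p),
              stats::setNames(lapply(site_levels(cohort),
                                     function(s) p[p$site_id == s, ]),
                              site_levels(cohort)))
  out <- do.call(rbind, lapply(fields, function(f) {
    do.call(rbind, lapply(names(groups), function(g) {
      d <- groups[[g]]
      n_miss <- sum(is.na(d[[f]]))
      data.frame(field = f, site = g, n_missing = n_miss,
                 n_patients = nrow(d),
                 pct_missing = round(100 * n_miss / nrow(d), 1))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Demographic summary table
#'
#' Age as mean (SD) over non-missing values; sex, race and ethnicity as
#' counts with percentages on the full patient denominator, missing shown
#' as its own level — overall and per site.
#'
#' @param cohort A [cohort()].
#' @return Data frame with columns `variable`, `level`, `site`, `n`,
#'   `pct`, `mean`, `sd`. For `variable == "age"` the `mean`/`sd` columns
#'   are filled (SD is `NA` when fewer than two ages are known); for
#'   categorical variables `n`/`pct` are.
#' @export
demographic_summary <- function(cohort) {
  p <- cohort$patients
  if (nrow(p) == 0L) stop("empty cohort", call. = FALSE)
  groups <- c(list(overall = p),
              stats::setNames(lapply(site_levels(cohort),
                                     function(s) p[p$site_id == s, ]),
                              site_levels(cohort)))
  age_rows <- do.call(rbind, lapply(names(groups), function(g) {
    a <- groups[[g]]$age
    a <- a[!is.na(a)]
    data.frame(variable = "age", level = NA_character_, site = g,
               n = length(a), pct = NA_real_,
               mean = round(mean(a), 2),
               sd = if (length(a) >= 2) round(stats::sd(a), 2) else NA_real_)
  }))
  cat_rows <- do.call(rbind, lapply(
    c("sex", "race", "ethnicity"), function(f) {
      lv <- unique(c(sort(unique(p[[f]][!is.na(p[[f]])])),
                     if (anyNA(p[[f]])) "missing"))
      do.call(rbind, lapply(names(groups), function(g) {
        d <- groups[[g]]
        vals <- ifelse(is.na(d[[f]]), "missing", d[[f]])
        do.call(rbind, lapply(lv, function(l) {
          n <- sum(vals == l)
          data.frame(variable = f, level = l, site = g, n = n,
                     pct = round(100 * n / nrow(d), 1),
                     mean = NA_real_, sd = NA_real_)
        }))
      }))
    }))
  out <- rbind(age_rows, cat_rows)
  rownames(out) <- NULL
  out
}

#' Distribution of aggregated breast-cancer stage by site
#'
#' @param cohort A [cohort()].
#' @return Data frame with one row per (stage, site) pair, stages ordered
#'   I, II, III, IV, missing; columns `stage`, `site`, `n`, `pct`
#'   (percentage of the site's patients, one decimal place).
#' @export
stage_distribution <- function(cohort) {
  p <- cohort$patients
  if (nrow(p) == 0L) stop("empty cohort", call. = FALSE)
  groups <- c(list(overall = p),
              stats::setNames(lapply(site_levels(cohort),
                                     function(s) p[p$site_id == s, ]),
                              site_levels(cohort)))
  lv <- c(.stage_levels, "missing")
  out <- do.call(rbind, lapply(lv, function(l) {
    do.call(rbind, lapply(names(groups), function(g) {
      d <- groups[[g]]
      vals <- ifelse(is.na(d$bc_stage), "missing", d$bc_stage)
      n <- sum(vals == l)
      data.frame(stage = l, site = g, n = n,
                 pct = round(100 * n / nrow(d), 1))
    }))
  }))
  rownames(out) <- NULL
  out
}
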