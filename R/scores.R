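# The four score components of the hierarchical rank-sort. Each WSI gets a
# tuple (density, race/ethnicity, stage/age/sex, pitfalls); higher scores
# mark cases that are rarer in the cohort and should be annotated first.
# Missing patient attributes always contribute 0 points.

#' Assign sTILs densities to bins
#'
#' @param density_pct Numeric vector of sTILs densities in \[0, 100\].
#' @param binning A [density_binning()].
#' @return Factor with levels `low`, `medium`, `high`; `NA` in, `NA` out.
#' @examples
#' assign_density_bin(c(0, 10, 40, 40.5))  # low low medium high
#' @export
assign_density_bin <- function(density_pct, binning = density_binning()) {
  bad <- !is.na(density_pct) & (density_pct < 0 | density_pct > 100)
  if (any(bad))
    stop("sTILs density outside [0,100]: ",
         toString(density_pct[bad]), call. = FALSE)
  bin <- ifelse(density_pct <= binning$low_max_pct, "low",
                ifelse(density_pct <= binning$medium_max_pct, "medium",
                       "high"))
  factor(bin, levels = .density_bins)
}

#' Normalized density count score of one WSI
#'
#' The fraction of the WSI's ROIs falling in each sTILs density bin,
#' weighted by the bin's points (default high 2, medium 1, low 0) and
#' summed. With the default `"all"` denominator the fraction is taken over
#' every ROI annotated on the WSI; not-evaluable ROIs have no density, fall
#' in no bin, and therefore only dilute the score.
#'
#' @param rois Data frame of the WSI's ROI annotations (columns `evaluable`,
#'   `stils_density_pct`).
#' @param binning A [density_binning()].
#' @param weights Named bin weights.
#' @param denominator `"all"` or `"evaluable"`; see
#'   [prioritization_config()].
#' @return A single numeric score in \[0, max(weights)\]. A WSI with no
#'   evaluable ROI scores 0 (with a warning under the `"evaluable"`
#'   denominator, which is otherwise undefined for it).
#' @export
normalized_density_count_score <- function(rois,
                                           binning = density_binning(),
                                           weights = c(low = 0, medium = 1,
                                                       high = 2),
                                           denominator = c("all", "evaluable")) {
  denominator <- match.arg(denominator)
  if (nrow(rois) == 0L) stop("WSI has no ROIs", call. = FALSE)
  dens <- rois$stils_density_pct[rois$evaluable]
  denom <- if (denominator == "all") nrow(rois) else length(dens)
  if (denom == 0L) {
    warning("WSI has no evaluable ROIs; density score set to 0",
            call. = FALSE)
    return(0)
  }
  if (length(dens) == 0L) return(0)
  counts <- table(assign_density_bin(dens, binning))
  sum(weights[.density_bins] * as.numeric(counts[.density_bins]) / denom)
}

#' Race and ethnicity score of one patient
#'
#' 2 points when race is present and not White, plus 2 points when
#' ethnicity is present and Hispanic or Latino. Missing values contribute 0.
#'
#' @param race,ethnicity Character vectors (vectorized over patients).
#' @return Integer vector with values in \{0, 2, 4\}.
#' @examples
#' race_ethnicity_score("Black or African American", "Hispanic or Latino") # 4
#' race_ethnicity_score("White", "Not Hispanic or Latino")                 # 0
#' @export
race_ethnicity_score <- function(race, ethnicity) {
  2L * as.integer(!is.na(race) & race != "White") +
    2L * as.integer(!is.na(ethnicity) & ethnicity == "Hispanic or Latino")
}

#' Stage, age and sex score of one patient
#'
#' Sum of three parts: stage (III/IV: 2, I/II: 1, missing: 0), age bracket
#' in whole years (<=40, 41-50, 81-90 and above: 2; 51-60, 71-80: 1;
#' 61-70: 0), and sex (present and not F: 2). Missing components
#' contribute 0; non-integer ages are floored.
#'
#' @param bc_stage,age,sex Vectors over patients.
#' @param stage_points,age_points,sex_nonfemale_points Point tables, see
#'   [prioritization_config()].
#' @return Integer vector in \[0, 6\].
#' @export
bcs_age_sex_score <- function(bc_stage, age, sex,
                              stage_points = c(I = 1, II = 1, III = 2, IV = 2),
                              age_points = .default_age_points(),
                              sex_nonfemale_points = 2) {
  len <- max(length(bc_stage), length(age), length(sex))
  bc_stage <- rep_len(bc_stage, len)
  age <- rep_len(age, len)
  sex <- rep_len(sex, len)

  s_pts <- ifelse(is.na(bc_stage), 0, stage_points[bc_stage])
  s_pts[is.na(s_pts)] <- 0

  a <- floor(age)
  a_pts <- rep(0, len)
  for (i in seq_len(nrow(age_points))) {
    hit <- !is.na(a) & a >= age_points$lower[i] & a <= age_points$upper[i]
    a_pts[hit] <- age_points$points[i]
  }

  x_pts <- ifelse(!is.na(sex) & sex != "F", sex_nonfemale_points, 0)
  as.integer(s_pts + a_pts + x_pts)
}

#' Pitfall score of one WSI
#'
#' Every pitfall occurrence across the WSI's ROIs is worth the points of
#' its rarity tier; occurrences are counted per ROI appearance (a pitfall
#' listed on 3 ROIs counts 3 times).
#'
#' @param rois Data frame of the WSI's ROI annotations (column `pitfalls`,
#'   semicolon-joined labels).
#' @param rarity_map Named vector, label -> points.
#' @param unlisted `"error"`: stop on a label absent from the map, naming
#'   it; `"zero"`: count it 0 points with a warning.
#' @return A single non-negative integer.
#' @export
pitfall_score <- function(rois, rarity_map = default_rarity_map(),
                          unlisted = c("error", "zero")) {
  unlisted <- match.arg(unlisted)
  labels <- unlist(lapply(rois$pitfalls, parse_pitfalls), use.names = FALSE)
  if (!length(labels)) return(0L)
  unknown <- setdiff(unique(labels), names(rarity_map))
  if (length(unknown)) {
    if (unlisted == "error")
      stop("pitfall label(s) not in rarity map: ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    warning("pitfall label(s) not in rarity map scored 0: ",
            paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  pts <- rarity_map[labels]
  pts[is.na(pts)] <- 0L
  as.integer(sum(pts))
}

#' Derive a pitfall rarity map from a cohort
#'
#' Counts, for each pitfall label, the number of distinct cases (WSIs) in
#' which it appears at least once, and assigns 2 points to rare labels
#' (<= `rare_max_cases` cases), 1 to semi-rare (<= `semirare_max_cases`),
#' and 0 to common ones.
#'
#' @param cohort A [cohort()].
#' @param rare_max_cases,semirare_max_cases Tier thresholds (defaults 2
#'   and 10).
#' @return Named integer vector, label -> points.
#' @export
derive_rarity_map <- function(cohort, rare_max_cases = 2,
                              semirare_max_cases = 10) {
  r <- cohort$rois
  per_roi <- lapply(r$pitfalls, parse_pitfalls)
  pairs <- data.frame(
    wsi_id = rep(r$wsi_id, lengths(per_roi)),
    label = unlist(per_roi, use.names = FALSE))
  if (nrow(pairs) == 0L) return(stats::setNames(integer(), character()))
  n_cases <- tapply(pairs$wsi_id, pairs$label,
                    function(w) length(unique(w)))
  pts <- ifelse(n_cases <= rare_max_cases, 2L,
                ifelse(n_cases <= semirare_max_cases, 1L, 0L))
  stats::setNames(as.integer(pts), names(n_cases))
}

#' Score one WSI on all four components
#'
#' @param wsi_id Identifier of the WSI to score.
#' @param cohort A [cohort()].
#' @param config A [prioritization_config()].
#' @return Named numeric vector `c(density_score, race_ethnicity_score,
#'   bcs_age_sex_score, pitfall_score)` — the score tuple, ordered by sort
#'   precedence.
#' @examples
#' coh <- generate_cohort(synthetic_config(seed = 1))
#' score_wsi(coh$wsis$wsi_id[1], coh)
#' @export
score_wsi <- function(wsi_id, cohort, config = prioritization_config()) {
  w <- cohort$wsis[cohort$wsis$wsi_id == wsi_id, , drop = FALSE]
  if (nrow(w) != 1L) stop("unknown wsi_id: ", wsi_id, call. = FALSE)
  p <- cohort$patients[cohort$patients$patient_id == w$patient_id, ,
                       drop = FALSE]
  r <- cohort$rois[cohort$rois$wsi_id == wsi_id, , drop = FALSE]
  rarity <- if (config$derive_rarity)
    derive_rarity_map(cohort, config$rare_max_cases,
                      config$semirare_max_cases)
  else config$rarity_map
  c(density_score = normalized_density_count_score(
      r, config$binning, config$bin_weights, config$denominator),
    race_ethnicity_score = race_ethnicity_score(p$race, p$ethnicity),
    bcs_age_sex_score = bcs_age_sex_score(p$bc_stage, p$age, p$sex,
                                          config$stage_points,
                                          config$age_points,
                                          config$sex_nonfemale_points),
    pitfall_score = pitfall_score(r, rarity, config$unlisted_pitfalls))
}
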