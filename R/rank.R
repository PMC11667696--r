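# Hierarchical rank-sort: descending lexicographic order on the score
# tuple (density > race/ethnicity > stage/age/sex > pitfalls), residual
# ties broken by ascending wsi_id; one WSI per patient; round-robin batch
# assignment of the top cases.

.score_cols <- c("density_score", "race_ethnicity_score",
                 "bcs_age_sex_score", "pitfall_score")

#' Rank every WSI of a cohort by the hierarchical rank-sort
#'
#' Computes the four-component score tuple of each WSI ([score_wsi()]) and
#' sorts descending lexicographically: the normalized density count score
#' decides first; each later component is consulted only to break a tie in
#' all earlier ones. Residual ties are broken by ascending `wsi_id`
#' (byte-order), so the ranking is a deterministic function of the cohort
#' and config, independent of input row order.
#'
#' @param cohort A [cohort()].
#' @param config A [prioritization_config()].
#' @return Data frame with columns `rank`, `wsi_id`, `patient_id`, the four
#'   score columns — one row per WSI, in rank order.
#' @export
rank_cases <- function(cohort, config = prioritization_config()) {
  w <- cohort$wsis
  if (nrow(w) == 0L) stop("cohort has no WSIs", call. = FALSE)
  rarity <- if (config$derive_rarity)
    derive_rarity_map(cohort, config$rare_max_cases,
                      config$semirare_max_cases)
  else config$rarity_map

  p <- cohort$patients
  pi <- match(w$patient_id, p$patient_id)
  re <- race_ethnicity_score(p$race[pi], p$ethnicity[pi])
  bas <- bcs_age_sex_score(p$bc_stage[pi], p$age[pi], p$sex[pi],
                           config$stage_points, config$age_points,
                           config$sex_nonfemale_points)
  roi_split <- split(cohort$rois, factor(cohort$rois$wsi_id,
                                         levels = w$wsi_id))
  dens <- vapply(roi_split, normalized_density_count_score, numeric(1),
                 binning = config$binning, weights = config$bin_weights,
                 denominator = config$denominator)
  pit <- vapply(roi_split, pitfall_score, integer(1),
                rarity_map = rarity, unlisted = config$unlisted_pitfalls)

  scored <- data.frame(wsi_id = w$wsi_id, patient_id = w$patient_id,
                       density_score = unname(dens),
                       race_ethnicity_score = re,
                       bcs_age_sex_score = bas,
                       pitfall_score = unname(pit))
  ord <- order(-scored$density_score, -scored$race_ethnicity_score,
               -scored$bcs_age_sex_score, -scored$pitfall_score,
               scored$wsi_id, method = "radix")
  scored <- scored[ord, , drop = FALSE]
  scored <- cbind(rank = seq_len(nrow(scored)), scored)
  rownames(scored) <- NULL
  scored
}

#' Keep one WSI per patient
#'
#' Among a patient's WSIs (sequential sections of the same biopsy), only
#' the best-ranked one is retained; lower-ranked duplicates are excluded.
#' Relative order of retained entries is preserved.
#'
#' @param ranked Ranked data frame from [rank_cases()].
#' @return List with `retained` (ranked data frame, original `rank` values
#'   kept) and `excluded` (character vector of excluded `wsi_id`s).
#' @export
deduplicate_by_patient <- function(ranked) {
  keep <- !duplicated(ranked$patient_id)
  list(retained = ranked[keep, , drop = FALSE],
       excluded = ranked$wsi_id[!keep])
}

#' Assign the top-ranked cases to batches round-robin
#'
#' Takes the top `batch_size * n_batches` retained cases and assigns the
#' case at rank r (1-indexed within the retained order) to batch
#' `((r - 1) mod n_batches) + 1` — i.e. batches fill in the round-robin
#' pattern 1, 2, ..., n, 1, 2, ... — so every batch ends with exactly
#' `batch_size` members and the batches partition the selected cases.
#'
#' @param retained Retained ranked data frame from
#'   [deduplicate_by_patient()].
#' @param batch_size Cases per batch (default 8).
#' @param n_batches Number of batches (default 5).
#' @return The selected rows with an added integer `batch` column, in
#'   retained-rank order.
#' @export
create_batches <- function(retained, batch_size = 8, n_batches = 5) {
  need <- batch_size * n_batches
  if (nrow(retained) < need)
    stop(sprintf(
      "not enough cases to fill %d batches of %d: need %d, have %d (short %d)",
      n_batches, batch_size, need, nrow(retained), need - nrow(retained)),
      call. = FALSE)
  sel <- retained[seq_len(need), , drop = FALSE]
  sel$batch <- as.integer((seq_len(need) - 1L) %% n_batches + 1L)
  rownames(sel) <- NULL
  sel
}

#' Prioritize a cohort's cases into annotation batches
#'
#' The central entry point: scores every WSI on the four components, sorts
#' them by the hierarchical rank-sort, keeps one WSI per patient, and
#' assigns the top `batch_size * n_batches` cases to batches round-robin.
#'
#' @param cohort A [cohort()].
#' @param config A [prioritization_config()].
#' @return An object of class `batch_plan` with elements:
#'   \describe{
#'     \item{ranked}{every WSI with score tuple and rank;}
#'     \item{retained}{the per-patient deduplicated ranking;}
#'     \item{excluded_duplicates}{`wsi_id`s dropped by deduplication;}
#'     \item{batches}{the selected cases with their `batch` assignment;}
#'     \item{batch_size, n_batches}{the batch geometry;}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' coh <- generate_cohort(two_site_preset(seed = 1))
#' plan <- prioritize_cases(coh)
#' plan
#' head(as.data.frame(plan))
#' @export
prioritize_cases <- function(cohort, config = prioritization_config()) {
  ranked <- rank_cases(cohort, config)
  dedup <- deduplicate_by_patient(ranked)
  batches <- create_batches(dedup$retained, config$batch_size,
                            config$n_batches)
  structure(list(ranked = ranked,
                 retained = dedup$retained,
                 excluded_duplicates = dedup$excluded,
                 batches = batches,
                 batch_size = config$batch_size,
                 n_batches = config$n_batches,
                 config = config),
            class = "batch_plan")
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf(
    "<batch_plan> %d WSIs ranked, %d duplicate section(s) excluded\n",
    nrow(x$ranked), length(x$excluded_duplicates)))
  cat(sprintf("  %d batches of %d cases (top %d of %d unique patients)\n",
              x$n_batches, x$batch_size, nrow(x$batches),
              nrow(x$retained)))
  invisible(x)
}

#' @export
summary.batch_plan <- function(object, ...) {
  b <- object$batches
  agg <- do.call(rbind, lapply(split(b, b$batch), function(d) {
    data.frame(batch = d$batch[1], n = nrow(d),
               mean_density_score = mean(d$density_score),
               mean_total_score = mean(d$density_score +
                                         d$race_ethnicity_score +
                                         d$bcs_age_sex_score +
                                         d$pitfall_score))
  }))
  rownames(agg) <- NULL
  structure(list(plan = object, per_batch = agg), class = "summary.batch_plan")
}

#' @export
print.summary.batch_plan <- function(x, ...) {
  print(x$plan)
  cat("\nPer-batch summary:\n")
  print(x$per_batch, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.batch_plan <- function(x, ...) {
  x$batches
}
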