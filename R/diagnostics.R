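# Diversity diagnostics: Shannon entropy of the sTILs density bins, sample
# skewness of the densities, and a before/after report around a batch plan.

#' Shannon entropy of category counts
#'
#' \eqn{H = -\sum_i p_i \log_b p_i} with \eqn{p_i} the category
#' proportions; zero-count categories contribute 0. Entropy increases as
#' the categories become more evenly occupied, reaching \eqn{\log_b k} for
#' a uniform distribution over k categories.
#'
#' @param counts Non-negative numeric vector of category counts (named or
#'   not); at least one must be positive.
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return A single non-negative number.
#' @examples
#' shannon_entropy(c(low = 269, medium = 88, high = 40))
#' shannon_entropy(rep(5, 3)) == log(3)
#' @export
shannon_entropy <- function(counts, base = exp(1)) {
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p) / log(base))
}

#' Sample skewness (Fisher-Pearson)
#'
#' The moment coefficient \eqn{g_1 = m_3 / m_2^{3/2}} with \eqn{m_k} the
#' k-th central sample moment; with `adjusted = TRUE` the bias-corrected
#' \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)} is returned instead. Positive values
#' indicate a right-skewed distribution (mass concentrated at low values
#' with a long right tail), as is typical of sTILs densities.
#'
#' @param values Numeric vector, at least 3 non-missing values with
#'   non-zero variance.
#' @param adjusted Return the bias-corrected estimator (default `FALSE`).
#' @return A single number; skewness is invariant under location shifts and
#'   positive scaling, and changes sign when the sample is negated.
#' @export
sample_skewness <- function(values, adjusted = FALSE) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  if (adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Diversity report: cohort before vs. selected batches after
#'
#' Quantifies what the rank-sort selection did to the cohort's diversity.
#' "Before" metrics are computed over all evaluable ROIs in the cohort
#' (the unit is the ROI); "after" metrics over the evaluable ROIs of the
#' WSIs assigned to batches. Reported are the Shannon entropy of the
#' density-bin counts, the sample skewness of the densities, per-bin
#' counts, per-batch bin counts, and a subgroup retention table (for each
#' demographic level: patients in the cohort vs. patients selected).
#'
#' @param cohort A [cohort()].
#' @param plan A [prioritize_cases()] batch plan derived from `cohort`.
#' @param binning A [density_binning()].
#' @param base Entropy logarithm base (default natural log; the bins are
#'   the three evaluable density bins).
#' @param adjusted Use bias-corrected skewness (default `FALSE`).
#' @param retention_vars Patient variables for the retention table.
#' @return An object of class `diversity_report` (also serializable with
#'   [write_diversity_report()]): a list with `entropy_before/after`,
#'   `skewness_before/after`, `bin_counts_before/after`,
#'   `per_batch_bin_counts`, `subgroup_retention`, and the unit label.
#' @export
diversity_report <- function(cohort, plan, binning = density_binning(),
                             base = exp(1), adjusted = FALSE,
                             retention_vars = c("race", "ethnicity", "sex",
                                                "bc_stage", "age_decade")) {
  r <- cohort$rois
  before <- r[r$evaluable, , drop = FALSE]
  sel_wsis <- plan$batches$wsi_id
  after <- before[before$wsi_id %in% sel_wsis, , drop = FALSE]

  bin_counts <- function(d) {
    tab <- table(assign_density_bin(d$stils_density_pct, binning))
    stats::setNames(as.integer(tab[.density_bins]), .density_bins)
  }
  bc_before <- bin_counts(before)
  bc_after <- bin_counts(after)

  per_batch <- do.call(rbind, lapply(sort(unique(plan$batches$batch)),
    function(b) {
      wsis <- plan$batches$wsi_id[plan$batches$batch == b]
      cbind(data.frame(batch = b),
            as.data.frame(as.list(bin_counts(
              before[before$wsi_id %in% wsis, , drop = FALSE]))))
    }))

  p <- cohort$patients
  p$age_decade <- age_decade_bin(p$age)
  sel_patients <- unique(plan$batches$patient_id)
  retention <- do.call(rbind, lapply(retention_vars, function(v) {
    vals <- p[[v]]
    lv <- c(sort(unique(vals[!is.na(vals)])), if (anyNA(vals)) "missing")
    vals <- ifelse(is.na(vals), "missing", vals)
    sel <- vals[p$patient_id %in% sel_patients]
    do.call(rbind, lapply(lv, function(l) {
      data.frame(variable = v, level = l,
                 n_cohort = sum(vals == l),
                 n_selected = sum(sel == l))
    }))
  }))
  rownames(retention) <- NULL

  structure(list(
    unit = "evaluable ROI",
    entropy_base = base,
    skewness_adjusted = adjusted,
    entropy_before = shannon_entropy(bc_before, base),
    entropy_after = shannon_entropy(bc_after, base),
    skewness_before = skewness_or_na(before$stils_density_pct, adjusted),
    skewness_after = skewness_or_na(after$stils_density_pct, adjusted),
    bin_counts_before = bc_before,
    bin_counts_after = bc_after,
    per_batch_bin_counts = per_batch,
    subgroup_retention = retention
  ), class = "diversity_report")
}

# Skewness is undefined for fewer than 3 values or zero variance; the
# report marks it NA there instead of refusing the whole summary.
skewness_or_na <- function(values, adjusted) {
  tryCatch(sample_skewness(values, adjusted),
           error = function(e) NA_real_)
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report> unit:", x$unit, "\n")
  cat(sprintf("  entropy  (base %.3f): %.4f -> %.4f\n",
              x$entropy_base, x$entropy_before, x$entropy_after))
  cat(sprintf("  skewness (%s): %.4f -> %.4f\n",
              if (x$skewness_adjusted) "G1" else "g1",
              x$skewness_before, x$skewness_after))
  cat("  bin counts before:",
      paste(names(x$bin_counts_before), x$bin_counts_before,
            collapse = ", "), "\n")
  cat("  bin counts after: ",
      paste(names(x$bin_counts_after), x$bin_counts_after,
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a diversity report as JSON
#'
#' @param report A [diversity_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_report <- function(report, path) {
  out <- unclass(report)
  out$bin_counts_before <- as.list(out$bin_counts_before)
  out$bin_counts_after <- as.list(out$bin_counts_after)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
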