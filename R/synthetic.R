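# Seeded synthetic cohorts with the statistical structure of a two-site
# TNBC annotation study: per-site demographics, ~10 ROIs per WSI,
# low-skewed sTILs densities, tiered pitfall frequencies, and realistic
# (site-dependent) stage missingness. Everything is driven by one RNG
# seeded from the config; the global random state is saved and restored.

#' Configuration of the synthetic cohort generator
#'
#' All probabilities may be given per site (named by site) or as a single
#' value shared by every site. Densities are drawn hierarchically: first a
#' bin from `density_mixture`, then uniformly within that bin's range —
#' matching a cohort described only by its marginal bin frequencies.
#'
#' @param seed Integer seed; identical seed + config give bit-identical
#'   cohorts.
#' @param n_patients_per_site Named integer vector, site -> patient count.
#' @param multi_wsi_fraction Probability a patient contributes a second WSI
#'   (sequential section); scalar or per site.
#' @param age_model Per-site list `list(mean =, sd =, min =, max =)` of a
#'   truncated normal in years (or one list shared by all sites).
#' @param sex_probs Named probabilities over sex categories (default all
#'   female, as in a TNBC cohort).
#' @param race_probs,ethnicity_probs Per-site named probability vectors
#'   over the controlled vocabularies.
#' @param stage_probs Named probabilities over stages I-IV, conditional on
#'   the stage being known.
#' @param stage_missing_prob,race_missing_prob,ethnicity_missing_prob
#'   Missingness probabilities; scalar or per site.
#' @param rois_per_wsi ROIs annotated per WSI (default 10).
#' @param evaluable_prob Probability an ROI is evaluable (default 0.79).
#' @param density_mixture Named probabilities of the low/medium/high bins
#'   (default 0.68 / 0.22 / 0.10, a low-skewed distribution).
#' @param pitfall_rates Named per-ROI occurrence probability of each
#'   pitfall label, tiered so that rare / semi-rare / common classes emerge
#'   at realistic cohort sizes.
#' @return A `synthetic_config` list.
#' @seealso [two_site_preset()] for a ready-made two-site configuration.
#' @export
synthetic_config <- function(seed = 1L,
                             n_patients_per_site = c(site_a = 30L,
                                                     site_b = 30L),
                             multi_wsi_fraction = 0.15,
                             age_model = list(mean = 60, sd = 12,
                                              min = 18, max = 100),
                             sex_probs = c(F = 1),
                             race_probs = list(
                               site_a = c("White" = 0.80,
                                          "Black or African American" = 0.15,
                                          "Other" = 0.05),
                               site_b = c("White" = 0.40,
                                          "Black or African American" = 0.55,
                                          "Other" = 0.05)),
                             ethnicity_probs = c(
                               "Not Hispanic or Latino" = 0.92,
                               "Hispanic or Latino" = 0.08),
                             stage_probs = c(I = 0.45, II = 0.35,
                                             III = 0.12, IV = 0.08),
                             stage_missing_prob = 0.5,
                             race_missing_prob = 0.01,
                             ethnicity_missing_prob = 0.04,
                             rois_per_wsi = 10L,
                             evaluable_prob = 0.79,
                             density_mixture = c(low = 0.68, medium = 0.22,
                                                 high = 0.10),
                             pitfall_rates = default_pitfall_rates()) {
  cfg <- structure(list(seed = as.integer(seed),
                        n_patients_per_site = n_patients_per_site,
                        multi_wsi_fraction = multi_wsi_fraction,
                        age_model = age_model,
                        sex_probs = sex_probs,
                        race_probs = race_probs,
                        ethnicity_probs = ethnicity_probs,
                        stage_probs = stage_probs,
                        stage_missing_prob = stage_missing_prob,
                        race_missing_prob = race_missing_prob,
                        ethnicity_missing_prob = ethnicity_missing_prob,
                        rois_per_wsi = as.integer(rois_per_wsi),
                        evaluable_prob = evaluable_prob,
                        density_mixture = density_mixture,
                        pitfall_rates = pitfall_rates),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' Default per-ROI pitfall occurrence rates
#'
#' Tiered so that, at a cohort of ~50 WSIs with 10 ROIs each, labels in the
#' rare tier turn up in roughly 1-2 cases, semi-rare in 3-10 and common in
#' more than 10 — the case-count classes of the default rarity map.
#'
#' @return Named numeric vector, label -> per-ROI probability.
#' @export
default_pitfall_rates <- function() {
  rarity <- default_rarity_map()
  rates <- c(`2` = 0.003, `1` = 0.010, `0` = 0.050)
  stats::setNames(unname(rates[as.character(rarity)]), names(rarity))
}

validate_synthetic_config <- function(cfg) {
  errs <- character()
  add <- function(...) errs[[length(errs) + 1L]] <<- sprintf(...)
  sites <- names(cfg$n_patients_per_site)
  if (is.null(sites) || any(!nzchar(sites)))
    add("n_patients_per_site must be a named vector of site counts")
  if (any(cfg$n_patients_per_site < 1)) add("patient counts must be positive")
  check_probs <- function(p, what) {
    if (any(p < 0 | p > 1)) add("%s outside [0,1]", what)
    if (abs(sum(p) - 1) > 1e-8) add("%s must sum to 1", what)
  }
  for (s in names(per_site(cfg$race_probs, sites)))
    check_probs(per_site(cfg$race_probs, sites)[[s]],
                paste0("race_probs[", s, "]"))
  for (s in names(per_site(cfg$ethnicity_probs, sites)))
    check_probs(per_site(cfg$ethnicity_probs, sites)[[s]],
                paste0("ethnicity_probs[", s, "]"))
  check_probs(cfg$sex_probs, "sex_probs")
  check_probs(cfg$stage_probs, "stage_probs")
  check_probs(cfg$density_mixture, "density_mixture")
  for (f in c("multi_wsi_fraction", "stage_missing_prob",
              "race_missing_prob", "ethnicity_missing_prob",
              "evaluable_prob")) {
    v <- unlist(cfg[[f]])
    if (any(v < 0 | v > 1)) add("%s outside [0,1]", f)
  }
  if (any(cfg$pitfall_rates < 0 | cfg$pitfall_rates > 1))
    add("pitfall_rates outside [0,1]")
  if (cfg$rois_per_wsi < 1) add("rois_per_wsi must be positive")
  if (length(errs))
    stop("invalid synthetic_config:\n", paste("-", errs, collapse = "\n"),
         call. = FALSE)
  invisible(cfg)
}

# Resolve a scalar-or-per-site parameter to a named list/vector over sites.
per_site <- function(x, sites) {
  if (is.list(x) && !is.null(names(x)) && all(sites %in% names(x)))
    return(x[sites])
  if (!is.list(x) && !is.null(names(x)) && all(sites %in% names(x)))
    return(as.list(x[sites]))
  stats::setNames(rep(list(x), length(sites)), sites)
}

#' Two-site study preset
#'
#' A [synthetic_config()] mimicking the printed structure of a two-site
#' TNBC cohort of 105 patients: site_a (n = 49) predominantly White
#' (87.8%), mean age 64.98 (SD 14.95), stage missing for 83.7% of
#' patients; site_b (n = 56) predominantly Black or African American
#' (63.6% of known race), mean age 62.09 (SD 13.80), stage missing for
#' 23.2% — about 51% stage missingness overall. All patients female;
#' 10 ROIs per WSI; low-skewed densities (bins 0.68 / 0.22 / 0.10).
#'
#' @param seed Integer seed passed through to the config.
#' @return A `synthetic_config`.
#' @export
two_site_preset <- function(seed = 1L) {
  synthetic_config(
    seed = seed,
    n_patients_per_site = c(site_a = 49L, site_b = 56L),
    multi_wsi_fraction = c(site_a = 0.35, site_b = 0),
    age_model = list(
      site_a = list(mean = 64.98, sd = 14.95, min = 18, max = 100),
      site_b = list(mean = 62.09, sd = 13.80, min = 18, max = 100)),
    sex_probs = c(F = 1),
    race_probs = list(
      site_a = c("White" = 0.878, "Black or African American" = 0.102,
                 "Other" = 0.020),
      site_b = c("White" = 0.364, "Black or African American" = 0.636)),
    ethnicity_probs = list(
      site_a = c("Not Hispanic or Latino" = 0.918,
                 "Hispanic or Latino" = 0.082),
      site_b = c("Not Hispanic or Latino" = 0.981,
                 "Hispanic or Latino" = 0.019)),
    stage_probs = c(I = 0.481, II = 0.365, III = 0.096, IV = 0.058),
    stage_missing_prob = c(site_a = 0.837, site_b = 0.232),
    race_missing_prob = c(site_a = 0, site_b = 0.018),
    ethnicity_missing_prob = c(site_a = 0, site_b = 0.071),
    rois_per_wsi = 10L,
    evaluable_prob = 0.79,
    density_mixture = c(low = 0.68, medium = 0.22, high = 0.10))
}

#' Generate a synthetic cohort
#'
#' Draws a referentially intact [cohort()] from a [synthetic_config()].
#' Identical seed and config produce bit-identical cohorts; the caller's
#' global random state is left untouched.
#'
#' @param config A `synthetic_config`.
#' @return A validated `cohort`.
#' @examples
#' coh <- generate_cohort(two_site_preset(seed = 7))
#' coh
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed)

  sites <- names(config$n_patients_per_site)
  age_m <- per_site(config$age_model, sites)
  race_p <- per_site(config$race_probs, sites)
  eth_p <- per_site(config$ethnicity_probs, sites)
  st_miss <- per_site(config$stage_missing_prob, sites)
  race_miss <- per_site(config$race_missing_prob, sites)
  eth_miss <- per_site(config$ethnicity_missing_prob, sites)
  multi <- per_site(config$multi_wsi_fraction, sites)

  draw_cat <- function(n, probs) {
    sample(names(probs), n, replace = TRUE, prob = probs)
  }
  with_missing <- function(x, p_missing) {
    x[stats::runif(length(x)) < p_missing] <- NA_character_
    x
  }
  rtruncnorm <- function(n, m) {
    lo <- stats::pnorm(m$min, m$mean, m$sd)
    hi <- stats::pnorm(m$max, m$mean, m$sd)
    stats::qnorm(stats::runif(n, lo, hi), m$mean, m$sd)
  }

  patients <- do.call(rbind, lapply(sites, function(s) {
    n <- config$n_patients_per_site[[s]]
    data.frame(
      patient_id = sprintf("%s-P%03d", s, seq_len(n)),
      site_id = s,
      age = round(rtruncnorm(n, age_m[[s]])),
      sex = draw_cat(n, config$sex_probs),
      race = with_missing(draw_cat(n, race_p[[s]]), race_miss[[s]]),
      ethnicity = with_missing(draw_cat(n, eth_p[[s]]), eth_miss[[s]]),
      bc_stage = with_missing(draw_cat(n, config$stage_probs), st_miss[[s]]),
      tumor_size_cm = round(stats::rlnorm(n, log(2.0), 0.6), 1))
  }))

  n_wsis <- 1L + stats::rbinom(nrow(patients), 1L,
                               unlist(multi)[match(patients$site_id, sites)])
  wsis <- data.frame(
    wsi_id = sprintf("%s-W%d", rep(patients$patient_id, n_wsis),
                     unlist(lapply(n_wsis, seq_len))),
    patient_id = rep(patients$patient_id, n_wsis),
    scanner_make_model = "Aperio AT2 DX",
    image_resolution_um_per_px = 0.25,
    objective_magnification = 40,
    numerical_aperture = 0.95)

  k <- config$rois_per_wsi
  n_roi <- nrow(wsis) * k
  binning <- density_binning()
  ranges <- rbind(low = c(0, binning$low_max_pct),
                  medium = c(binning$low_max_pct, binning$medium_max_pct),
                  high = c(binning$medium_max_pct, 100))
  evaluable <- stats::runif(n_roi) < config$evaluable_prob
  bin <- draw_cat(n_roi, config$density_mixture)
  density <- round(stats::runif(n_roi, ranges[bin, 1], ranges[bin, 2]), 1)
  density[!evaluable] <- NA_real_
  # Rounding can land a draw exactly on the lower bin edge; that edge
  # belongs to the bin below, which is the intended half-open convention.
  labels <- names(config$pitfall_rates)
  hits <- matrix(stats::runif(n_roi * length(labels)), n_roi) <
    matrix(config$pitfall_rates, n_roi, length(labels), byrow = TRUE)
  pitfalls <- apply(hits, 1L, function(h)
    if (any(h)) paste(labels[h], collapse = ";") else NA_character_)

  rois <- data.frame(
    roi_id = sprintf("%s-R%02d", rep(wsis$wsi_id, each = k),
                     rep(seq_len(k), nrow(wsis))),
    wsi_id = rep(wsis$wsi_id, each = k),
    evaluable = evaluable,
    stils_density_pct = density,
    tumor_region_type = draw_cat(n_roi, c(tumor_core = 0.6,
                                          tumor_edge = 0.4)),
    stroma_pct = round(stats::runif(n_roi, 5, 95)),
    pitfalls = pitfalls)

  cohort(patients, wsis, rois)
}
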