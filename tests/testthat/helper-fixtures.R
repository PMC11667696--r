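# Fixture builders and independent oracles shared across the suite.

# A patient row with benign defaults; override any field.
patient_row <- function(patient_id, site_id = "A", age = 65, sex = "F",
                        race = "White",
                        ethnicity = "Not Hispanic or Latino",
                        bc_stage = NA_character_) {
  data.frame(patient_id = patient_id, site_id = site_id, age = age,
             sex = sex, race = race, ethnicity = ethnicity,
             bc_stage = bc_stage)
}

empty_wsis <- function() data.frame(wsi_id = character(),
                                    patient_id = character())

empty_rois <- function() data.frame(roi_id = character(),
                                    wsi_id = character(),
                                    evaluable = logical(),
                                    stils_density_pct = numeric())

# ROI rows for one WSI from a vector of densities (NA = not evaluable).
roi_rows <- function(wsi_id, densities, pitfalls = NA_character_) {
  data.frame(roi_id = sprintf("%s-R%02d", wsi_id, seq_along(densities)),
             wsi_id = rep_len(wsi_id, length(densities)),
             evaluable = !is.na(densities),
             stils_density_pct = densities,
             pitfalls = rep_len(pitfalls, length(densities)))
}

# Cohort of one-WSI patients: `specs` is a list of lists with fields
# patient (a patient_row) and densities / pitfalls for its single WSI.
build_cohort <- function(specs) {
  patients <- do.call(rbind, lapply(specs, `[[`, "patient"))
  wsis <- data.frame(wsi_id = paste0("W-", patients$patient_id),
                     patient_id = patients$patient_id)
  rois <- do.call(rbind, lapply(seq_along(specs), function(i) {
    roi_rows(wsis$wsi_id[i], specs[[i]]$densities,
             specs[[i]]$pitfalls %||% NA_character_)
  }))
  cohort(patients, wsis, rois)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-site fixture mirroring a 105-patient cohort: 49 + 56 patients,
# site mean ages 64.98 / 62.09 years, stage missing for 41 / 13 patients,
# race 43/5/1 (White/Black/Other) and 20/35/1 (White/Black/missing).
two_site_fixture <- function() {
  patients <- rbind(
    do.call(rbind, lapply(1:49, function(i) {
      patient_row(sprintf("A%03d", i), site_id = "site_a", age = 64.98,
                  bc_stage = if (i <= 41) NA_character_ else "I")
    })),
    do.call(rbind, lapply(1:56, function(i) {
      patient_row(sprintf("B%03d", i), site_id = "site_b", age = 62.09,
                  race = c(rep("White", 20),
                           rep("Black or African American", 35),
                           NA)[i],
                  ethnicity = if (i <= 4) NA_character_
                              else "Not Hispanic or Latino",
                  bc_stage = if (i <= 13) NA_character_ else "II")
    })))
  patients$race[1:49] <- c(rep("White", 43),
                           rep("Black or African American", 5), "Other")
  cohort(patients, empty_wsis(), empty_rois())
}

# Brute-force ranking oracle: selection sort under exhaustive pairwise
# lexicographic comparison of the score tuples (descending), residual tie
# broken by ascending wsi_id. Independent of rank_cases' order() call.
oracle_sort <- function(scored) {
  score_cols <- c("density_score", "race_ethnicity_score",
                  "bcs_age_sex_score", "pitfall_score")
  before <- function(i, j) {
    for (col in score_cols) {
      if (scored[[col]][i] > scored[[col]][j]) return(TRUE)
      if (scored[[col]][i] < scored[[col]][j]) return(FALSE)
    }
    scored$wsi_id[i] < scored$wsi_id[j]
  }
  pool <- seq_len(nrow(scored))
  out <- integer()
  while (length(pool)) {
    best <- pool[1]
    for (j in pool[-1]) if (before(j, best)) best <- j
    out <- c(out, best)
    pool <- setdiff(pool, best)
  }
  scored[out, , drop = FALSE]
}

# A small random cohort (<= max_wsis WSIs) exercising ties, shared
# patients, missing attributes and pitfalls.
random_small_cohort <- function(seed, max_wsis = 8) {
  set.seed(seed)
  n_wsi <- sample(1:max_wsis, 1)
  n_pat <- sample(seq_len(n_wsi), 1)
  maybe <- function(x, p = 0.2) if (runif(1) < p) NA else x
  patients <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    patient_row(sprintf("P%02d", i),
                site_id = sample(c("A", "B"), 1),
                age = maybe(sample(18:95, 1)),
                sex = maybe(sample(c("F", "M"), 1, prob = c(0.9, 0.1))),
                race = maybe(sample(c("White", "Black or African American",
                                      "Other"), 1)),
                ethnicity = maybe(sample(c("Hispanic or Latino",
                                           "Not Hispanic or Latino"), 1)),
                bc_stage = maybe(sample(c("I", "II", "III", "IV"), 1)))
  }))
  owners <- sort(c(seq_len(n_pat),
                   sample(seq_len(n_pat), n_wsi - n_pat, replace = TRUE)))
  wsis <- data.frame(wsi_id = sprintf("W%02d", seq_len(n_wsi)),
                     patient_id = patients$patient_id[owners])
  labels <- names(default_rarity_map())
  rois <- do.call(rbind, lapply(seq_len(n_wsi), function(i) {
    k <- sample(1:4, 1)
    dens <- ifelse(runif(k) < 0.8,
                   round(sample(c(runif(k, 0, 10), runif(k, 10, 100)), k), 1),
                   NA)
    pits <- vapply(seq_len(k), function(j) {
      m <- sample(0:2, 1)
      if (m == 0) NA_character_
      else paste(sample(labels, m), collapse = ";")
    }, character(1))
    roi_rows(wsis$wsi_id[i], dens, pits)
  }))
  cohort(patients, wsis, rois)
}
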