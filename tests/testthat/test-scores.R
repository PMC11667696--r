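# The four score components of the hierarchical rank-sort.

test_that("density bin boundaries are low <= 10 < medium <= 40 < high", {
  bins <- assign_density_bin(c(0, 10, 10.5, 40, 40.5, 100))
  expect_equal(as.character(bins),
               c("low", "low", "medium", "medium", "high", "high"))
  expect_error(assign_density_bin(101), "\\[0,100\\]")
  expect_error(assign_density_bin(-1), "\\[0,100\\]")
})

test_that("normalized density count score is the weighted bin fraction", {
  all_high <- roi_rows("W1", rep(80, 10))
  expect_equal(normalized_density_count_score(all_high), 2.0)
  all_low <- roi_rows("W1", rep(5, 10))
  expect_equal(normalized_density_count_score(all_low), 0.0)
  split_5_5 <- roi_rows("W1", c(rep(80, 5), rep(5, 5)))
  expect_equal(normalized_density_count_score(split_5_5), 1.0)
})

test_that("not-evaluable ROIs dilute under the all-ROIs denominator only", {
  mixed <- roi_rows("W1", c(rep(80, 5), rep(NA, 5)))
  expect_equal(normalized_density_count_score(mixed, denominator = "all"), 1.0)
  expect_equal(normalized_density_count_score(mixed,
                                              denominator = "evaluable"), 2.0)
  none <- roi_rows("W1", rep(NA_real_, 4))
  expect_warning(
    s <- normalized_density_count_score(none, denominator = "evaluable"),
    "no evaluable")
  expect_equal(s, 0)
  expect_equal(normalized_density_count_score(none, denominator = "all"), 0)
  expect_error(normalized_density_count_score(roi_rows("W1", numeric())),
               "no ROIs")
})

test_that("race/ethnicity scoring matches the published worked examples", {
  expect_equal(race_ethnicity_score("Black or African American",
                                    "Hispanic or Latino"), 4L)
  expect_equal(race_ethnicity_score("White", "Not Hispanic or Latino"), 0L)
  expect_equal(race_ethnicity_score(NA, NA), 0L)
  expect_equal(race_ethnicity_score("Other", NA), 2L)
  expect_equal(race_ethnicity_score("White", "Hispanic or Latino"), 2L)
})

test_that("stage/age/sex scoring follows the point table", {
  expect_equal(bcs_age_sex_score("III", 35, "M"), 6L)
  expect_equal(bcs_age_sex_score(NA, 65, "F"), 0L)
  expect_equal(bcs_age_sex_score("I", 55, "F"), 2L)
  # age brackets, one probe per bracket (+ the configurable > 90 rule)
  ages <- c(40, 45, 55, 65, 75, 85, 95)
  expect_equal(bcs_age_sex_score(rep(NA, 7), ages, rep("F", 7)),
               c(2L, 2L, 1L, 0L, 1L, 2L, 2L))
  expect_equal(bcs_age_sex_score(NA, 40.9, "F"), 2L)  # floored to 40
  expect_equal(bcs_age_sex_score(NA, NA, NA), 0L)
})

test_that("pitfall score counts occurrences per ROI appearance", {
  rois <- roi_rows("W1", c(20, 20, 20, 20),
                   pitfalls = c("Carcinoma In Situ", "Adipocytes",
                                "Adipocytes", "Adipocytes"))
  expect_equal(pitfall_score(rois), 2L)
  expect_equal(pitfall_score(roi_rows("W1", c(20, 20))), 0L)
  two_benign <- roi_rows("W1", c(20, 20),
                         pitfalls = c("Benign Glands", "Benign Glands"))
  expect_equal(pitfall_score(two_benign), 2L)
  # a pitfall repeated across 3 ROIs counts 3 times
  thrice <- roi_rows("W1", c(20, 20, 20), pitfalls = "Ischemia")
  expect_equal(pitfall_score(thrice), 6L)
})

test_that("unlisted pitfall labels error strictly or score 0 leniently", {
  rois <- roi_rows("W1", 20, pitfalls = "Space Dust")
  expect_error(pitfall_score(rois), "Space Dust")
  expect_warning(s <- pitfall_score(rois, unlisted = "zero"), "Space Dust")
  expect_equal(s, 0L)
})

test_that("rarity map derivation tiers labels by distinct-case counts", {
  # one label in 2 WSIs, one in 3, one in 11
  specs <- lapply(1:11, function(i) {
    pits <- c(if (i <= 2) "Fibers", if (i <= 3) "Eosinophilia", "Adipocytes")
    list(patient = patient_row(sprintf("P%02d", i)),
         densities = c(20, 20),
         pitfalls = paste(pits, collapse = ";"))
  })
  coh <- build_cohort(specs)
  map <- derive_rarity_map(coh)
  expect_equal(map[["Fibers"]], 2L)        # <= 2 cases
  expect_equal(map[["Eosinophilia"]], 1L)  # 3-10 cases
  expect_equal(map[["Adipocytes"]], 0L)    # > 10 cases
})

test_that("score_wsi composes the four components", {
  coh <- build_cohort(list(
    list(patient = patient_row("P1", age = 35, sex = "M",
                               race = "Black or African American",
                               ethnicity = "Hispanic or Latino",
                               bc_stage = "IV"),
         densities = rep(80, 10), pitfalls = c("Ischemia", rep(NA, 9))),
    list(patient = patient_row("P2"),  # 65y White non-Hispanic female
         densities = rep(5, 10)),
    list(patient = patient_row("P3"),
         densities = c(rep(80, 5), rep(5, 5)))))
  expect_equal(score_wsi("W-P1", coh),
               c(density_score = 2.0, race_ethnicity_score = 4,
                 bcs_age_sex_score = 6, pitfall_score = 2))
  expect_equal(score_wsi("W-P2", coh),
               c(density_score = 0, race_ethnicity_score = 0,
                 bcs_age_sex_score = 0, pitfall_score = 0))
  expect_equal(score_wsi("W-P3", coh),
               c(density_score = 1.0, race_ethnicity_score = 0,
                 bcs_age_sex_score = 0, pitfall_score = 0))
})

test_that("score bounds hold on random cohorts", {
  for (seed in 1:25) {
    coh <- random_small_cohort(seed)
    ranked <- suppressWarnings(rank_cases(coh))
    expect_true(all(ranked$density_score >= 0 & ranked$density_score <= 2))
    expect_true(all(ranked$race_ethnicity_score %in% c(0L, 2L, 4L)))
    expect_true(all(ranked$bcs_age_sex_score >= 0 &
                      ranked$bcs_age_sex_score <= 6))
    expect_true(all(ranked$pitfall_score >= 0))
  }
})

test_that("making a present field missing never increases a score", {
  set.seed(42)
  for (i in 1:50) {
    race <- sample(c("White", "Black or African American", "Other"), 1)
    eth <- sample(c("Hispanic or Latino", "Not Hispanic or Latino"), 1)
    stage <- sample(c("I", "II", "III", "IV"), 1)
    age <- sample(18:95, 1)
    sex <- sample(c("F", "M"), 1)
    full_re <- race_ethnicity_score(race, eth)
    expect_lte(race_ethnicity_score(NA, eth), full_re)
    expect_lte(race_ethnicity_score(race, NA), full_re)
    full_bas <- bcs_age_sex_score(stage, age, sex)
    expect_lte(bcs_age_sex_score(NA, age, sex), full_bas)
    expect_lte(bcs_age_sex_score(stage, NA, sex), full_bas)
    expect_lte(bcs_age_sex_score(stage, age, NA), full_bas)
  }
})

test_that("upgrading a low ROI to high and adding a rare pitfall are monotone", {
  set.seed(7)
  for (i in 1:20) {
    dens <- round(runif(sample(3:8, 1), 0, 100), 1)
    rois <- roi_rows("W1", dens)
    base <- normalized_density_count_score(rois)
    low_idx <- which(dens <= 10)
    if (length(low_idx)) {
      dens2 <- dens
      dens2[low_idx[1]] <- 80
      expect_gte(normalized_density_count_score(roi_rows("W1", dens2)), base)
    }
    pits <- sample(names(default_rarity_map()), 2)
    rois$pitfalls <- c(paste(pits, collapse = ";"),
                       rep(NA, length(dens) - 1))
    with_pit <- pitfall_score(rois)
    rois$pitfalls[2] <- "Ischemia"  # rare, 2 points
    expect_gte(pitfall_score(rois), with_pit)
  }
})
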