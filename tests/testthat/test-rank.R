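# Hierarchical rank-sort, deduplication, batching.

test_that("later score components only break ties in earlier ones", {
  # equal on first three components, pitfall 6 vs 2 -> higher pitfall first
  coh <- build_cohort(list(
    list(patient = patient_row("P1"), densities = rep(20, 4),
         pitfalls = c("Ischemia", "Ischemia", "Ischemia", NA)),
    list(patient = patient_row("P2"), densities = rep(20, 4),
         pitfalls = c("Ischemia", NA, NA, NA))))
  ranked <- rank_cases(coh)
  expect_equal(ranked$wsi_id, c("W-P1", "W-P2"))
  # but a higher density score outranks any pitfall advantage
  coh2 <- build_cohort(list(
    list(patient = patient_row("P1"), densities = rep(20, 4),
         pitfalls = "Ischemia"),
    list(patient = patient_row("P2"), densities = rep(80, 4))))
  expect_equal(rank_cases(coh2)$wsi_id, c("W-P2", "W-P1"))
})

test_that("a single WSI ranks first and full ties fall back to wsi_id", {
  single <- build_cohort(list(list(patient = patient_row("P1"),
                                   densities = 20)))
  expect_equal(rank_cases(single)$rank, 1L)
  tied <- build_cohort(list(
    list(patient = patient_row("P2"), densities = rep(20, 3)),
    list(patient = patient_row("P1"), densities = rep(20, 3))))
  expect_equal(rank_cases(tied)$wsi_id, c("W-P1", "W-P2"))
})

test_that("ranking matches the brute-force pairwise oracle on small cohorts", {
  for (seed in 1:200) {
    coh <- random_small_cohort(seed)
    ranked <- suppressWarnings(rank_cases(coh))
    # oracle input: rows shuffled so agreement cannot come from input order
    shuffled <- ranked[sample(nrow(ranked)), , drop = FALSE]
    expect_equal(oracle_sort(shuffled)$wsi_id, ranked$wsi_id,
                 info = paste("seed", seed))
  }
})

test_that("ranking agrees with componentwise score_wsi and is deterministic", {
  coh <- random_small_cohort(99)
  ranked <- suppressWarnings(rank_cases(coh))
  for (i in seq_len(nrow(ranked))) {
    tup <- suppressWarnings(score_wsi(ranked$wsi_id[i], coh))
    expect_equal(unname(tup),
                 unname(unlist(ranked[i, c("density_score",
                                           "race_ethnicity_score",
                                           "bcs_age_sex_score",
                                           "pitfall_score")])))
  }
  expect_identical(ranked, suppressWarnings(rank_cases(coh)))
  # row order of the input tables must not matter
  coh2 <- coh
  coh2$wsis <- coh2$wsis[rev(seq_len(nrow(coh2$wsis))), ]
  coh2$rois <- coh2$rois[sample(nrow(coh2$rois)), ]
  ranked2 <- suppressWarnings(rank_cases(coh2))
  expect_equal(ranked2$wsi_id, ranked$wsi_id)
})

test_that("non-White patients outrank White patients, all else equal", {
  specs <- lapply(1:10, function(i) {
    list(patient = patient_row(sprintf("P%02d", i),
                               race = if (i %% 2) "White"
                                      else "Black or African American"),
         densities = c(5, 20, 80), pitfalls = "Adipocytes")
  })
  ranked <- rank_cases(build_cohort(specs))
  nonwhite_ranks <- ranked$rank[ranked$race_ethnicity_score > 0]
  white_ranks <- ranked$rank[ranked$race_ethnicity_score == 0]
  expect_true(max(nonwhite_ranks) < min(white_ranks))
})

test_that("deduplication keeps each patient's best-ranked WSI only", {
  patients <- rbind(patient_row("P1"), patient_row("P2"))
  wsis <- data.frame(wsi_id = c("W1", "W2", "W3", "W4", "W5"),
                     patient_id = c("P1", "P1", "P1", "P2", "P2"))
  rois <- do.call(rbind, lapply(1:5, function(i) {
    roi_rows(paste0("W", i), rep(c(80, 50, 20, 30, 5)[i], 2))
  }))
  coh <- cohort(patients, wsis, rois)
  ranked <- rank_cases(coh)
  dd <- deduplicate_by_patient(ranked)
  expect_equal(nrow(dd$retained), 2L)
  expect_equal(anyDuplicated(dd$retained$patient_id), 0L)
  expect_setequal(dd$excluded, c("W2", "W3", "W5"))
  # retained tuple is lexicographically maximal among the patient's WSIs
  for (pid in unique(ranked$patient_id)) {
    own <- ranked[ranked$patient_id == pid, ]
    best <- oracle_sort(own)[1, ]
    expect_equal(dd$retained$wsi_id[dd$retained$patient_id == pid],
                 best$wsi_id)
  }
  # identity when every patient has one WSI
  coh1 <- random_small_cohort(3)
  r1 <- suppressWarnings(rank_cases(coh1))
  if (anyDuplicated(r1$patient_id) == 0)
    expect_identical(deduplicate_by_patient(r1)$retained, r1)
})

test_that("round-robin batching partitions the top cases", {
  retained <- data.frame(rank = 1:45, wsi_id = sprintf("W%02d", 1:45),
                         patient_id = sprintf("P%02d", 1:45))
  sel <- create_batches(retained, batch_size = 8, n_batches = 5)
  expect_equal(nrow(sel), 40L)
  expect_equal(sel$batch, rep(1:5, 8))
  expect_equal(as.vector(table(sel$batch)), rep(8L, 5))
  expect_setequal(sel$wsi_id, retained$wsi_id[1:40])

  one <- create_batches(retained[1:8, ], batch_size = 8, n_batches = 1)
  expect_equal(one$batch, rep(1L, 8))
  two <- create_batches(retained[1:16, ], batch_size = 8, n_batches = 2)
  expect_equal(two$wsi_id[two$batch == 1], retained$wsi_id[seq(1, 15, 2)])
  expect_equal(two$wsi_id[two$batch == 2], retained$wsi_id[seq(2, 16, 2)])

  expect_error(create_batches(retained[1:39, ], 8, 5), "short 1")
})

test_that("prioritize_cases assembles a consistent plan", {
  coh <- generate_cohort(synthetic_config(seed = 5))
  cfg <- prioritization_config(batch_size = 4, n_batches = 3)
  plan <- prioritize_cases(coh, cfg)
  expect_s3_class(plan, "batch_plan")
  # batches partition the top 12 retained cases
  expect_equal(plan$batches$wsi_id, plan$retained$wsi_id[1:12])
  expect_equal(anyDuplicated(plan$batches$wsi_id), 0L)
  expect_equal(sort(unique(plan$batches$batch)), 1:3)
  # ranked is a permutation of the cohort's WSIs
  expect_setequal(plan$ranked$wsi_id, coh$wsis$wsi_id)
  # determinism across runs
  plan2 <- prioritize_cases(coh, cfg)
  expect_identical(plan$batches, plan2$batches)
  expect_output(print(plan), "batch_plan")
  expect_output(print(summary(plan)), "Per-batch")
})
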