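# Entropy, skewness, diversity report, stage distribution.

test_that("entropy closed forms: uniform, degenerate, direct evaluation", {
  expect_equal(shannon_entropy(rep(7, 4)), log(4))
  expect_equal(shannon_entropy(c(10, 0, 0)), 0)
  # direct one-line evaluation of -sum(p log p) for counts (269, 88, 40)
  expect_equal(shannon_entropy(c(269, 88, 40)), 0.8289282733,
               tolerance = 1e-9)
  expect_equal(shannon_entropy(c(1, 1), base = 2), 1)
  expect_error(shannon_entropy(c(0, 0)), "zero")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("entropy is bounded, permutation- and scale-invariant", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    counts <- sample(0:30, k, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    h <- shannon_entropy(counts)
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
    expect_equal(shannon_entropy(sample(counts)), h)
    expect_equal(shannon_entropy(counts * 2), h)
  }
  # maximal exactly at uniformity
  expect_lt(shannon_entropy(c(5, 6, 7)), log(3))
})

test_that("skewness matches the moment definition and its symmetries", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0)
  expect_equal(sample_skewness(c(-4, -1, 0, 1, 4)), 0)
  expect_equal(sample_skewness(c(0, 0, 1)), 1 / sqrt(2))
  set.seed(21)
  for (i in 1:20) {
    x <- rlnorm(sample(5:40, 1))
    g1 <- sample_skewness(x)
    expect_equal(sample_skewness(-x), -g1)
    expect_equal(sample_skewness(3 + 2 * x), g1)
  }
  expect_error(sample_skewness(c(1, 2)), "at least 3")
  expect_error(sample_skewness(rep(4, 5)), "variance")
})

test_that("skewness agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (i in 1:10) {
    x <- rgamma(sample(10:60, 1), shape = 2)
    expect_equal(sample_skewness(x), e1071::skewness(x, type = 1))
    expect_equal(sample_skewness(x, adjusted = TRUE),
                 e1071::skewness(x, type = 2))
  }
})

test_that("selecting the whole cohort leaves every metric unchanged", {
  coh <- generate_cohort(synthetic_config(
    seed = 2, n_patients_per_site = c(site_a = 6, site_b = 6),
    multi_wsi_fraction = 0))
  cfg <- prioritization_config(batch_size = 4, n_batches = 3)  # all 12
  plan <- prioritize_cases(coh, cfg)
  rep <- diversity_report(coh, plan)
  expect_equal(rep$entropy_after, rep$entropy_before)
  expect_equal(rep$skewness_after, rep$skewness_before)
  expect_equal(rep$bin_counts_after, rep$bin_counts_before)
  expect_equal(rep$subgroup_retention$n_selected,
               rep$subgroup_retention$n_cohort)
})

test_that("a selection holding only low-bin ROIs has zero entropy after", {
  specs <- lapply(1:4, function(i)
    list(patient = patient_row(paste0("P", i)), densities = rep(5, 3)))
  coh <- build_cohort(specs)
  plan <- prioritize_cases(coh, prioritization_config(batch_size = 2,
                                                      n_batches = 2))
  rep <- diversity_report(coh, plan)
  expect_equal(rep$entropy_after, 0)
  expect_equal(unname(rep$bin_counts_after), c(12L, 0L, 0L))
})

test_that("retention counts are consistent with the selection", {
  coh <- generate_cohort(two_site_preset(seed = 3))
  plan <- prioritize_cases(coh)
  rep <- diversity_report(coh, plan)
  ret <- rep$subgroup_retention
  expect_true(all(ret$n_selected <= ret$n_cohort))
  expect_true(all(ret$n_selected >= 0))
  n_sel <- length(unique(plan$batches$patient_id))
  for (v in unique(ret$variable)) {
    expect_equal(sum(ret$n_selected[ret$variable == v]), n_sel)
    expect_equal(sum(ret$n_cohort[ret$variable == v]), nrow(coh$patients))
  }
  # per-batch bin counts cover exactly the batched evaluable ROIs
  expect_equal(sum(unlist(rep$per_batch_bin_counts[, c("low", "medium",
                                                       "high")])),
               sum(unname(rep$bin_counts_after)))
})

test_that("stage distribution counts per site and overall", {
  specs <- lapply(1:4, function(i)
    list(patient = patient_row(paste0("P", i),
                               bc_stage = c("II", "II", "II", "I")[i]),
         densities = 20))
  coh <- build_cohort(specs)
  sd_tab <- stage_distribution(coh)
  row <- sd_tab[sd_tab$stage == "II" & sd_tab$site == "overall", ]
  expect_equal(row$n, 3L)
  expect_equal(row$pct, 75.0)
  all_missing <- build_cohort(list(
    list(patient = patient_row("P1"), densities = 20),
    list(patient = patient_row("P2"), densities = 20)))
  sd2 <- stage_distribution(all_missing)
  expect_equal(sd2$n[sd2$stage == "missing" & sd2$site == "overall"], 2L)
  expect_equal(sum(sd2$n[sd2$site == "overall"]), 2L)
})
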