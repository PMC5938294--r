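test_that("AUC handles perfect separation, pure ties and the worked pair count", {
  out4 <- c("passed", "passed", "not_passed", "not_passed")
  expect_equal(roc_auc(c(1, 2, 8, 9), out4)$auc, 1)
  expect_equal(roc_auc(c(5, 5, 5, 5), out4)$auc, 0.5)
  ex <- roc_auc(c(3, 4, 5, 6), c("passed", "passed", "not_passed", "passed"))
  expect_equal(ex$auc, brute_auc(c(3, 4, 5, 6),
                                 c("passed", "passed", "not_passed", "passed")))
  expect_equal(ex$n_pos, 3L)
  expect_equal(ex$n_neg, 1L)
  expect_error(roc_auc(1:4, rep("passed", 4)), "undefined AUC")
})

test_that("AUC equals exhaustive pair counting on random instances", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    scores <- round(rnorm(n, 5, 2), sample(0:2, 1))  # induce ties sometimes
    outcomes <- ifelse(runif(n) < plogis(5 - scores), "passed", "not_passed")
    if (length(unique(outcomes)) < 2) next
    expect_equal(roc_auc(scores, outcomes)$auc, brute_auc(scores, outcomes),
                 tolerance = 1e-12)
  }
})

test_that("AUC is antisymmetric under score negation for tie-free scores", {
  set.seed(15)
  scores <- rnorm(40)
  outcomes <- ifelse(runif(40) < 0.5, "passed", "not_passed")
  a1 <- roc_auc(scores, outcomes)$auc
  a2 <- roc_auc(-scores, outcomes)$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("AUC confidence interval brackets the point estimate", {
  set.seed(16)
  scores <- rnorm(80, 5, 1.5)
  outcomes <- ifelse(runif(80) < plogis(5 - scores), "passed", "not_passed")
  r <- roc_auc(scores, outcomes)
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
})

test_that("Bland-Altman bias and limits follow the closed form", {
  id <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$bias, 0)
  expect_equal(id$loa, c(0, 0))
  off <- bland_altman(c(1, 2, 3), c(1, 2, 3) - 0.2)
  expect_equal(off$bias, 0.2)
  expect_equal(off$loa, c(0.2, 0.2))
  h <- bland_altman(c(1.0, 2.4), c(1.0, 2.0))
  s <- stats::sd(c(0, 0.4))
  expect_equal(h$bias, 0.2)
  expect_equal(h$loa, c(0.2 - 1.96 * s, 0.2 + 1.96 * s))
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("ppt bins are half-open with the boundary assigned upward", {
  b <- ppt_bins(c(5, 25, 45, 65, 85))
  expect_equal(unname(b), rep(0.2, 5))
  expect_equal(unname(ppt_bins(20)["20-40"]), 1)
  expect_equal(unname(ppt_bins(100)[">80"]), 1)
  expect_equal(sum(ppt_bins(runif(50, 0, 100))), 1)
  expect_error(ppt_bins(c(5, 101)), "invalid input")
})

test_that("uniform ppt draws fill the five bins evenly", {
  set.seed(17)
  b <- ppt_bins(runif(1000, 0, 100))
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_true(all(abs(b - 0.2) < 3 * se))
})

test_that("Friedman statistic matches the rank formula and base R", {
  # identical columns: no evidence
  f0 <- friedman_rank_test(matrix(rep(1:5, 3), 5, 3))
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1, tolerance = 0.05)  # permutation branch, n < 8
  # strictly ordered 3x3 rows: classic value 6
  m3 <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  expect_equal(friedman_rank_test(m3)$statistic, 6)
  # tie-free data: equals stats::friedman.test
  set.seed(18)
  y <- matrix(rnorm(12 * 4), 12, 4)
  expect_equal(friedman_rank_test(y)$statistic,
               unname(stats::friedman.test(y)$statistic), tolerance = 1e-12)
  expect_equal(friedman_rank_test(y)$p_value,
               stats::friedman.test(y)$p.value, tolerance = 1e-12)
  expect_error(friedman_rank_test(matrix(1, 1, 3)), "invalid input")
})

test_that("a zero-noise study has zero spread everywhere", {
  cfg <- study_config(cohort = cohort_params(n = 300,
                                             reader_biases = c(0, 0, 0),
                                             reader_sds = c(0, 0, 0)))
  rep <- run_study(cfg, seed = 5)
  expect_equal(unname(rep$main$upper$bins["<20"]), 1)
  expect_equal(unname(rep$main$lower$bins["<20"]), 1)
  expect_equal(rep$main$upper$median_ppt, 0)
  expect_equal(rep$main$lower$frac_gt20, 0)
})

test_that("upper stones are more variability-sensitive than lower stones", {
  rep <- run_study(study_config(), seed = 11)
  expect_gt(rep$main$upper$frac_gt20, rep$main$lower$frac_gt20)
})

test_that("the asymmetry comes from curve steepness, not the location label", {
  ml <- calibrate_from_anchors(passage_anchors("lower"))
  cfg <- study_config(model_upper = ml, model_lower = ml)
  same <- run_study(cfg, seed = 11)
  true_study <- run_study(study_config(), seed = 11)
  gap_same <- same$main$upper$frac_gt20 - same$main$lower$frac_gt20
  gap_true <- true_study$main$upper$frac_gt20 - true_study$main$lower$frac_gt20
  # assigning the flat lower curve to both arms collapses the asymmetry;
  # the small residual reflects upper stones being larger on average
  expect_lt(gap_same, 0.5 * gap_true)
  expect_lt(same$main$upper$frac_gt20, 0.5 * true_study$main$upper$frac_gt20)
})

test_that("study reports are reproducible from the seed", {
  a <- run_study(study_config(cohort = cohort_params(n = 200)), seed = 3)
  b <- run_study(study_config(cohort = cohort_params(n = 200)), seed = 3)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$main, b$main)
  expect_identical(a$auc_table, b$auc_table)
})

test_that("the secondary analysis runs only with supplied models", {
  base <- run_study(study_config(cohort = cohort_params(n = 200)), seed = 4)
  expect_null(base$secondary)
  cfg <- study_config(cohort = cohort_params(n = 400),
                      secondary_models = secondary_model_set())
  rep <- run_study(cfg, seed = 4)
  expect_named(rep$secondary$bins,
               c("width_bone", "length_bone", "width_soft", "length_soft"))
  for (b in rep$secondary$bins)
    expect_equal(sum(b), 1, tolerance = 1e-9)
  expect_true(is.finite(rep$secondary$friedman$p_value))
  expect_error(study_config(secondary_models = list(width_bone = 1)),
               "config error")
})

test_that("real-cohort values travel as annotations, not results", {
  rep <- run_study(study_config(cohort = cohort_params(n = 150)), seed = 9)
  expect_match(rep$reference$note, "orientation only")
  expect_equal(unname(rep$reference$auc_range), c(0.88, 0.90))
  expect_equal(unname(rep$reference$frac_gt20), c(0.44, 0.06))
  expect_equal(unname(rep$reference$median_ppt), c(17, 16, 16, 12))
})
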