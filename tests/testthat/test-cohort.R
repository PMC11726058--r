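test_that("generated images satisfy the masked-image invariants", {
  coh <- small_cohort()
  for (s in coh$subjects[1:3]) {
    expect_false(any(s$mask_left & s$mask_right))
    expect_identical(dim(s$hu), dim(s$mask_left))
    expect_true(all(is.finite(s$hu[s$mask_left | s$mask_right])))
  }
  # per-slice counts taper below the trimming threshold at the ends
  counts <- apply(coh$subjects[[1]]$mask_left, 1, sum)
  expect_lt(counts[1], coh$config$min_voxels)
  expect_lt(counts[length(counts)], coh$config$min_voxels)
  expect_gt(max(counts), coh$config$min_voxels)
})

test_that("identical config reproduces the cohort bit-identically", {
  c1 <- generate_cohort(cohort_config(n_subjects = 2, seed = 31))
  c2 <- generate_cohort(cohort_config(n_subjects = 2, seed = 31))
  expect_identical(c1$subjects[[1]]$hu, c2$subjects[[1]]$hu)
  expect_identical(c1$subjects[[2]]$mask_left, c2$subjects[[2]]$mask_left)
  expect_identical(c1$records, c2$records)
})

test_that("no batch effect: same cluster and seed differ only by mask", {
  cfg <- cohort_config(n_subjects = 2, scanner_levels = 2,
                       scanner_effect = list(shift = c(0, 0),
                                             scale = c(1, 1)),
                       seed = 5)
  a <- generate_subject(cfg, 1, 1, seed = 99, subject_id = "A")
  b <- generate_subject(cfg, 1, 2, seed = 99, subject_id = "B")
  expect_identical(a$image$hu, b$image$hu)
  expect_false(identical(a$image$mask_left, b$image$mask_left))
})

test_that("additive scanner shift moves the within-mask mean by the shift", {
  cfg <- cohort_config(n_subjects = 2, scanner_levels = 2,
                       scanner_effect = list(shift = c(0, 50),
                                             scale = c(1, 1)),
                       seed = 5)
  a <- generate_subject(cfg, 1, 1, seed = 42, subject_id = "A")
  b <- generate_subject(cfg, 1, 2, seed = 42, subject_id = "A")
  ma <- mean(a$image$hu[a$image$mask_left | a$image$mask_right])
  mb <- mean(b$image$hu[b$image$mask_left | b$image$mask_right])
  expect_equal(mb - ma, 50, tolerance = 1e-10)
})

test_that("registered variant shares the template mask across subjects", {
  cfg <- cohort_config(n_subjects = 2, seed = 5)
  a <- generate_subject(cfg, 1, 1, seed = 1, subject_id = "A",
                        registered = TRUE)
  b <- generate_subject(cfg, 2, 2, seed = 2, subject_id = "B",
                        registered = TRUE)
  expect_identical(a$image$mask_left, b$image$mask_left)
  expect_identical(a$image$mask_right, b$image$mask_right)
  expect_true(a$image$registered)
})

test_that("null cluster coefficients give outcomes independent of cluster", {
  cfg <- cohort_config(n_subjects = 150, seed = 7)
  om <- cfg$outcome_model
  om$pft$fev1$cluster <- rep(0, 3)
  cfg$outcome_model <- om
  rec <- withr::with_seed(7, tibble::tibble(
    subject_id = sprintf("S%03d", 1:150),
    cluster_true = sample(1:3, 150, TRUE),
    age = rnorm(150, 53, 10), sex = rbinom(150, 1, 0.5),
    height = rnorm(150, 67, 4), bmi = rnorm(150, 30, 6)
  ))
  out <- generate_outcomes(rec, cfg, seed = 11)
  p <- summary(aov(fev1 ~ factor(cluster_true), data = out))[[1]][1, 5]
  expect_gt(p, 0.01)
})

test_that("strong planted cluster effect is detectable by ANOVA", {
  cfg <- cohort_config(n_subjects = 200, seed = 7)  # default: 2 SD spread
  rec <- withr::with_seed(8, tibble::tibble(
    subject_id = sprintf("S%03d", 1:200),
    cluster_true = sample(1:3, 200, TRUE),
    age = rnorm(200, 53, 10), sex = rbinom(200, 1, 0.5),
    height = rnorm(200, 67, 4), bmi = rnorm(200, 30, 6)
  ))
  out <- generate_outcomes(rec, cfg, seed = 12)
  p <- summary(aov(fev1 ~ factor(cluster_true), data = out))[[1]][1, 5]
  expect_lt(p, 0.001)
})

test_that("deeply negative logistic intercept saturates VAS at zero", {
  cfg <- cohort_config(n_subjects = 100, seed = 7)
  om <- cfg$outcome_model
  om$vas$fibrotic$intercept <- -20
  om$vas$fibrotic$cluster <- rep(0, 3)
  cfg$outcome_model <- om
  cfg$p_missing <- 0
  rec <- withr::with_seed(9, tibble::tibble(
    subject_id = sprintf("S%03d", 1:100),
    cluster_true = sample(1:3, 100, TRUE),
    age = rnorm(100, 53, 10), sex = rbinom(100, 1, 0.5),
    height = rnorm(100, 67, 4), bmi = rnorm(100, 30, 6)
  ))
  out <- generate_outcomes(rec, cfg, seed = 13)
  expect_true(all(out$vas_fibrotic == 0))
})

test_that("cohort variogram features separate the planted clusters", {
  # within-mask texture must follow the cluster's Matern parameters:
  # higher-psill clusters produce higher empirical semivariance
  coh <- small_cohort()
  fm <- build_feature_matrix(coh, "empirical", "raw", registered = TRUE)
  rec <- coh$records[match(fm$subject_id, coh$records$subject_id), ]
  # average mid-lag semivariance over central deciles; with 8 subjects,
  # compare the extreme clusters (psill 400 vs 1600 HU^2)
  mid_cols <- intersect(c("left_d4_g08", "left_d5_g08", "left_d6_g08",
                          "right_d4_g08", "right_d5_g08", "right_d6_g08"),
                        names(fm))
  mid <- rowMeans(fm[, mid_cols])
  m_by_cluster <- tapply(mid, rec$cluster_true, mean)
  expect_gt(m_by_cluster[["3"]], m_by_cluster[["1"]])
})
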