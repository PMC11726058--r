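test_that("feature counts match the engineered design", {
  coh <- small_cohort()
  emp <- build_feature_matrix(coh, "empirical", "raw", registered = TRUE)
  expect_equal(ncol(emp) - 1, 270)  # 2 lungs x 9 deciles x 15 lags
  info <- attr(emp, "feature_info")
  expect_equal(nrow(info), 270)
  expect_false(any(duplicated(info$column)))
  exp_fm <- build_feature_matrix(coh, "exponential", "raw",
                                 registered = TRUE)
  expect_equal(ncol(exp_fm) - 1, 36)
  mat <- build_feature_matrix(coh, "matern", "raw", registered = TRUE)
  expect_equal(ncol(mat) - 1, 54)
  # no missing values among retained subjects
  expect_false(anyNA(emp))
  expect_false(anyNA(mat))
})

test_that("column order is lung, decile, kind", {
  coh <- small_cohort()
  fm <- build_feature_matrix(coh, "matern", "raw", registered = TRUE)
  cols <- setdiff(names(fm), "subject_id")
  expect_equal(cols[1:3], c("left_d1_psill", "left_d1_range",
                            "left_d1_kappa"))
  expect_equal(cols[28:30], c("right_d1_psill", "right_d1_range",
                              "right_d1_kappa"))
})

test_that("sill and range are log-z-scored, kappa left raw", {
  coh <- small_cohort()
  fm <- build_feature_matrix(coh, "matern", "raw", registered = TRUE)
  psill_cols <- grep("_psill$", names(fm), value = TRUE)
  for (cn in psill_cols[1:3]) {
    expect_lt(abs(mean(fm[[cn]])), 1e-10)
    expect_lt(abs(sd(fm[[cn]]) - 1), 1e-10)
  }
  kappa <- fm$left_d5_kappa
  expect_true(all(kappa > 0 & kappa <= 5))  # raw grid values
  sc <- attr(fm, "scaling")
  expect_true(all(grepl("_psill$|_range$", sc$column)))
})

test_that("gamma features are invariant to a constant HU offset", {
  coh <- small_cohort()
  coh2 <- coh
  for (i in seq_along(coh2$subjects)) {
    coh2$subjects[[i]]$hu <- coh2$subjects[[i]]$hu + 100
  }
  a <- build_feature_matrix(coh, "empirical", "raw", registered = TRUE)
  b <- build_feature_matrix(coh2, "empirical", "raw", registered = TRUE)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-8)
})

test_that("all 12 unharmonized datasets share one retained subject set", {
  coh <- small_cohort()
  fs <- engineer_features(coh)
  expect_length(fs$datasets, 12)
  ids <- lapply(fs$datasets, function(d) d$subject_id)
  for (i in seq_along(ids)) expect_identical(ids[[i]], ids[[1]])
  # counts per data type
  nc <- vapply(fs$datasets, ncol, integer(1)) - 1L
  expect_setequal(unique(nc), c(270L, 36L, 54L))
})

test_that("a subject failing anywhere is excluded everywhere", {
  coh <- small_cohort()
  coh2 <- coh
  # cripple one subject's native mask so trimming leaves < 10 slices
  m <- coh2$subjects[[2]]$mask_left
  keep <- c(14, 15, 16)
  for (s in seq_len(dim(m)[1])) if (!(s %in% keep)) m[s, , ] <- FALSE
  coh2$subjects[[2]]$mask_left <- m
  fs <- engineer_features(coh2)
  expect_true(coh2$subjects[[2]]$subject_id %in% fs$exclusions$subject_id)
  for (d in fs$datasets) {
    expect_false(coh2$subjects[[2]]$subject_id %in% d$subject_id)
  }
  # registered datasets were unaffected by the native mask, yet the
  # exclusion still applies there
  expect_equal(nrow(fs$datasets[["empirical_raw_registered_unharmonized"]]),
               length(coh2$subjects) - 1)
})

test_that("decile selection depends on the mask only, not HU content", {
  coh <- small_cohort()
  s <- coh$subjects[[1]]
  counts <- apply(s$mask_left, 1, sum)
  d1 <- select_decile_slices(trim_slices(counts, coh$config$min_voxels))
  s2 <- s
  s2$hu <- s$hu * 3 + 17
  counts2 <- apply(s2$mask_left, 1, sum)
  d2 <- select_decile_slices(trim_slices(counts2, coh$config$min_voxels))
  expect_identical(d1, d2)
})
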