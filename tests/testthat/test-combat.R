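make_records <- function(n, batch) {
  withr::with_seed(42, tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    scanner_id = batch,
    scadding = sample(0:4, n, TRUE),
    height = rnorm(n, 67, 4),
    age = rnorm(n, 53, 10),
    bmi = rnorm(n, 30, 6),
    sex = rbinom(n, 1, 0.5)
  ))
}

as_fm <- function(X, records) {
  tibble::tibble(subject_id = records$subject_id,
                 !!!stats::setNames(as.data.frame(X),
                                    paste0("f", seq_len(ncol(X)))))
}

test_that("a single batch returns the input unchanged", {
  n <- 40
  rec <- make_records(n, rep("only", n))
  X <- withr::with_seed(1, matrix(rnorm(n * 5), n, 5))
  fm <- as_fm(X, rec)
  hm <- combat_fit_apply(fm, rec)
  expect_equal(as.matrix(hm[, -1]), as.matrix(fm[, -1]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("planted additive batch shift is removed", {
  n <- 1000  # 500 per batch
  batch <- rep(c("a", "b"), each = n / 2)
  rec <- make_records(n, batch)
  X <- withr::with_seed(2, matrix(rnorm(n * 8), n, 8))
  X[batch == "b", ] <- X[batch == "b", ] + 1.5
  hm <- combat_fit_apply(as_fm(X, rec), rec)
  rec_kept <- rec[match(hm$subject_id, rec$subject_id), ]
  r2 <- vapply(seq_len(8), function(j) {
    scanner_anova(hm[[j + 1]], rec_kept$scanner_id)$r2
  }, numeric(1))
  r2_pre <- vapply(seq_len(8), function(j) {
    scanner_anova(X[, j], batch)$r2
  }, numeric(1))
  expect_gt(min(r2_pre), 0.3)
  expect_lt(max(r2), 0.01)
})

test_that("agrees with the reference parametric ComBat implementation", {
  skip_if_not_installed("sva")
  n <- 120
  batch <- rep(c("a", "b", "c"), each = n / 3)
  rec <- make_records(n, batch)
  X <- withr::with_seed(3, matrix(rnorm(n * 10), n, 10) +
                          outer(as.integer(factor(batch)), rnorm(10)))
  hm <- combat_fit_apply(as_fm(X, rec), rec)
  mod <- stats::model.matrix(~ factor(scadding) + height + age + bmi + sex,
                             data = rec)
  ref <- t(sva::ComBat(t(X), batch = batch, mod = mod, par.prior = TRUE))
  expect_lt(max(abs(as.matrix(hm[, -1]) - ref)), 1e-4)
})

test_that("covariate-linked group differences survive harmonization", {
  n <- 600
  batch <- rep(c("a", "b"), each = n / 2)
  rec <- make_records(n, batch)
  # sex-linked mean shift, no batch effect
  X <- withr::with_seed(4, matrix(rnorm(n * 6), n, 6) + 2 * rec$sex)
  hm <- combat_fit_apply(as_fm(X, rec), rec)
  rec_kept <- rec[match(hm$subject_id, rec$subject_id), ]
  for (j in 1:3) {
    before <- coef(lm(X[, j] ~ rec$sex))[2]
    after <- coef(lm(hm[[j + 1]] ~ rec_kept$sex))[2]
    expect_lt(abs(after - before) / abs(before), 0.1)
  }
})

test_that("harmonization is approximately idempotent on balanced batches", {
  # empirical-Bayes shrinkage leaves a small residual batch effect after
  # one pass (shrinkage weights are moment-matched across features), so a
  # second pass still moves values slightly; it must move them far less
  # than the first pass did, and by only a few percent overall
  n <- 400
  batch <- rep(c("a", "b"), each = n / 2)
  rec <- make_records(n, batch)
  X <- withr::with_seed(5, matrix(rnorm(n * 6), n, 6))
  X[batch == "b", ] <- 1.3 * X[batch == "b", ] + 0.8
  fm <- as_fm(X, rec)
  h1 <- combat_fit_apply(fm, rec)
  h2 <- combat_fit_apply(h1, rec)
  kept <- match(h1$subject_id, fm$subject_id)
  pass1 <- max(abs(as.matrix(h1[, -1]) - as.matrix(fm[kept, -1])))
  pass2 <- max(abs(as.matrix(h2[, -1]) - as.matrix(h1[, -1])))
  denom <- max(abs(as.matrix(h1[, -1])))
  expect_lt(pass2 / denom, 0.05)
  expect_lt(pass2, 0.1 * pass1)
})

test_that("subjects with missing covariates are dropped, model exported", {
  n <- 60
  batch <- rep(c("a", "b"), each = n / 2)
  rec <- make_records(n, batch)
  rec$scadding[c(3, 17)] <- NA
  X <- withr::with_seed(6, matrix(rnorm(n * 4), n, 4))
  hm <- combat_fit_apply(as_fm(X, rec), rec)
  expect_equal(nrow(hm), n - 2)
  expect_setequal(attr(hm, "dropped_subjects"),
                  rec$subject_id[c(3, 17)])
  model <- attr(hm, "harmonization_model")
  expect_equal(model$batch_levels, c("a", "b"))
  expect_true(all(model$delta_star > 0))
  expect_equal(dim(model$gamma_star), c(2, 4))
})

test_that("single-subject batches and collinear designs fail loudly", {
  n <- 21
  batch <- c(rep("a", 20), "b")
  rec <- make_records(n, batch)
  X <- withr::with_seed(7, matrix(rnorm(n * 3), n, 3))
  expect_error(combat_fit_apply(as_fm(X, rec), rec), "batch")
  rec2 <- make_records(20, rep(c("a", "b"), each = 10))
  rec2$height <- rec2$age  # collinear
  X2 <- withr::with_seed(8, matrix(rnorm(20 * 3), 20, 3))
  expect_error(combat_fit_apply(as_fm(X2, rec2), rec2), "collinear")
})
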