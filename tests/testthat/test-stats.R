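test_that("one-way ANOVA R2 matches the hand computation", {
  # groups {1,2,3} and {2,3,4}: grand mean 2.5, SSB = 3(0.5^2)*2 = 1.5,
  # SSW = 2 + 2 = 4, SST = SSB + SSW = 5.5, so R2 = 1.5/5.5
  res <- scanner_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(res$r2, 1.5 / 5.5, tolerance = 1e-12)
  expect_equal(scanner_anova(rep(5, 8), rep(c("a", "b"), 4)),
               tibble::tibble(r2 = 0, p_value = 1))
  perfect <- scanner_anova(rep(1:3, each = 4), rep(c("a", "b", "c"),
                                                   each = 4))
  expect_equal(perfect$r2, 1)
})

test_that("vectorized scanner ANOVA agrees with the scalar version", {
  withr::with_seed(1, {
    X <- matrix(rnorm(60 * 5), 60, 5)
    colnames(X) <- paste0("f", 1:5)
    g <- sample(c("a", "b", "c"), 60, TRUE)
    vec <- variophen:::scanner_anova_matrix(X, g)
    for (j in 1:5) {
      ref <- scanner_anova(X[, j], g)
      expect_equal(vec$r2[j], ref$r2, tolerance = 1e-10)
      expect_equal(vec$p_value[j], ref$p_value, tolerance = 1e-10)
    }
  })
})

test_that("ICC(3,1) oracle cases", {
  x <- c(1, 2, 3, 4, 6)
  expect_equal(icc31(x, x), 1)
  expect_equal(icc31(x, x + 7), 1)  # consistency ignores fixed shifts
  # brute-force two-way ANOVA oracle on a hand fixture
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 10)
  long <- data.frame(val = c(x, y),
                     subj = factor(rep(1:4, 2)),
                     rater = factor(rep(1:2, each = 4)))
  av <- anova(lm(val ~ subj + rater, data = long))
  ms_subj <- av["subj", "Mean Sq"]
  ms_err <- av["Residuals", "Mean Sq"]
  expect_equal(icc31(x, y), (ms_subj - ms_err) / (ms_subj + ms_err),
               tolerance = 1e-12)
  # vectorized version agrees
  expect_equal(variophen:::icc31_matrix(cbind(x), cbind(y)),
               icc31(x, y), tolerance = 1e-12)
})

test_that("Spearman correlation with midranks", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_warning(v <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(v))
})

test_that("bias-corrected Cramer's V oracle cases", {
  expect_equal(cramers_v_bc(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(cramers_v_bc(matrix(c(5, 5, 5, 5), 2)), 0)
  # zero-margin rows are dropped
  t3 <- rbind(c(10, 0, 0), c(0, 10, 0))
  expect_equal(cramers_v_bc(t3), 1)
})

test_that("bias correction removes the upward bias under independence", {
  uncorrected <- function(tab) {
    n <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / n
    sqrt(sum((tab - e)^2 / e) / n / (min(dim(tab)) - 1))
  }
  withr::with_seed(5, {
    vs <- t(vapply(1:400, function(i) {
      tab <- table(factor(sample(1:3, 200, TRUE), levels = 1:3),
                   factor(sample(1:4, 200, TRUE), levels = 1:4))
      c(bc = cramers_v_bc(tab), raw = uncorrected(tab))
    }, numeric(2)))
  })
  expect_lt(mean(vs[, "bc"]), mean(vs[, "raw"]))
  expect_lt(mean(vs[, "bc"]), 0.05)
})

test_that("simulated Fisher p agrees with the exact 2x2 test", {
  tab <- matrix(c(10, 0, 0, 10), 2)
  p_exact <- fisher.test(tab)$p.value  # 2 / choose(20, 10)
  p_sim <- fisher_sim_p(tab, n_rep = 20000, seed = 1)
  expect_lt(p_sim, 0.001)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(p_sim - p_exact), 3 * mc_se + 2 / 20001)
  # a moderate table
  tab2 <- matrix(c(8, 4, 3, 9), 2)
  p2 <- fisher.test(tab2)$p.value
  s2 <- fisher_sim_p(tab2, n_rep = 20000, seed = 2)
  expect_lt(abs(s2 - p2), 3 * sqrt(p2 * (1 - p2) / 20000))
  # identical rows: no association
  expect_gt(fisher_sim_p(matrix(c(50, 50, 50, 50), 2), seed = 3), 0.99)
})

test_that("simulated Fisher p is reproducible under a fixed seed", {
  tab <- matrix(c(6, 2, 3, 7), 2)
  expect_identical(fisher_sim_p(tab, 2000, seed = 9),
                   fisher_sim_p(tab, 2000, seed = 9))
})

test_that("linear model fit: R2 and loglik against base R", {
  withr::with_seed(11, {
    d <- data.frame(a = rnorm(30), b = rnorm(30))
    y <- 1 + 2 * d$a - d$b + rnorm(30, sd = 0.3)
    f <- lm_fit(y, d)
    ref <- lm(y ~ a + b, data = d)
    expect_equal(f$r2, summary(ref)$r.squared, tolerance = 1e-12)
    expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
    # exact linear outcome and null design
    expect_equal(lm_fit(1 + 2 * d$a, d["a"])$r2, 1)
    expect_equal(lm_fit(y, d[, 0])$r2, 0)
  })
  # 6-point hand-checkable fit against the normal equations
  x <- c(0, 1, 2, 3, 4, 5)
  y6 <- c(1, 3, 2, 5, 4, 7)
  f6 <- lm_fit(y6, data.frame(x = x))
  Xd <- cbind(1, x)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y6)
  r2 <- 1 - sum((y6 - Xd %*% beta)^2) / sum((y6 - mean(y6))^2)
  expect_equal(f6$r2, r2, tolerance = 1e-12)
})

test_that("likelihood-ratio test basics and null calibration", {
  withr::with_seed(12, {
    d <- data.frame(a = rnorm(40), b = rnorm(40))
    y <- rnorm(40)
    full <- lm_fit(y, d)
    red <- lm_fit(y, d["a"])
    expect_equal(lrt(full, full), 1)
    expect_error(lrt(red, full), "nested")
    # duplicated column makes the design rank deficient
    d2 <- d
    d2$c <- d2$a
    expect_error(lm_fit(y, d2), "aliased")
  })
  # null p-values approximately uniform
  withr::with_seed(13, {
    ps <- vapply(1:1000, function(i) {
      x <- rnorm(60)
      y <- rnorm(60)
      lrt(lm_fit(y, data.frame(x = x)), lm_fit(y, data.frame(x = x)[, 0]))
    }, numeric(1))
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
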