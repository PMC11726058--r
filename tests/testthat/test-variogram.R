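test_that("empirical variogram matches hand-computed 3-point example", {
  ev <- empirical_variogram(c(0, 1, 2), cbind(c(0, 1, 2), c(0, 0, 0)),
                            cutoff = 2.5, n_bins = 2)
  expect_equal(ev$gamma_hat, c(0.5, 2))
  expect_equal(ev$n_pairs, c(2, 1))
  expect_equal(ev$h, c(1, 2))
})

test_that("empirical variogram equals brute-force all-pairs oracle", {
  for (drift in c("raw", "linear")) {
    for (seed in 1:3) {
      withr::with_seed(seed, {
        nr <- sample(6:12, 1)
        nc <- sample(6:12, 1)
        idx <- which(matrix(TRUE, nr, nc), arr.ind = TRUE)
        co <- cbind(idx[, 2] * 1.0, idx[, 1] * 1.0)
        z <- rnorm(nrow(co)) + 0.3 * co[, 1]
        ev <- empirical_variogram(z, co, cutoff = 7.3, n_bins = 6,
                                  drift_mode = drift)
        or <- brute_variogram(z, co, cutoff = 7.3, n_bins = 6,
                              drift_mode = drift)
        expect_equal(ev$bin, or$bin)
        expect_equal(ev$h, or$h, tolerance = 1e-12)
        expect_equal(ev$gamma_hat, or$gamma_hat, tolerance = 1e-12)
        expect_equal(ev$n_pairs, or$n_pairs)
      })
    }
  }
})

test_that("constant field and exact plane behave as expected", {
  idx <- which(matrix(TRUE, 8, 8), arr.ind = TRUE)
  co <- cbind(idx[, 2] * 1.0, idx[, 1] * 1.0)
  expect_true(all(empirical_variogram(rep(4, 64), co, 10, 5)$gamma_hat == 0))
  plane <- 2 * co[, 1] + 3 * co[, 2]
  expect_true(all(abs(empirical_variogram(plane, co, 10, 5,
                                          "linear")$gamma_hat) < 1e-20))
  expect_true(all(empirical_variogram(plane, co, 10, 5,
                                      "raw")$gamma_hat > 0))
})

test_that("voxel ordering does not change the variogram", {
  withr::with_seed(4, {
    idx <- which(matrix(TRUE, 9, 9), arr.ind = TRUE)
    co <- cbind(idx[, 2] * 1.0, idx[, 1] * 1.0)
    z <- rnorm(81)
    perm <- sample(81)
    a <- empirical_variogram(z, co, 8, 5)
    b <- empirical_variogram(z[perm], co[perm, ], 8, 5)
    expect_equal(a$gamma_hat, b$gamma_hat, tolerance = 1e-12)
    expect_equal(a$n_pairs, b$n_pairs)
  })
})

test_that("insufficient data raises a classed slice-level failure", {
  expect_error(empirical_variogram(1, cbind(0, 0), 5, 5),
               class = "variophen_insufficient_data")
  expect_error(empirical_variogram(c(1, 2), cbind(c(0, 100), c(0, 0)), 5, 5),
               class = "variophen_insufficient_data")
})

test_that("Matern correlation closed forms hold", {
  h <- c(0, 0.5, 1, 3, 7, 20)
  expect_equal(matern_correlation(0, 3, 2.2), 1)
  expect_equal(matern_correlation(h, 5, 0.5), exp(-h / 5),
               tolerance = 1e-12)
  expect_equal(matern_correlation(h, 5, 1.5), (1 + h / 5) * exp(-h / 5),
               tolerance = 1e-10)
  # strictly decreasing, vanishing at infinity
  r <- matern_correlation(seq(0, 50, by = 0.5), 4, 2.7)
  expect_true(all(diff(r) < 0))
  expect_lt(matern_correlation(1e4, 4, 2.7), 1e-10)
})

test_that("variogram model form: zero at origin, sill at infinity", {
  expect_equal(variogram_model(0, "exponential", 2, 5), 0)
  expect_equal(variogram_model(5, "exponential", 1, 5), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(variogram_model(5e6, "matern", 3, 5, kappa = 1.3), 3,
               tolerance = 1e-8)
  g <- variogram_model(seq(0, 40, 0.5), "matern", 2, 6, kappa = 0.8)
  expect_true(all(diff(g) > 0))
})

make_emp <- function(gamma, h = seq(25 / 30, 25, length.out = 15),
                     np = rep(200, length(h))) {
  out <- tibble::tibble(bin = seq_along(h), h = h, gamma_hat = gamma,
                        n_pairs = np)
  structure(out, cutoff = max(h), n_bins = length(h), drift_mode = "raw",
            class = c("empirical_variogram", class(out)))
}

test_that("WLS fit recovers exact exponential data", {
  h <- seq(25 / 30, 25, length.out = 15)
  emp <- make_emp(variogram_model(h, "exponential", 1, 5), h)
  f <- fit_variogram_wls(emp, "exponential")
  expect_true(f$valid)
  expect_lt(abs(f$psill - 1), 1e-3)
  expect_lt(abs(f$range - 5) / 5, 1e-3)
  fm <- fit_variogram_wls(emp, "matern")
  expect_equal(fm$kappa, 0.5)
  expect_lte(fm$wsse, f$wsse + 1e-9)
})

test_that("WLS fit recovers exact Matern data including kappa", {
  h <- seq(25 / 30, 25, length.out = 15)
  emp <- make_emp(variogram_model(h, "matern", 2, 4, kappa = 1.5), h)
  f <- fit_variogram_wls(emp, "matern")
  expect_true(f$valid)
  expect_lt(abs(f$kappa - 1.5), 0.05)
  expect_lt(abs(f$psill - 2) / 2, 0.01)
  expect_lt(abs(f$range - 4) / 4, 0.02)
})

test_that("Matern grid fit never does worse than the exponential fit", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      h <- seq(25 / 30, 25, length.out = 15)
      g <- variogram_model(h, "exponential", 2, sample(2:8, 1)) *
        exp(rnorm(15, 0, 0.15))
      np <- round(runif(15, 20, 400))
      emp <- make_emp(g, h, np)
      fe <- fit_variogram_wls(emp, "exponential")
      fm <- fit_variogram_wls(emp, "matern")
      expect_lte(fm$wsse, fe$wsse + 1e-9 * max(1, fe$wsse))
    })
  }
})

test_that("psill scales quadratically under HU rescaling, range invariant", {
  withr::with_seed(9, {
    h <- seq(25 / 30, 25, length.out = 15)
    g <- variogram_model(h, "exponential", 1.5, 6) * exp(rnorm(15, 0, 0.1))
    emp <- make_emp(g, h)
    emp4 <- make_emp(4 * g, h)  # z -> 2 z scales gamma by 4
    f1 <- fit_variogram_wls(emp, "exponential")
    f4 <- fit_variogram_wls(emp4, "exponential")
    expect_equal(f4$psill / f1$psill, 4, tolerance = 1e-6)
    expect_equal(f4$range, f1$range, tolerance = 1e-6)
  })
})

test_that("degenerate and invalid fits are flagged, not raised", {
  emp0 <- make_emp(rep(0, 15))
  f0 <- fit_variogram_wls(emp0, "exponential")
  expect_false(f0$valid)
  # decreasing empirical variogram drives the profiled psill negative or
  # the fit degenerate; either way valid = FALSE and no error
  empd <- make_emp(seq(2, 0.1, length.out = 15))
  fd <- fit_variogram_wls(empd, "exponential")
  expect_type(fd$valid, "logical")
  expect_error(fit_variogram_wls(make_emp(c(1, NA, rep(1, 13))), "matern"),
               "non-finite")
})
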