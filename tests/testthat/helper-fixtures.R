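# shared fixtures and independent oracles, computed lazily and cached for
# the whole test session

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small cohort shared across feature/pipeline tests
small_cohort <- function() {
  memo("small_cohort", generate_cohort(cohort_config(n_subjects = 8,
                                                     seed = 101)))
}

# brute-force all-pairs empirical variogram: independent R implementation
# of the binning rule (equal-width bins over (0, cutoff], h = mean pair
# distance, gamma = mean squared difference / 2)
brute_variogram <- function(values, coords, cutoff, n_bins,
                            drift_mode = "raw") {
  z <- values
  if (drift_mode == "linear") {
    z <- resid(lm(values ~ coords[, 1] + coords[, 2]))
  }
  n <- length(z)
  pairs <- t(combn(n, 2))
  d <- sqrt((coords[pairs[, 1], 1] - coords[pairs[, 2], 1])^2 +
              (coords[pairs[, 1], 2] - coords[pairs[, 2], 2])^2)
  keep <- d > 0 & d <= cutoff
  pairs <- pairs[keep, , drop = FALSE]
  d <- d[keep]
  sq <- (z[pairs[, 1]] - z[pairs[, 2]])^2
  width <- cutoff / n_bins
  bin <- pmin(pmax(ceiling(d / width), 1), n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    idx <- bin == b
    if (!any(idx)) return(NULL)
    data.frame(bin = b, h = mean(d[idx]), gamma_hat = sum(sq[idx]) /
                 (2 * sum(idx)), n_pairs = sum(idx))
  })
  do.call(rbind, out)
}

# hard-labeled Gaussian data with planted clusters and noise features
planted_clusters <- function(n = 200, k = 3, sep = 6, p_rel = 6,
                             p_noise = 30, seed = 1) {
  withr::with_seed(seed, {
    z <- sample(seq_len(k), n, replace = TRUE)
    mu <- outer(seq_len(k) - 1, rep(sep, p_rel))
    X <- cbind(mu[z, , drop = FALSE] + matrix(rnorm(n * p_rel), n, p_rel),
               matrix(rnorm(n * p_noise), n, p_noise))
    colnames(X) <- c(sprintf("rel%d", seq_len(p_rel)),
                     sprintf("noise%d", seq_len(p_noise)))
    list(X = X, z = z)
  })
}

expect_tbl_equal <- function(a, b, tol = 1e-10) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
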