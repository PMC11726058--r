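#' Simulate a stationary Gaussian random field slice with Matern covariance
#'
#' Draws one 2D realization of a zero-mean stationary, isotropic Gaussian
#' random field with covariance \eqn{C(h) = \sigma^2 \rho_{Matern}(h; r,
#' \kappa)}, then adds independent Gaussian voxel noise with standard
#' deviation `noise_sd` and a planar drift `drift_slope[1] * x +
#' drift_slope[2] * y` (mm coordinates). Under the Matern model the
#' noise-free field has theoretical variogram `psill * (1 - rho(h))`, which is
#' what the estimation side of the package is designed to recover.
#'
#' Two exact simulation methods are used: dense Cholesky factorization of the
#' full covariance matrix (with 1e-8 diagonal jitter) for grids up to 128^2
#' voxels, and circulant embedding on an enlarged torus (Dietrich-Newsam)
#' above that. The Cholesky factor can be precomputed with
#' [grf_cholesky_factor()] and passed in to amortize the factorization across
#' many slices sharing the same covariance.
#'
#' @param matern named numeric vector or list with `psill` (HU^2), `range`
#'   (mm), `kappa`.
#' @param shape integer vector `(rows, cols)`.
#' @param drift_slope numeric length 2, HU per mm along x (column) and y
#'   (row); default `c(0, 0)`.
#' @param noise_sd independent noise standard deviation (HU), default 0.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param voxel_size_mm voxel edge length (mm), default 1.
#' @param method `"auto"` (Cholesky up to 128^2 voxels, circulant above),
#'   `"cholesky"`, or `"circulant"`.
#' @param chol_factor optional precomputed factor from
#'   [grf_cholesky_factor()].
#' @return numeric `rows x cols` matrix of HU values.
#' @examples
#' f <- simulate_grf_slice(c(psill = 1, range = 5, kappa = 0.5),
#'                         shape = c(16, 16), seed = 1)
#' @export
simulate_grf_slice <- function(matern, shape, drift_slope = c(0, 0),
                               noise_sd = 0, seed = 1, voxel_size_mm = 1,
                               method = c("auto", "cholesky", "circulant"),
                               chol_factor = NULL) {
  method <- match.arg(method)
  psill <- matern[["psill"]]; rng <- matern[["range"]]; kap <- matern[["kappa"]]
  stopifnot(psill >= 0, rng > 0, kap > 0, length(shape) == 2, all(shape >= 1))
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  nvox <- rows * cols
  if (method == "auto") {
    method <- if (nvox <= 128^2) "cholesky" else "circulant"
  }
  with_seed(seed, {
    field <- if (psill == 0) {
      matrix(0, rows, cols)
    } else if (method == "cholesky") {
      if (is.null(chol_factor)) {
        chol_factor <- grf_cholesky_factor(c(psill = psill, range = rng,
                                             kappa = kap),
                                           shape, voxel_size_mm)
      }
      matrix(crossprod(chol_factor, rnorm(nvox)), rows, cols)
    } else {
      grf_circulant_draw(psill, rng, kap, rows, cols, voxel_size_mm)
    }
    if (noise_sd > 0) field <- field + matrix(rnorm(nvox, sd = noise_sd),
                                              rows, cols)
    if (any(drift_slope != 0)) {
      xs <- (seq_len(cols) - 1) * voxel_size_mm
      ys <- (seq_len(rows) - 1) * voxel_size_mm
      field <- field + outer(ys, xs, function(y, x) {
        drift_slope[1] * x + drift_slope[2] * y
      })
    }
    field
  })
}

#' Precompute the Cholesky factor of a Matern grid covariance
#'
#' @inheritParams simulate_grf_slice
#' @return upper-triangular Cholesky factor `R` with `t(R) %*% R` equal to
#'   the (jittered) covariance of the vectorized grid, voxels in
#'   column-major order.
#' @export
grf_cholesky_factor <- function(matern, shape, voxel_size_mm = 1) {
  psill <- matern[["psill"]]; rng <- matern[["range"]]; kap <- matern[["kappa"]]
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  nvox <- rows * cols
  if (nvox > 128^2) {
    stop("dense Cholesky restricted to grids <= 128^2 voxels; use circulant")
  }
  idx <- seq_len(nvox) - 1L
  x <- (idx %/% rows) * voxel_size_mm
  y <- (idx %% rows) * voxel_size_mm
  d <- as.matrix(dist(cbind(x, y)))
  C <- psill * matrix(cpp_matern_rho(as.numeric(d), rng, kap), nvox, nvox)
  diag(C) <- diag(C) + 1e-8
  out <- tryCatch(chol(C), error = function(e) {
    stop("covariance not positive definite after jitter: ",
         conditionMessage(e))
  })
  out
}

# circulant embedding draw (Dietrich & Newsam); exact when the embedded
# circulant spectrum is nonnegative, with padding doubled once on failure
grf_circulant_draw <- function(psill, rng, kap, rows, cols, voxel_size_mm) {
  for (pad in c(2L, 4L)) {
    M <- stats::nextn(pad * rows, 2)
    N <- stats::nextn(pad * cols, 2)
    di <- pmin(0:(M - 1), M - (0:(M - 1))) * voxel_size_mm
    dj <- pmin(0:(N - 1), N - (0:(N - 1))) * voxel_size_mm
    dmat <- sqrt(outer(di^2, dj^2, `+`))
    Cc <- psill * matrix(cpp_matern_rho(as.numeric(dmat), rng, kap), M, N)
    lambda <- Re(fft(Cc))
    if (min(lambda) >= -1e-6 * max(lambda)) {
      lambda[lambda < 0] <- 0
      z <- matrix(complex(real = rnorm(M * N), imaginary = rnorm(M * N)), M, N)
      e <- fft(sqrt(lambda) * z) / sqrt(M * N)
      return(Re(e)[seq_len(rows), seq_len(cols), drop = FALSE])
    }
  }
  stop("circulant embedding failed: negative spectrum after padding")
}
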