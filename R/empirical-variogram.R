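#' Empirical variogram of a masked 2D slice
#'
#' Matheron-type binned estimator of the semivariance
#' \eqn{\gamma(h) = \tfrac12 E[(z_i - z_j)^2]} over all unordered voxel pairs
#' of one masked axial slice. Distances are Euclidean in-plane distances in
#' mm; the interval \eqn{(0, cutoff]} is split into `n_bins` equal-width bins,
#' a pair contributes to the bin containing its distance, and a bin's
#' representative lag `h` is the mean pair distance within the bin (not the
#' midpoint). Bins with no pairs are dropped and recorded. With
#' `drift_mode = "linear"`, ordinary least-squares residuals of
#' `values ~ x + y` (with intercept) replace the raw values before pair
#' differencing, relaxing the constant-mean assumption to a planar drift.
#'
#' @param values numeric vector of HU values at masked voxels.
#' @param coords two-column matrix (x, y) of voxel center coordinates in mm.
#' @param cutoff maximum pair distance considered (mm), default 25.
#' @param n_bins number of equal-width distance bins, default 15.
#' @param drift_mode `"raw"` (assume a constant mean) or `"linear"` (remove a
#'   fitted planar drift first).
#' @return a tibble of class `empirical_variogram` with columns `bin`, `h`,
#'   `gamma_hat`, `n_pairs` (empty bins dropped) and attributes `cutoff`,
#'   `n_bins`, `drift_mode`, `dropped_bins`.
#' @examples
#' ev <- empirical_variogram(c(0, 1, 2), cbind(c(0, 1, 2), 0),
#'                           cutoff = 2.5, n_bins = 2)
#' ev$gamma_hat # 0.5, 2
#' @export
empirical_variogram <- function(values, coords, cutoff = 25, n_bins = 15,
                                drift_mode = c("raw", "linear")) {
  drift_mode <- match.arg(drift_mode)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, cutoff > 0, n_bins >= 1)
  if (length(values) != nrow(coords)) {
    stop("values and coords must have matching lengths")
  }
  if (length(values) < 2) {
    insufficient_data("fewer than 2 voxels in slice")
  }
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (!all(is.finite(values))) stop("values must be finite")
  z <- values
  if (drift_mode == "linear") {
    z <- resid(lm.fit(cbind(1, coords), values))
  }
  res <- cpp_empirical_variogram(coords[, 1], coords[, 2], z,
                                 as.numeric(cutoff), as.integer(n_bins))
  keep <- res$np > 0
  if (!any(keep)) {
    insufficient_data("no voxel pair within cutoff")
  }
  out <- tibble::tibble(
    bin = which(keep),
    h = res$h[keep],
    gamma_hat = res$gamma[keep],
    n_pairs = res$np[keep]
  )
  structure(out,
            cutoff = cutoff, n_bins = n_bins, drift_mode = drift_mode,
            dropped_bins = which(!keep),
            class = c("empirical_variogram", class(out)))
}

# classed condition so slice-level failures can be carried per subject
insufficient_data <- function(msg) {
  stop(structure(class = c("variophen_insufficient_data", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @export
autoplot.empirical_variogram <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$h, y = .data$gamma_hat)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "lag h (mm)", y = expression(hat(gamma)(h) ~ (HU^2)),
                  size = "pairs")
  if (!is.null(fit) && isTRUE(fit$valid)) {
    hs <- seq(min(object$h) / 4, max(object$h), length.out = 200)
    curve_df <- tibble::tibble(
      h = hs,
      gamma = variogram_model(hs, fit$family, fit$psill, fit$range, fit$kappa)
    )
    p <- p + ggplot2::geom_line(data = curve_df,
                                ggplot2::aes(x = .data$h, y = .data$gamma),
                                inherit.aes = FALSE, colour = "steelblue")
  }
  p
}
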