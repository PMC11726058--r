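#' Default Matern smoothness grid
#'
#' The kappa values searched when fitting the Matern family: 0.01 to 5 in
#' steps of 0.01 (500 points). The grid contains 0.5, so the exponential
#' model is nested in every Matern grid search.
#' @return numeric vector of length 500.
#' @export
default_kappa_grid <- function() seq(0.01, 5, by = 0.01)

#' Fit an exponential or Matern variogram model by weighted least squares
#'
#' Minimizes the Cressie-weighted sum of squares
#' \deqn{\sum_j w_j\,(\hat\gamma(h_j) - \gamma(h_j;\theta))^2, \qquad
#'   w_j = N_j / \gamma(h_j;\theta)^2,}
#' over \eqn{\theta = (\sigma^2, r)} with the nugget fixed at zero. Weights
#' depend on the current model values and are recomputed by iteratively
#' reweighted least squares (Gauss-Newton inner solve; outer reweighting
#' until the relative change in the weighted SSE falls below `tol`, at most
#' `max_iter` passes). Initialization is `psill = max(gamma_hat)`,
#' `range = 1`. For the Matern family the smoothness `kappa` is not fit
#' continuously: each value of `kappa_grid` is fit in turn and the grid point
#' with minimal weighted SSE is returned (ties to the smallest kappa). The
#' exponential family fixes `kappa = 0.5`.
#'
#' Parameters are not constrained to be positive during optimization; a fit
#' whose optimum has `psill <= 0` or `range <= 0` (or that fails) is returned
#' with `valid = FALSE` rather than raising, so that subject-level exclusion
#' can be handled downstream.
#'
#' @param emp an [empirical_variogram] object with at least two retained bins.
#' @param family `"exponential"` or `"matern"`.
#' @param kappa_grid numeric grid of kappa values for the Matern family;
#'   default [default_kappa_grid()].
#' @param max_iter maximum reweighting passes (default 200).
#' @param tol relative weighted-SSE tolerance for reweighting (default 1e-8).
#' @return an object of class `variogram_fit`: list with `family`, `psill`,
#'   `range`, `kappa`, `nugget` (always 0), `wsse`, `converged`, `valid`.
#' @export
fit_variogram_wls <- function(emp, family = c("exponential", "matern"),
                              kappa_grid = default_kappa_grid(),
                              max_iter = 200, tol = 1e-8) {
  family <- match.arg(family)
  if (!inherits(emp, "empirical_variogram")) {
    stop("emp must be an empirical_variogram")
  }
  if (nrow(emp) < 2) stop("need at least 2 retained bins to fit")
  if (!all(is.finite(emp$gamma_hat))) stop("non-finite gamma_hat")
  grid <- if (family == "exponential") 0.5 else as.numeric(kappa_grid)
  if (all(emp$gamma_hat == 0)) {
    return(new_variogram_fit(family, 0, 0, if (family == "exponential") 0.5
                             else grid[1], 0, FALSE, FALSE))
  }
  res <- cpp_fit_variogram(emp$h, emp$gamma_hat, emp$n_pairs, grid,
                           max(emp$gamma_hat), 1.0,
                           as.integer(max_iter), tol)
  valid <- is.finite(res$psill) && is.finite(res$range) &&
    res$psill > 0 && res$range > 0
  new_variogram_fit(family, res$psill, res$range, res$kappa, res$wsse,
                    isTRUE(res$converged), valid)
}

new_variogram_fit <- function(family, psill, range, kappa, wsse, converged,
                              valid) {
  structure(list(family = family, psill = psill, range = range, kappa = kappa,
                 nugget = 0, wsse = wsse, converged = converged,
                 valid = valid),
            class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf("<variogram_fit> %s: psill=%.4g range=%.4g kappa=%.3g wsse=%.4g %s\n",
              x$family, x$psill, x$range, x$kappa, x$wsse,
              if (x$valid) "" else "(invalid)"))
  invisible(x)
}

#' @rdname fit_variogram_wls
#' @param x a `variogram_fit`.
#' @param ... unused.
#' @export
tidy.variogram_fit <- function(x, ...) {
  tibble::tibble(
    term = c("psill", "range", "kappa", "nugget"),
    estimate = c(x$psill, x$range, x$kappa, x$nugget)
  )
}

#' @rdname fit_variogram_wls
#' @export
glance.variogram_fit <- function(x, ...) {
  tibble::tibble(family = x$family, psill = x$psill, range = x$range,
                 kappa = x$kappa, nugget = x$nugget, wsse = x$wsse,
                 converged = x$converged, valid = x$valid)
}
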