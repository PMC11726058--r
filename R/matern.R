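#' Matern correlation function
#'
#' Classical (gstat-convention) Matern correlation
#' \deqn{\rho(h) = \frac{2^{1-\kappa}}{\Gamma(\kappa)}\,(h/r)^{\kappa}\,
#'   K_{\kappa}(h/r),}
#' where \eqn{K_\kappa} is the modified Bessel function of the second kind,
#' \eqn{r} the range parameter and \eqn{\kappa} the smoothness. At
#' \eqn{\kappa = 0.5} this is the exponential correlation
#' \eqn{\exp(-h/r)}; \eqn{\kappa \to \infty} approaches the Gaussian model.
#' Evaluation is carried out in log space so large \eqn{\kappa} and extreme
#' lags do not overflow.
#'
#' @param h numeric vector of nonnegative lag distances (mm).
#' @param range positive range parameter (mm). This is the model's distance
#'   scale parameter, not the practical range.
#' @param kappa positive smoothness parameter (unitless).
#' @return numeric vector of correlations in \eqn{[0, 1]}; \code{rho(0) = 1}.
#' @examples
#' matern_correlation(0:5, range = 5, kappa = 0.5)
#' all.equal(matern_correlation(3, 5, 0.5), exp(-3 / 5))
#' @export
matern_correlation <- function(h, range, kappa) {
  stopifnot(range > 0, kappa > 0, all(h >= 0))
  cpp_matern_rho(as.numeric(h), range, kappa)
}

#' Theoretical variogram of an exponential or Matern model
#'
#' For a stationary field with covariance \eqn{C(h) = \sigma^2 \rho(h)} the
#' variogram is \eqn{\gamma(h) = C(0) - C(h) = \tau^2 + \sigma^2 (1 - \rho(h))}
#' with nugget \eqn{\tau^2} (zero throughout this package) and partial sill
#' \eqn{\sigma^2}.
#'
#' @param h numeric vector of lag distances (mm).
#' @param family `"exponential"` or `"matern"`.
#' @param psill partial sill (HU^2).
#' @param range range parameter (mm).
#' @param kappa Matern smoothness; ignored (fixed at 0.5) for the exponential
#'   family.
#' @param nugget nugget variance (HU^2), default 0.
#' @return numeric vector of semivariances (HU^2), nondecreasing in `h`,
#'   approaching `nugget + psill`.
#' @examples
#' variogram_model(5, "exponential", psill = 1, range = 5) # 1 - exp(-1)
#' @export
variogram_model <- function(h, family = c("exponential", "matern"),
                            psill, range, kappa = 0.5, nugget = 0) {
  family <- match.arg(family)
  if (family == "exponential") kappa <- 0.5
  nugget + psill * (1 - matern_correlation(h, range, kappa))
}
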