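#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{\ell(\beta) + \tfrac12 \log\det I(\beta)} by Newton iterations with
#' the Firth-adjusted score \eqn{X^T(y - p + h(1/2 - p))} (h the hat
#' diagonal) and step-halving, yielding finite estimates even under
#' complete separation. The intercept-only fit with 0 successes of 10
#' gives fitted probability 0.5/11.
#'
#' @param outcome binary 0/1 response. One-class outcomes are allowed: the
#'   Jeffreys penalty keeps the fit finite (intercept-only with y successes
#'   of n gives fitted probability `(y + 1/2) / (n + 1)`); the AUC is `NA`
#'   in that case.
#' @param design data frame of covariates (possibly zero columns).
#' @param max_iter Newton iteration cap (default 200).
#' @param tol convergence tolerance on the score norm.
#' @return object of class `firth_fit`: list with `coefficients`,
#'   `penalized_loglik`, `loglik`, `fitted`, `auc` (training AUC by
#'   midrank Mann-Whitney), `df`, `n`, `converged`.
#' @export
firth_logistic <- function(outcome, design, max_iter = 200, tol = 1e-8) {
  df <- as.data.frame(design)
  ok <- !is.na(outcome) & complete.cases(df)
  y <- as.numeric(outcome[ok])
  df <- df[ok, , drop = FALSE]
  stopifnot(all(y %in% c(0, 1)))
  X <- if (ncol(df) == 0) matrix(1, length(y), 1,
                                 dimnames = list(NULL, "(Intercept)"))
  else model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  n <- length(y)
  beta <- rep(0, ncol(X))
  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * w
    info <- crossprod(X, XW)
    # hat diagonal of the weighted projection
    U <- chol(info)
    XiU <- X %*% backsolve(U, backsolve(U, diag(ncol(X)), transpose = TRUE))
    h <- rowSums(XiU * XW)
    score <- crossprod(X, y - p + h * (0.5 - p))
    grad_norm <- sqrt(sum(score^2))
    if (grad_norm < tol) {
      converged <- TRUE
      break
    }
    step <- drop(backsolve(U, backsolve(U, score, transpose = TRUE)))
    # monotone ascent on the penalized likelihood with step-halving; if no
    # step improves, the optimum is resolved to numeric precision
    lam <- 1
    improved <- FALSE
    repeat {
      ll_new <- pen_ll(beta + lam * step)
      if (is.finite(ll_new) && ll_new > ll_old) {
        improved <- TRUE
        break
      }
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    if (!improved) {
      converged <- TRUE
      break
    }
    beta <- beta + lam * step
    ll_old <- ll_new
  }
  if (!converged && grad_norm > 1) {
    stop(sprintf("Firth fit did not converge; gradient norm %.3g",
                 grad_norm))
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  ll <- sum(y * eta - log1p(exp(eta)))
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 penalized_loglik = as.numeric(ll_old), loglik = ll,
                 fitted = p, auc = auc_mann_whitney(y, p),
                 df = ncol(X), n = n, converged = converged,
                 X = X, y = y),
            class = "firth_fit")
}

# maximize the full-design penalized likelihood with the coefficients
# outside `free` fixed at zero (profile penalized likelihood of the
# nested hypothesis); the Jeffreys penalty always uses the full design
firth_constrained_pl <- function(y, X, free, max_iter = 200, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    sum(y * eta - log1p(exp(eta))) +
      0.5 * determinant(info, logarithm = TRUE)$modulus
  }
  ll_old <- pen_ll(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * w
    info <- crossprod(X, XW)
    U <- chol(info)
    XiU <- X %*% backsolve(U, backsolve(U, diag(ncol(X)), transpose = TRUE))
    h <- rowSums(XiU * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))[free]
    if (sqrt(sum(score^2)) < tol) break
    step_free <- solve(info[free, free, drop = FALSE], score)
    step <- rep(0, ncol(X))
    step[free] <- step_free
    lam <- 1
    improved <- FALSE
    repeat {
      ll_new <- pen_ll(beta + lam * step)
      if (is.finite(ll_new) && ll_new > ll_old) {
        improved <- TRUE
        break
      }
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    if (!improved) break
    beta <- beta + lam * step
    ll_old <- ll_new
  }
  as.numeric(ll_old)
}

#' Training AUC by midrank Mann-Whitney
#'
#' @param y binary labels.
#' @param score numeric scores (higher = more positive).
#' @return AUC in `[0, 1]`; ties handled by midranks, so the value is
#'   invariant under monotone transformations of the scores.
#' @export
auc_mann_whitney <- function(y, score) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Penalized likelihood-ratio test between nested Firth fits
#'
#' Twice the difference in penalized log-likelihood referred to chi-square
#' with df equal to the parameter difference. The reduced model is scored
#' as a constrained fit of the full design (tested coefficients fixed at
#' zero) so both penalized likelihoods carry the same Jeffreys penalty —
#' comparing penalties of different dimensions would inflate the null
#' statistic.
#'
#' @param firth_full,firth_reduced [firth_logistic()] fits on the same
#'   observations, the reduced design's terms a subset of the full one's.
#' @return p-value; identical models give 1.
#' @export
plrt <- function(firth_full, firth_reduced) {
  if (firth_full$n != firth_reduced$n) {
    stop("models fitted on different observation sets")
  }
  df_diff <- firth_full$df - firth_reduced$df
  if (df_diff < 0) stop("models not nested: full has fewer parameters")
  if (df_diff == 0) return(1)
  free <- colnames(firth_full$X) %in% names(firth_reduced$coefficients)
  if (sum(free) != firth_reduced$df) {
    stop("models not nested: reduced terms are not a subset of the full design")
  }
  pl0 <- firth_constrained_pl(firth_full$y, firth_full$X, free)
  stat <- 2 * (firth_full$penalized_loglik - pl0)
  pchisq(max(stat, 0), df = df_diff, lower.tail = FALSE)
}

#' @export
tidy.firth_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.firth_fit <- function(x, ...) {
  tibble::tibble(penalized_loglik = x$penalized_loglik, loglik = x$loglik,
                 auc = x$auc, df = x$df, n = x$n, converged = x$converged)
}
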