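# ---- diagonal Gaussian mixture with irrelevant-feature model ----------------

# feature matrix input: accepts a feature_matrix tibble (subject_id column
# dropped) or a plain numeric matrix
as_feature_X <- function(features) {
  if (is.matrix(features)) return(features)
  cols <- setdiff(names(features), "subject_id")
  X <- as.matrix(features[, cols])
  rownames(X) <- features$subject_id %||% NULL
  X
}

log_rowsumexp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# per-feature Gaussian loglik of columns of X under a single (mean, MLE var)
common_feature_loglik <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  v <- colMeans(sweep(X, 2, mu)^2)
  v <- pmax(v, 1e-12)
  -0.5 * n * (log(2 * pi * v) + 1)
}

# k-means++-style seeding on internally standardized columns (so that the
# initialization, and hence the whole fit, is equivariant under per-feature
# affine rescaling)
kmeanspp_centers <- function(Xs, K) {
  n <- nrow(Xs)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  if (K > 1) {
    d2 <- rowSums(sweep(Xs, 2, Xs[centers[1], ])^2)
    for (k in 2:K) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      centers[k] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, rowSums(sweep(Xs, 2, Xs[centers[k], ])^2))
    }
  }
  centers
}

#' Fit a sparse diagonal Gaussian mixture for fixed K and relevance
#'
#' EM for a mixture of diagonal Gaussians on the relevant features; each
#' irrelevant feature is modelled by a single Gaussian common to all
#' clusters (homoscedastic irrelevance). The observed-data log-likelihood is
#' nondecreasing across EM iterations; the best of `n_starts` random
#' k-means++-style initializations is returned. Components that empty out
#' are re-seeded from the lowest-density subject; starts that end with a
#' degenerate (collapsed-variance) component are discarded, and an error is
#' raised if every start degenerates.
#'
#' The criterion fields use the maximization convention
#' `BIC = loglik - (n_params / 2) * log(n)` (larger is better), with
#' `n_params = (K - 1) + 2 K p_rel + 2 p_irr`; MICL is the integrated
#' complete-data likelihood of the hard partition under conjugate
#' Normal-inverse-Gamma priors (see [micl_score()]).
#'
#' @param features `feature_matrix`, tibble with `subject_id`, or numeric
#'   matrix (subjects x features).
#' @param K number of clusters (>= 1).
#' @param relevance logical vector per feature; `NULL` = all relevant.
#' @param seed integer master seed (start seeds derived from it).
#' @param n_starts number of initializations (default 20).
#' @param max_iter,tol EM iteration cap and relative loglik tolerance.
#' @param init optional hard label vector used as a warm start; when given
#'   it is run first and the random starts are skipped unless it
#'   degenerates.
#' @return object of class `cluster_model`.
#' @export
fit_gmm_diag <- function(features, K, relevance = NULL, seed = 1,
                         n_starts = 20, max_iter = 200, tol = 1e-8,
                         init = NULL) {
  X <- as_feature_X(features)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(K >= 1, n > K)
  if (is.null(relevance)) relevance <- rep(TRUE, p)
  stopifnot(length(relevance) == p)
  ll_irr <- if (any(!relevance)) {
    sum(common_feature_loglik(X[, !relevance, drop = FALSE]))
  } else 0
  Xr <- X[, relevance, drop = FALSE]
  pr <- ncol(Xr)
  if (K == 1 || pr == 0) {
    mu <- if (pr > 0) matrix(colMeans(Xr), 1) else matrix(0, 1, 0)
    s2 <- if (pr > 0) matrix(pmax(colMeans(sweep(Xr, 2, colMeans(Xr))^2),
                                  1e-12), 1) else matrix(0, 1, 0)
    ll <- (if (pr > 0) sum(common_feature_loglik(Xr)) else 0) + ll_irr
    resp <- matrix(1, n, K)
    if (K > 1) resp <- cbind(1, matrix(0, n, K - 1))
    fit <- list(pi = rep(1 / K, K), mu = mu, sigma2 = s2,
                resp = resp, loglik = ll, converged = TRUE)
  } else {
    fit <- NULL
    col_var <- pmax(apply(Xr, 2, var), 1e-12)
    Xs <- sweep(sweep(Xr, 2, colMeans(Xr)), 2, sqrt(col_var), "/")
    if (!is.null(init)) {
      stopifnot(length(init) == n, all(init >= 1), all(init <= K))
      cand <- with_seed(derive_seed(seed, 0),
                        em_run(Xr, Xs, K, col_var, max_iter, tol,
                               hard = init))
      if (!is.null(cand)) {
        cand$loglik <- cand$loglik + ll_irr
        fit <- cand
      }
    }
    if (is.null(fit)) {
      for (s in seq_len(n_starts)) {
        cand <- with_seed(derive_seed(seed, s), {
          em_run(Xr, Xs, K, col_var, max_iter, tol)
        })
        if (is.null(cand)) next
        cand$loglik <- cand$loglik + ll_irr
        if (is.null(fit) || cand$loglik > fit$loglik) fit <- cand
      }
    }
    if (is.null(fit)) stop("all EM starts degenerated (variance collapse)")
  }
  n_params <- (K - 1) + 2 * K * pr + 2 * (p - pr)
  assignments <- max.col(fit$resp, ties.method = "first")
  model <- structure(list(
    K = K, relevance = relevance, pi = fit$pi, mu = fit$mu,
    sigma2 = fit$sigma2,
    mu0 = if (any(!relevance)) colMeans(X[, !relevance, drop = FALSE])
    else numeric(0),
    sigma2_0 = if (any(!relevance)) {
      apply(X[, !relevance, drop = FALSE], 2,
            function(x) mean((x - mean(x))^2))
    } else numeric(0),
    responsibilities = fit$resp, assignments = assignments,
    loglik = fit$loglik, n_params = n_params,
    bic = fit$loglik - n_params / 2 * log(n),
    micl = NA_real_, seed_used = seed, converged = fit$converged
  ), class = "cluster_model")
  model$micl <- micl_score(X, assignments, relevance, K)
  model
}

# one EM run; returns NULL if a component's variance collapses
em_run <- function(Xr, Xs, K, col_var, max_iter, tol, hard = NULL) {
  n <- nrow(Xr)
  pr <- ncol(Xr)
  if (is.null(hard)) {
    centers <- kmeanspp_centers(Xs, K)
    d2 <- vapply(centers, function(c) rowSums(sweep(Xs, 2, Xs[c, ])^2),
                 numeric(n))
    hard <- max.col(-d2, ties.method = "first")
  }
  R <- matrix(0, n, K)
  R[cbind(seq_len(n), hard)] <- 1
  ll_old <- -Inf
  converged <- FALSE
  floor_v <- 1e-10 * col_var
  pi_k <- NULL; mu <- NULL; s2 <- NULL
  for (it in seq_len(max_iter)) {
    Nk <- colSums(R)
    # re-seed emptied components from the least well-explained subject
    # whose own cluster can spare a member
    repeat {
      empty <- which(Nk < 1e-8)
      if (length(empty) == 0) break
      lab <- max.col(R, ties.method = "first")
      eligible <- which(Nk[lab] >= 2 - 1e-8)
      if (length(eligible) == 0) return(NULL)
      i0 <- eligible[which.min(apply(R[eligible, , drop = FALSE], 1, max))]
      R[i0, ] <- 0
      R[i0, empty[1]] <- 1
      Nk <- colSums(R)
    }
    pi_k <- Nk / n
    mu <- crossprod(R, Xr) / Nk
    s2 <- crossprod(R, Xr^2) / Nk - mu^2
    if (any(s2 < matrix(floor_v, K, pr, byrow = TRUE))) {
      if (it > 3) return(NULL)  # variance collapse: discard this start
      s2 <- pmax(s2, matrix(floor_v, K, pr, byrow = TRUE))
    }
    iv <- 1 / s2
    const <- -0.5 * (rowSums(log(2 * pi * s2)) + rowSums(mu^2 * iv))
    LL <- -0.5 * (Xr^2 %*% t(iv)) + Xr %*% t(mu * iv) +
      matrix(const, n, K, byrow = TRUE) +
      matrix(log(pmax(pi_k, 1e-300)), n, K, byrow = TRUE)
    lse <- log_rowsumexp(LL)
    ll <- sum(lse)
    R <- exp(LL - lse)
    if (is.finite(ll_old) && ll < ll_old - 1e-6 * (1 + abs(ll_old))) {
      # should not happen; guard against numerical regression
      break
    }
    if (is.finite(ll_old) && ll - ll_old < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(pi = pi_k, mu = mu, sigma2 = s2, resp = R, loglik = ll_old,
       converged = converged)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "<cluster_model> K=%d, %d/%d relevant features, loglik=%.2f BIC=%.2f MICL=%.2f\n",
    x$K, sum(x$relevance), length(x$relevance), x$loglik, x$bic, x$micl))
  invisible(x)
}

#' @rdname fit_gmm_diag
#' @param x a `cluster_model`.
#' @param ... unused.
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(K = x$K, n_relevant = sum(x$relevance),
                 n_features = length(x$relevance), loglik = x$loglik,
                 n_params = x$n_params, bic = x$bic, micl = x$micl,
                 converged = x$converged)
}

#' @rdname fit_gmm_diag
#' @export
tidy.cluster_model <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$K),
    pi = x$pi,
    size = tabulate(x$assignments, nbins = x$K)
  )
}
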