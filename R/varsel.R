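# ---- integrated complete-data likelihood (MICL) -----------------------------

# log marginal likelihood of one Gaussian data block under a conjugate
# Normal-inverse-Gamma prior, vectorized over features from sufficient
# statistics (n, sum, sum of squares per feature)
nig_log_marginal <- function(n, s1, s2, m0, k0, a0, b0) {
  if (n == 0) return(rep(0, length(s1)))
  xbar <- s1 / n
  ss <- pmax(s2 - n * xbar^2, 0)
  kn <- k0 + n
  an <- a0 + n / 2
  bn <- b0 + 0.5 * ss + k0 * n * (xbar - m0)^2 / (2 * kn)
  -n / 2 * log(2 * pi) + 0.5 * (log(k0) - log(kn)) +
    a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0)
}

micl_prior <- function(X, k0 = 1, a0 = 1) {
  list(m0 = colMeans(X),
       b0 = pmax(apply(X, 2, function(x) mean((x - mean(x))^2)), 1e-12),
       k0 = k0, a0 = a0)
}

# log Dirichlet-multinomial partition prior, symmetric Dirichlet(alpha)
partition_log_prior <- function(nk, alpha = 0.5) {
  K <- length(nk)
  n <- sum(nk)
  lgamma(K * alpha) - lgamma(n + K * alpha) +
    sum(lgamma(nk + alpha)) - K * lgamma(alpha)
}

#' Integrated complete-data likelihood of a hard partition
#'
#' Scores a hard clustering with per-feature relevance flags by the log
#' integrated complete-data likelihood: relevant features contribute the
#' product over clusters of Normal-inverse-Gamma marginal likelihoods of
#' their within-cluster data; irrelevant features contribute a single
#' whole-sample marginal; the label vector contributes a symmetric
#' Dirichlet(1/2)-multinomial term. Hyperparameters are unit-information
#' NIG centered at each feature's empirical mean and variance
#' (`k0 = 1`, `a0 = 1`, `b0` = empirical variance), exposed via `k0`, `a0`.
#'
#' @param X numeric matrix (subjects x features).
#' @param z integer cluster labels in `1..K`.
#' @param relevance logical per feature.
#' @param K number of clusters.
#' @param k0,a0 NIG hyperparameters.
#' @return scalar log MICL.
#' @export
micl_score <- function(X, z, relevance, K = max(z), k0 = 1, a0 = 1) {
  pr <- micl_prior(X, k0, a0)
  nk <- tabulate(z, nbins = K)
  total <- partition_log_prior(nk)
  if (any(relevance)) {
    Xr <- X[, relevance, drop = FALSE]
    for (k in seq_len(K)) {
      rows <- z == k
      if (!any(rows)) next
      Xk <- Xr[rows, , drop = FALSE]
      total <- total + sum(nig_log_marginal(
        nrow(Xk), colSums(Xk), colSums(Xk^2),
        pr$m0[relevance], pr$k0, pr$a0, pr$b0[relevance]))
    }
  }
  if (any(!relevance)) {
    Xi <- X[, !relevance, drop = FALSE]
    total <- total + sum(nig_log_marginal(
      nrow(Xi), colSums(Xi), colSums(Xi^2),
      pr$m0[!relevance], pr$k0, pr$a0, pr$b0[!relevance]))
  }
  total
}

# per-feature clustered-vs-common decision given a hard partition:
# clustered score uses within-cluster MLE Gaussians and a (2K/2) log n
# penalty per feature, common score a single Gaussian and (2/2) log n.
# Cluster variances are floored at a small fraction of the overall feature
# variance so singleton clusters cannot buy infinite likelihood.
bic_relevance_scores <- function(X, z, K) {
  n <- nrow(X)
  vall <- pmax(apply(X, 2, function(x) mean((x - mean(x))^2)), 1e-12)
  clustered <- rep(0, ncol(X))
  for (k in seq_len(K)) {
    rows <- z == k
    nk <- sum(rows)
    if (nk == 0) next
    Xk <- X[rows, , drop = FALSE]
    mu <- colMeans(Xk)
    v <- pmax(colMeans(sweep(Xk, 2, mu)^2), 1e-6 * vall)
    clustered <- clustered - 0.5 * nk * (log(2 * pi * v) + 1) -
      0.5 * (colSums(sweep(Xk, 2, mu)^2) / v - nk)
  }
  common <- common_feature_loglik(X)
  list(clustered = unname(clustered - K * log(n)),
       common = unname(common - log(n)))
}

# MICL per-feature scores given a hard partition (no explicit penalty; the
# integration handles complexity)
micl_relevance_scores <- function(X, z, K, k0 = 1, a0 = 1) {
  pr <- micl_prior(X, k0, a0)
  clustered <- rep(0, ncol(X))
  for (k in seq_len(K)) {
    rows <- z == k
    if (!any(rows)) next
    Xk <- X[rows, , drop = FALSE]
    clustered <- clustered + nig_log_marginal(
      nrow(Xk), colSums(Xk), colSums(Xk^2), pr$m0, pr$k0, pr$a0, pr$b0)
  }
  common <- nig_log_marginal(nrow(X), colSums(X), colSums(X^2),
                             pr$m0, pr$k0, pr$a0, pr$b0)
  list(clustered = unname(clustered), common = unname(common))
}

# iterated conditional modes on hard labels maximizing MICL for fixed
# relevance; incremental sufficient-statistic updates, deterministic sweep
# order, capped passes
micl_icm <- function(X, z, relevance, K, max_pass = 100, k0 = 1, a0 = 1) {
  n <- nrow(X)
  Xr <- X[, relevance, drop = FALSE]
  pr_all <- micl_prior(X, k0, a0)
  m0 <- pr_all$m0[relevance]
  b0 <- pr_all$b0[relevance]
  s1 <- matrix(0, K, ncol(Xr))
  s2 <- matrix(0, K, ncol(Xr))
  nk <- tabulate(z, nbins = K)
  for (k in seq_len(K)) {
    rows <- z == k
    if (any(rows)) {
      s1[k, ] <- colSums(Xr[rows, , drop = FALSE])
      s2[k, ] <- colSums(Xr[rows, , drop = FALSE]^2)
    }
  }
  block_lm <- function(k) nig_log_marginal(nk[k], s1[k, ], s2[k, ], m0,
                                           k0, a0, b0)
  lm_cache <- t(vapply(seq_len(K), function(k) sum(block_lm(k)),
                       numeric(1)))
  alpha <- 0.5
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      ci <- z[i]
      xi <- Xr[i, ]
      # score of each candidate label: partition term + affected blocks
      base_wo <- sum(nig_log_marginal(nk[ci] - 1, s1[ci, ] - xi,
                                      s2[ci, ] - xi^2, m0, k0, a0, b0))
      best_k <- ci
      best_delta <- 0
      for (k in seq_len(K)) {
        if (k == ci) next
        with_k <- sum(nig_log_marginal(nk[k] + 1, s1[k, ] + xi,
                                       s2[k, ] + xi^2, m0, k0, a0, b0))
        delta <- (base_wo - lm_cache[ci]) + (with_k - lm_cache[k]) +
          log(nk[k] + alpha) - log(nk[ci] - 1 + alpha)
        if (delta > best_delta + 1e-12) {
          best_delta <- delta
          best_k <- k
        }
      }
      if (best_k != ci) {
        nk[ci] <- nk[ci] - 1
        s1[ci, ] <- s1[ci, ] - xi
        s2[ci, ] <- s2[ci, ] - xi^2
        nk[best_k] <- nk[best_k] + 1
        s1[best_k, ] <- s1[best_k, ] + xi
        s2[best_k, ] <- s2[best_k, ] + xi^2
        z[i] <- best_k
        lm_cache[ci] <- sum(block_lm(ci))
        lm_cache[best_k] <- sum(block_lm(best_k))
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  z
}

#' Select the number of clusters and the relevant features
#'
#' Searches `K_range` (1 to 8 by default) for the sparse diagonal Gaussian
#' mixture maximizing BIC or MICL. For each K the procedure alternates (a)
#' an EM fit of the mixture given the current relevance flags
#' ([fit_gmm_diag()], best of `n_starts` initializations) and (b) a
#' per-feature relevance toggle choosing the clustered or the common model
#' by its criterion contribution given the current partition, iterating to
#' a fixed point. Under MICL the partition itself is further optimized by
#' iterated conditional updates of single-subject labels (hard assignment),
#' and relevance toggles use conjugate marginal likelihoods. The best
#' (K, relevance) pair under the requested criterion is returned; ties
#' break to the smaller K. Deterministic given `seed`.
#'
#' @inheritParams fit_gmm_diag
#' @param K_range integer vector of candidate cluster counts.
#' @param criterion `"BIC"` or `"MICL"`.
#' @param max_sweeps cap on relevance/partition alternations per K.
#' @return the selected `cluster_model`, with `criterion` and a `search`
#'   tibble (criterion value per K) attached.
#' @export
select_model <- function(features, K_range = 1:8,
                         criterion = c("BIC", "MICL"), seed = 1,
                         n_starts = 20, max_sweeps = 10) {
  criterion <- match.arg(criterion)
  X <- as_feature_X(features)
  n <- nrow(X)
  p <- ncol(X)
  best <- NULL
  best_val <- -Inf
  search <- list()
  for (K in K_range) {
    seed_k <- derive_seed(seed, 1000 + K)
    relevance <- rep(TRUE, p)
    model <- NULL
    warm <- NULL
    z <- NULL
    feasible <- TRUE
    for (sweep in seq_len(max_sweeps)) {
      model <- tryCatch(
        fit_gmm_diag(X, K, relevance, seed = seed_k,
                     n_starts = n_starts, init = warm),
        error = function(e) NULL)
      if (is.null(model)) {
        # every start degenerated: K unsupported by the data
        feasible <- FALSE
        break
      }
      z <- model$assignments
      if (criterion == "MICL" && K > 1) {
        z <- micl_icm(X, z, relevance, K)
      }
      if (K == 1) {
        new_rel <- rep(FALSE, p)
      } else {
        sc <- if (criterion == "BIC") bic_relevance_scores(X, z, K)
        else micl_relevance_scores(X, z, K)
        new_rel <- sc$clustered > sc$common
      }
      if (identical(new_rel, relevance)) break
      relevance <- new_rel
      warm <- z  # warm-start the refit from the current partition
    }
    if (!feasible) {
      search[[as.character(K)]] <- tibble::tibble(
        K = K, criterion = criterion, value = NA_real_,
        n_relevant = NA_integer_)
      next
    }
    if (criterion == "MICL" && K > 1) {
      model$assignments <- z
      model$micl <- micl_score(X, z, relevance, K)
    }
    val <- if (criterion == "BIC") model$bic else model$micl
    search[[as.character(K)]] <- tibble::tibble(
      K = K, criterion = criterion, value = val,
      n_relevant = sum(model$relevance))
    if (val > best_val + 1e-9) {  # strict improvement: ties keep smaller K
      best_val <- val
      best <- model
    }
  }
  best$criterion <- criterion
  best$search <- dplyr::bind_rows(search)
  best
}

#' @export
autoplot.cluster_model <- function(object, ...) {
  if (is.null(object$search)) {
    stop("autoplot needs a model returned by select_model()")
  }
  ggplot2::ggplot(object$search,
                  ggplot2::aes(x = .data$K, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$K, linetype = 2,
                        colour = "steelblue") +
    ggplot2::labs(y = unique(object$search$criterion),
                  x = "number of clusters K")
}
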