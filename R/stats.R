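#' One-way ANOVA of a feature on scanner model
#'
#' Regresses a single feature on the scanner factor and reports the model
#' R-squared and the F-test p-value. A constant feature returns `(0, 1)` by
#' convention.
#'
#' @param feature numeric vector.
#' @param scanner factor (or coercible) of scanner labels.
#' @return tibble with `r2` and `p_value`.
#' @export
scanner_anova <- function(feature, scanner) {
  scanner <- factor(scanner)
  ok <- is.finite(feature) & !is.na(scanner)
  feature <- feature[ok]
  scanner <- droplevels(scanner[ok])
  if (length(feature) < 3 || nlevels(scanner) < 2 ||
      isTRUE(all.equal(var(feature), 0)) || var(feature) == 0) {
    return(tibble::tibble(r2 = 0, p_value = 1))
  }
  fit <- lm(feature ~ scanner)
  s <- suppressWarnings(summary(fit))  # perfect fits are legitimate input
  fstat <- s$fstatistic
  p <- if (is.null(fstat)) 1 else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  tibble::tibble(r2 = unname(s$r.squared), p_value = p)
}

#' Intraclass correlation ICC(3,1): two-way mixed, single measure,
#' consistency
#'
#' Two-way ANOVA decomposition with subjects and the two variable versions
#' as factors; `ICC = (MS_subjects - MS_error) / (MS_subjects + (k - 1) *
#' MS_error)` with k = 2 raters. Consistency ICC ignores a fixed shift
#' between the versions: `icc31(x, x + 7) == 1`.
#'
#' @param x,y numeric vectors of equal length >= 3 (the matched variable
#'   computed two ways).
#' @return scalar ICC; `NA` (with a warning) if the subject variance is
#'   degenerate.
#' @export
icc31 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  k <- 2
  grand <- mean(c(x, y))
  subj_means <- (x + y) / 2
  rater_means <- c(mean(x), mean(y))
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_tot <- sum((c(x, y) - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_rater
  ms_subj <- ss_subj / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_subj + (k - 1) * ms_err
  if (denom <= 0) {
    warning("degenerate subject variance in ICC")
    return(NA_real_)
  }
  (ms_subj - ms_err) / denom
}

#' Spearman rank correlation (midranks for ties)
#'
#' @param x,y numeric vectors.
#' @return scalar rho; `NA` with a warning for constant input.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || var(x) == 0 || var(y) == 0) {
    warning("constant input: Spearman undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Bias-corrected Cramer's V (Bergsma)
#'
#' \eqn{\phi^2 = \chi^2/n}; \eqn{\tilde\phi^2 = \max(0, \phi^2 -
#' (r-1)(c-1)/(n-1))}; \eqn{\tilde r = r - (r-1)^2/(n-1)} (and analogously
#' \eqn{\tilde c}); \eqn{V = \sqrt{\tilde\phi^2 / \min(\tilde r - 1,
#' \tilde c - 1)}}. Rows/columns with zero margin are dropped first.
#'
#' @param table r x c contingency table of counts (matrix or table).
#' @return scalar in `[0, 1]`.
#' @examples
#' cramers_v_bc(matrix(c(10, 0, 0, 10), 2)) # 1
#' cramers_v_bc(matrix(c(5, 5, 5, 5), 2))   # 0
#' @export
cramers_v_bc <- function(table) {
  tab <- as.matrix(table)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  r <- nrow(tab)
  c <- ncol(tab)
  if (n < 2 || r < 2 || c < 2) return(0)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  phi2 <- chi2 / n
  phi2_bc <- max(0, phi2 - (r - 1) * (c - 1) / (n - 1))
  r_bc <- r - (r - 1)^2 / (n - 1)
  c_bc <- c - (c - 1)^2 / (n - 1)
  denom <- min(r_bc - 1, c_bc - 1)
  if (denom <= 0) return(0)
  sqrt(phi2_bc / denom)
}

#' Fisher exact test with simulated p-value
#'
#' Monte-Carlo p-value over random tables with the observed margins
#' (Patefield sampling via [stats::r2dtable()]); a replicate is as or more
#' extreme than the observed table when its fixed-margin hypergeometric
#' probability is less than or equal to the observed one (relative
#' tolerance 1e-7). `p = (1 + #extreme) / (n_rep + 1)`.
#'
#' @param table contingency table of nonnegative counts.
#' @param n_rep number of Monte-Carlo replicates (default 20000).
#' @param seed integer seed.
#' @return scalar p-value in (0, 1]; degenerate margins give 1.
#' @export
fisher_sim_p <- function(table, n_rep = 20000, seed = 1) {
  tab <- as.matrix(table)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  log_prob <- function(m) -sum(lgamma(m + 1))
  obs <- log_prob(tab)
  count <- with_seed(seed, {
    sims <- r2dtable(n_rep, rs, cs)
    lp <- vapply(sims, log_prob, numeric(1))
    sum(lp <= obs + abs(obs) * 1e-7)
  })
  (1 + count) / (n_rep + 1)
}

#' Linear model fit reporting R-squared and Gaussian log-likelihood
#'
#' @param outcome numeric response.
#' @param design data frame of covariates (may have zero columns for the
#'   null model); factors are expanded by the usual treatment contrasts.
#' @return list with `r2`, `loglik`, `df` (fitted parameters incl.
#'   intercept and error variance), `n`, and the `lm` fit. Rank-deficient
#'   designs fail naming the aliased columns.
#' @export
lm_fit <- function(outcome, design) {
  df <- as.data.frame(design)
  ok <- is.finite(outcome) & complete.cases(df)
  outcome <- outcome[ok]
  df <- df[ok, , drop = FALSE]
  fit <- if (ncol(df) == 0) lm(outcome ~ 1) else lm(outcome ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; aliased: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  r2 <- suppressWarnings(summary(fit))$r.squared
  list(r2 = unname(r2), loglik = as.numeric(logLik(fit)),
       df = attr(logLik(fit), "df"), n = length(outcome), fit = fit)
}

#' Likelihood-ratio test between nested linear models
#'
#' @param model_full,model_reduced results of [lm_fit()] on the same
#'   observations; the reduced design must nest in the full one.
#' @return p-value from the chi-square reference with df equal to the
#'   parameter difference; identical models give 1.
#' @export
lrt <- function(model_full, model_reduced) {
  if (model_full$n != model_reduced$n) {
    stop("models fitted on different observation sets")
  }
  df_diff <- model_full$df - model_reduced$df
  if (df_diff < 0) stop("models not nested: full has fewer parameters")
  stat <- 2 * (model_full$loglik - model_reduced$loglik)
  if (df_diff == 0) return(1)
  if (stat < -1e-6) stop("reduced model fits better: models not nested")
  pchisq(max(stat, 0), df = df_diff, lower.tail = FALSE)
}
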