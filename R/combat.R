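#' ComBat-style scanner harmonization of a feature matrix
#'
#' Parametric empirical-Bayes location/scale batch adjustment. Each feature
#' is modelled as grand mean + covariate effects + batch location effect,
#' with a batch scale effect on the residual; per-batch effects are shrunk
#' toward their across-feature means via a normal prior on locations and an
#' inverse-gamma prior on scales, with moment-matched hyperparameters and
#' fixed-point EB updates (tolerance 1e-6, at most 500 iterations). The
#' variability associated with the preserved covariates (Scadding stage as a
#' 5-level categorical, height, age, BMI, sex by default) is re-added after
#' adjustment.
#'
#' Subjects with a missing batch label or any missing covariate are dropped
#' from the harmonized output (they remain in the unharmonized input). With
#' a single batch the input is returned unchanged. A batch with fewer than
#' two subjects, or a singular covariate design, is an error.
#'
#' @param features a `feature_matrix` (or tibble with `subject_id` +
#'   numeric feature columns).
#' @param records tibble with `subject_id`, the batch column and the
#'   covariate columns, one row per subject.
#' @param batch_col name of the batch (scanner) column in `records`.
#' @param covariate_cols names of covariates whose variability is preserved;
#'   columns named in `factor_covariates` are encoded as categoricals.
#' @param factor_covariates subset of `covariate_cols` treated as factors.
#' @return harmonized `feature_matrix` with attribute
#'   `harmonization_model` (batch levels, `alpha_hat`, `beta_hat`,
#'   `gamma_star`, `delta_star`, `pooled_var`) and attribute
#'   `dropped_subjects`.
#' @export
combat_fit_apply <- function(features, records, batch_col = "scanner_id",
                             covariate_cols = c("scadding", "height", "age",
                                                "bmi", "sex"),
                             factor_covariates = "scadding") {
  feat_cols <- setdiff(names(features), "subject_id")
  df <- dplyr::left_join(features[, "subject_id", drop = FALSE],
                         records[, c("subject_id", batch_col,
                                     covariate_cols)],
                         by = "subject_id")
  complete <- complete.cases(df)
  dropped <- features$subject_id[!complete]
  keep <- which(complete)
  X <- as.matrix(features[keep, feat_cols])
  df <- df[keep, , drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  batch <- factor(df[[batch_col]])
  nb <- nlevels(batch)
  if (nb == 1) {
    out <- features[keep, , drop = FALSE]
    attr(out, "harmonization_model") <- NULL
    attr(out, "dropped_subjects") <- dropped
    return(mark_harmonized(out, features))
  }
  nbatch <- as.numeric(table(batch))
  if (any(nbatch < 2)) {
    stop("every batch needs >= 2 subjects; offending: ",
         paste(levels(batch)[nbatch < 2], collapse = ", "))
  }
  B <- model.matrix(~ batch - 1)
  cov_df <- df[, covariate_cols, drop = FALSE]
  for (fc in intersect(factor_covariates, covariate_cols)) {
    cov_df[[fc]] <- factor(cov_df[[fc]])
  }
  Cmat <- model.matrix(~ ., data = cov_df)[, -1, drop = FALSE]
  design <- cbind(B, Cmat)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("singular harmonization design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrd, X)                      # (nb + q) x p
  grand <- crossprod(nbatch / n, beta[seq_len(nb), , drop = FALSE])  # 1 x p
  resid_full <- X - design %*% beta
  pooled_var <- colMeans(resid_full^2)
  pooled_var[pooled_var <= 0] <- 1e-12
  stand_mean <- matrix(grand, n, p, byrow = TRUE) +
    Cmat %*% beta[-seq_len(nb), , drop = FALSE]
  Z <- (X - stand_mean) / matrix(sqrt(pooled_var), n, p, byrow = TRUE)
  gamma_hat <- matrix(0, nb, p)
  delta_hat <- matrix(0, nb, p)
  for (b in seq_len(nb)) {
    rows <- which(batch == levels(batch)[b])
    Zb <- Z[rows, , drop = FALSE]
    gamma_hat[b, ] <- colMeans(Zb)
    delta_hat[b, ] <- apply(Zb, 2, var)
  }
  delta_hat[delta_hat <= 0] <- 1e-12
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(nb)) {
    g_bar <- mean(gamma_hat[b, ])
    t2 <- var(gamma_hat[b, ])
    m <- mean(delta_hat[b, ])
    s2 <- var(delta_hat[b, ])
    if (p < 2 || !is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) {
      next  # too few features to moment-match priors: no shrinkage
    }
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    rows <- which(batch == levels(batch)[b])
    nb_i <- length(rows)
    Zb <- Z[rows, , drop = FALSE]
    g_old <- gamma_hat[b, ]
    d_old <- delta_hat[b, ]
    for (it in seq_len(500)) {
      g_new <- (t2 * nb_i * gamma_hat[b, ] + d_old * g_bar) /
        (t2 * nb_i + d_old)
      sum2 <- colSums((Zb - matrix(g_new, nb_i, p, byrow = TRUE))^2)
      d_new <- (0.5 * sum2 + b_prior) / (nb_i / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < 1e-6) break
    }
    gamma_star[b, ] <- g_old
    delta_star[b, ] <- d_old
  }
  Zadj <- Z
  for (b in seq_len(nb)) {
    rows <- which(batch == levels(batch)[b])
    Zadj[rows, ] <- (Z[rows, , drop = FALSE] -
                       matrix(gamma_star[b, ], length(rows), p,
                              byrow = TRUE)) /
      matrix(sqrt(delta_star[b, ]), length(rows), p, byrow = TRUE)
  }
  Xadj <- Zadj * matrix(sqrt(pooled_var), n, p, byrow = TRUE) + stand_mean
  out <- features[keep, , drop = FALSE]
  out[, feat_cols] <- tibble::as_tibble(as.data.frame(Xadj))
  model <- list(batch_levels = levels(batch),
                design_columns = colnames(design),
                alpha_hat = as.numeric(grand),
                beta_hat = beta[-seq_len(nb), , drop = FALSE],
                gamma_star = gamma_star, delta_star = delta_star,
                pooled_var = pooled_var)
  attr(out, "harmonization_model") <- model
  attr(out, "dropped_subjects") <- dropped
  mark_harmonized(out, features)
}

mark_harmonized <- function(out, features) {
  id <- attr(features, "dataset_id")
  if (!is.null(id)) {
    id <- dataset_id(id$data_type, id$drift, id$registered, TRUE)
    attr(out, "dataset_id") <- id
  }
  if (!inherits(out, "feature_matrix")) {
    class(out) <- c("feature_matrix", class(out))
  }
  out
}

#' Harmonize every dataset of a feature set
#'
#' Applies [combat_fit_apply()] to each of the 12 unharmonized datasets,
#' yielding the full 24-dataset design.
#'
#' @param fs a [engineer_features()] result.
#' @inheritParams combat_fit_apply
#' @return the `feature_set` with 12 harmonized datasets appended.
#' @export
harmonize_feature_set <- function(fs, batch_col = "scanner_id",
                                  covariate_cols = c("scadding", "height",
                                                     "age", "bmi", "sex"),
                                  factor_covariates = "scadding") {
  for (label in names(fs$datasets)) {
    fm <- fs$datasets[[label]]
    if (attr(fm, "dataset_id")$harmonized) next
    hm <- combat_fit_apply(fm, fs$records, batch_col, covariate_cols,
                           factor_covariates)
    fs$datasets[[attr(hm, "dataset_id")$label]] <- hm
  }
  fs
}
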