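# ---- full-design orchestration ----------------------------------------------

#' Match features across two engineered datasets
#'
#' Two variables from different datasets are matched when they were computed
#' for the same lung-decile and are either (a) both empirical variogram
#' values at the same binned distance or (b) both estimates of the same
#' model parameter. Empirical columns never match model columns; `psill`
#' and `range` match across the exponential and Matern families; `kappa`
#' matches only Matern-to-Matern.
#'
#' @param dataset_a,dataset_b `feature_matrix` objects.
#' @return tibble with columns `column_a`, `column_b`, `lung`, `decile`,
#'   `kind` (possibly zero rows).
#' @export
match_features <- function(dataset_a, dataset_b) {
  ia <- attr(dataset_a, "feature_info")
  ib <- attr(dataset_b, "feature_info")
  ta <- attr(dataset_a, "dataset_id")$data_type
  tb <- attr(dataset_b, "dataset_id")$data_type
  empty <- tibble::tibble(column_a = character(), column_b = character(),
                          lung = character(), decile = integer(),
                          kind = character())
  a_model <- ta %in% c("exponential", "matern")
  b_model <- tb %in% c("exponential", "matern")
  if (a_model != b_model) return(empty)
  m <- dplyr::inner_join(ia, ib, by = c("lung", "decile", "kind"),
                         suffix = c("_a", "_b"))
  tibble::tibble(column_a = m$column_a, column_b = m$column_b,
                 lung = m$lung, decile = m$decile, kind = m$kind)
}

# vectorized one-way ANOVA R^2 and F p-value of each column on a factor;
# agrees with scanner_anova() column by column
scanner_anova_matrix <- function(X, scanner) {
  scanner <- factor(scanner)
  n <- nrow(X)
  g <- nlevels(scanner)
  grand <- colMeans(X)
  sst <- colSums(sweep(X, 2, grand)^2)
  ssb <- rep(0, ncol(X))
  for (lev in levels(scanner)) {
    rows <- scanner == lev
    nb <- sum(rows)
    mb <- colMeans(X[rows, , drop = FALSE])
    ssb <- ssb + nb * (mb - grand)^2
  }
  r2 <- ifelse(sst > 0, ssb / sst, 0)
  fstat <- (ssb / (g - 1)) / pmax((sst - ssb) / (n - g), 1e-300)
  p <- ifelse(sst > 0, pf(fstat, g - 1, n - g, lower.tail = FALSE), 1)
  tibble::tibble(column = colnames(X), r2 = unname(r2),
                 p_value = unname(p))
}

# vectorized column-wise ICC(3,1) between two aligned matrices
icc31_matrix <- function(A, B) {
  n <- nrow(A)
  k <- 2
  grand <- (colMeans(A) + colMeans(B)) / 2
  sm <- (A + B) / 2
  ss_subj <- k * colSums(sweep(sm, 2, grand)^2)
  ss_rater <- n * ((colMeans(A) - grand)^2 + (colMeans(B) - grand)^2)
  ss_tot <- colSums(sweep(A, 2, grand)^2) + colSums(sweep(B, 2, grand)^2)
  ss_err <- ss_tot - ss_subj - ss_rater
  ms_subj <- ss_subj / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_subj + (k - 1) * ms_err
  unname(ifelse(denom > 0, (ms_subj - ms_err) / denom, NA_real_))
}

spearman_matrix <- function(A, B) {
  Ra <- apply(A, 2, rank)
  Rb <- apply(B, 2, rank)
  sa <- apply(Ra, 2, sd)
  sb <- apply(Rb, 2, sd)
  n <- nrow(A)
  cov <- colSums((Ra - matrix(colMeans(Ra), n, ncol(A), byrow = TRUE)) *
                   (Rb - matrix(colMeans(Rb), n, ncol(B), byrow = TRUE))) /
    (n - 1)
  unname(ifelse(sa > 0 & sb > 0, cov / (sa * sb), NA_real_))
}

#' Four-model outcome battery for one cluster analysis
#'
#' Fits the four models of the design — base (demographics), Scadding-only
#' (demographics + Scadding), cluster-only (demographics + cluster), full
#' (all three) — for one outcome, and reports model fit (R-squared for
#' continuous PFT outcomes via linear regression, training AUC for binary
#' VAS outcomes via Firth logistic regression) plus the three nested-model
#' tests full-vs-Scadding, cluster-vs-base, full-vs-cluster and the
#' cluster-free Scadding-vs-base contrast (likelihood-ratio tests for PFT,
#' penalized likelihood-ratio tests for VAS). Complete-case per outcome:
#' only subjects with complete demographics, Scadding, cluster label and
#' outcome enter.
#'
#' @param outcome numeric (PFT) or binary 0/1 (VAS) vector.
#' @param cluster cluster labels (factor or coercible).
#' @param covariates data frame with `sex`, `height`, `age`, `bmi`,
#'   `scadding`.
#' @param type `"pft"` or `"vas"`.
#' @return tibble with one row per model (`fit` = R2 or AUC) and the
#'   contrast p-values in attribute rows (`model` = contrast name,
#'   `p_value` set).
#' @export
outcome_battery <- function(outcome, cluster, covariates,
                            type = c("pft", "vas")) {
  type <- match.arg(type)
  df <- tibble::tibble(outcome = outcome,
                       cluster = factor(cluster),
                       sex = covariates$sex, height = covariates$height,
                       age = covariates$age, bmi = covariates$bmi,
                       scadding = factor(covariates$scadding))
  df <- df[complete.cases(df), ]
  df$cluster <- droplevels(df$cluster)
  df$scadding <- droplevels(df$scadding)
  demo <- c("sex", "height", "age", "bmi")
  # a single-level grouping contributes no parameters: drop the term so
  # the nested tests degenerate to identical-model comparisons (p = 1)
  cl_term <- if (nlevels(df$cluster) >= 2) "cluster" else character()
  sc_term <- if (nlevels(df$scadding) >= 2) "scadding" else character()
  designs <- list(
    base = df[, demo],
    scadding = df[, c(demo, sc_term)],
    cluster = df[, c(demo, cl_term)],
    full = df[, c(demo, cl_term, sc_term)]
  )
  if (type == "pft") {
    fits <- lapply(designs, function(d) lm_fit(df$outcome, d))
    fit_vals <- vapply(fits, function(f) f$r2, numeric(1))
    pv <- c(full_vs_scadding = lrt(fits$full, fits$scadding),
            cluster_vs_base = lrt(fits$cluster, fits$base),
            full_vs_cluster = lrt(fits$full, fits$cluster),
            scadding_vs_base = lrt(fits$scadding, fits$base))
  } else {
    fits <- lapply(designs, function(d) firth_logistic(df$outcome, d))
    fit_vals <- vapply(fits, function(f) f$auc, numeric(1))
    pv <- c(full_vs_scadding = plrt(fits$full, fits$scadding),
            cluster_vs_base = plrt(fits$cluster, fits$base),
            full_vs_cluster = plrt(fits$full, fits$cluster),
            scadding_vs_base = plrt(fits$scadding, fits$base))
  }
  dplyr::bind_rows(
    tibble::tibble(model = names(fit_vals), fit = unname(fit_vals),
                   p_value = NA_real_, n_used = nrow(df)),
    tibble::tibble(model = names(pv), fit = NA_real_,
                   p_value = unname(pv), n_used = nrow(df))
  )
}

#' Run the full texture-phenotyping design
#'
#' Generates (or accepts) a cohort, engineers the 24 feature datasets
#' (3 data types x 2 drift modes x 2 registration variants x 2
#' harmonization states), clusters each dataset under each criterion (48
#' analyses with the default two criteria), and computes the reporting
#' battery: per-dataset scanner-association distributions, matched-pair
#' robustness (ICC(3,1) and Spearman) across all dataset pairs sharing
#' feature definitions, the pairwise Cramer's V matrix of the 48 cluster
#' analyses, cluster-vs-covariate tests (bias-corrected Cramer's V +
#' simulated Fisher p for categoricals, F-tests for continuous), and the
#' four-model outcome battery for each PFT and VAS outcome. All seeds are
#' derived from `seed`; rerunning with the same configuration reproduces
#' every output byte-identically.
#'
#' @param config a [cohort_config()]; ignored if `cohort` is given.
#' @param cohort optionally a pre-generated [generate_cohort()] result.
#' @param out_dir if non-NULL, CSV/JSON outputs are written here.
#' @param cutoff,n_bins,min_voxels,kappa_grid variogram settings.
#' @param K_range,criteria,n_starts clustering settings.
#' @param fisher_n_rep Monte-Carlo replicates for simulated Fisher tests.
#' @param seed master seed for clustering and simulation-based tests.
#' @return object of class `variophen_report`; see Details.
#' @details The returned list has elements `manifest`, `datasets`
#'   (the `feature_set`), `scanner_assoc`, `robustness`, `analyses`
#'   (per-analysis cluster models and assignments), `cluster_consistency`,
#'   `cluster_covariates`, `outcomes`.
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         out_dir = NULL, cutoff = 25, n_bins = 15,
                         min_voxels = config$min_voxels,
                         kappa_grid = default_kappa_grid(),
                         K_range = 1:8, criteria = c("BIC", "MICL"),
                         n_starts = 20, fisher_n_rep = 20000,
                         seed = config$seed) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  fs <- engineer_features(cohort, cutoff = cutoff, n_bins = n_bins,
                          min_voxels = min_voxels, kappa_grid = kappa_grid)
  fs <- harmonize_feature_set(fs)
  enum <- enumerate_datasets()
  datasets <- fs$datasets[enum$label]
  records <- cohort$records

  # scanner association per dataset
  scanner_assoc <- purrr::imap_dfr(datasets, function(fm, label) {
    rec <- records[match(fm$subject_id, records$subject_id), ]
    res <- scanner_anova_matrix(as_feature_X(fm), rec$scanner_id)
    res$dataset <- label
    res
  })

  # matched-pair robustness across every dataset pair sharing features
  robustness <- robustness_battery(datasets)

  # 48 cluster analyses
  analyses <- list()
  ai <- 0
  for (label in enum$label) {
    for (crit in criteria) {
      ai <- ai + 1
      fm <- datasets[[label]]
      model <- select_model(fm, K_range = K_range, criterion = crit,
                            seed = derive_seed(seed, 5000 + ai),
                            n_starts = n_starts)
      analyses[[paste(label, crit, sep = ".")]] <- list(
        dataset = label, criterion = crit, model = model,
        assignments = tibble::tibble(subject_id = fm$subject_id,
                                     cluster = model$assignments))
    }
  }

  cluster_consistency <- consistency_matrix(analyses)
  cluster_covariates <- covariate_battery(analyses, records,
                                          fisher_n_rep, seed)
  outcomes <- outcome_report(analyses, records)

  manifest <- list(
    n_subjects = length(cohort$subjects),
    n_datasets = length(datasets),
    n_cluster_analyses = length(analyses),
    dataset_labels = names(datasets),
    analysis_labels = names(analyses),
    exclusions = fs$exclusions,
    n_retained = nrow(fs$records),
    settings = list(cutoff = cutoff, n_bins = n_bins,
                    min_voxels = min_voxels,
                    kappa_grid_length = length(kappa_grid),
                    K_range = range(K_range), criteria = criteria,
                    n_starts = n_starts, fisher_n_rep = fisher_n_rep,
                    seed = seed)
  )
  report <- structure(list(manifest = manifest, datasets = fs,
                           scanner_assoc = scanner_assoc,
                           robustness = robustness, analyses = analyses,
                           cluster_consistency = cluster_consistency,
                           cluster_covariates = cluster_covariates,
                           outcomes = outcomes, records = records),
                      class = "variophen_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

robustness_battery <- function(datasets) {
  labels <- names(datasets)
  out <- list()
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (j <= i) next
      a <- datasets[[i]]
      b <- datasets[[j]]
      pairs <- match_features(a, b)
      if (nrow(pairs) == 0) next
      common <- intersect(a$subject_id, b$subject_id)
      A <- as_feature_X(a[match(common, a$subject_id), ])
      B <- as_feature_X(b[match(common, b$subject_id), ])
      A <- A[, pairs$column_a, drop = FALSE]
      B <- B[, pairs$column_b, drop = FALSE]
      out[[paste(labels[i], labels[j], sep = "|")]] <- tibble::tibble(
        dataset_a = labels[i], dataset_b = labels[j],
        column_a = pairs$column_a, column_b = pairs$column_b,
        kind = pairs$kind,
        icc = icc31_matrix(A, B),
        spearman = spearman_matrix(A, B),
        n_used = length(common)
      )
    }
  }
  dplyr::bind_rows(out)
}

consistency_matrix <- function(analyses) {
  labels <- names(analyses)
  out <- list()
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (j <= i) next
      a <- analyses[[i]]$assignments
      b <- analyses[[j]]$assignments
      m <- dplyr::inner_join(a, b, by = "subject_id",
                             suffix = c("_a", "_b"))
      v <- cramers_v_bc(table(m$cluster_a, m$cluster_b))
      out[[length(out) + 1]] <- tibble::tibble(
        analysis_a = labels[i], analysis_b = labels[j], cramers_v = v,
        n_used = nrow(m))
    }
  }
  dplyr::bind_rows(out)
}

covariate_battery <- function(analyses, records, fisher_n_rep, seed) {
  cat_covs <- c("scanner_id", "sex", "scadding",
                grep("^vas_", names(records), value = TRUE))
  cont_covs <- c("age", "height", "bmi", "fev1", "fvc", "fev1_fvc", "dlco")
  out <- list()
  fi <- 0
  for (label in names(analyses)) {
    an <- analyses[[label]]
    rec <- dplyr::inner_join(an$assignments, records, by = "subject_id")
    for (cv in cat_covs) {
      fi <- fi + 1
      ok <- !is.na(rec[[cv]])
      tab <- table(rec$cluster[ok], rec[[cv]][ok])
      out[[length(out) + 1]] <- tibble::tibble(
        analysis = label, covariate = cv, kind = "cramers_v_bc",
        value = cramers_v_bc(tab),
        p_value = fisher_sim_p(tab, n_rep = fisher_n_rep,
                               seed = derive_seed(seed, 90000 + fi)),
        n_used = sum(ok))
    }
    for (cv in cont_covs) {
      ok <- !is.na(rec[[cv]])
      res <- scanner_anova(rec[[cv]][ok], rec$cluster[ok])
      out[[length(out) + 1]] <- tibble::tibble(
        analysis = label, covariate = cv, kind = "anova_r2",
        value = res$r2, p_value = res$p_value, n_used = sum(ok))
    }
  }
  dplyr::bind_rows(out)
}

outcome_report <- function(analyses, records) {
  pft_outcomes <- c("fev1", "fvc", "fev1_fvc", "dlco")
  vas_outcomes <- grep("^vas_", names(records), value = TRUE)
  covs <- records[, c("subject_id", "sex", "height", "age", "bmi",
                      "scadding")]
  out <- list()
  for (label in names(analyses)) {
    an <- analyses[[label]]
    rec <- dplyr::inner_join(an$assignments, records, by = "subject_id")
    for (oc in c(pft_outcomes, vas_outcomes)) {
      type <- if (oc %in% pft_outcomes) "pft" else "vas"
      bat <- tryCatch(
        outcome_battery(rec[[oc]], rec$cluster,
                        rec[, c("sex", "height", "age", "bmi", "scadding")],
                        type = type),
        error = function(e) tibble::tibble(model = "error", fit = NA_real_,
                                           p_value = NA_real_,
                                           n_used = NA_integer_))
      bat$analysis <- label
      bat$outcome <- oc
      out[[length(out) + 1]] <- bat
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.variophen_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<variophen_report> %d subjects (%d retained), ",
                     "%d datasets, %d cluster analyses\n"),
              m$n_subjects, m$n_retained, m$n_datasets,
              m$n_cluster_analyses))
  invisible(x)
}

#' Summary plots for a pipeline report
#'
#' `plot_scanner_assoc()` shows the per-dataset distribution of feature-on-
#' scanner R-squared values; `plot_outcome_fit()` shows model fit (R2/AUC)
#' for the four-model outcome battery across analyses.
#'
#' @param report a [run_pipeline()] result.
#' @return a ggplot object.
#' @export
plot_scanner_assoc <- function(report) {
  ggplot2::ggplot(report$scanner_assoc,
                  ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~ .data$dataset, scales = "free_y") +
    ggplot2::labs(x = expression(R^2 ~ "feature ~ scanner"), y = "features")
}

#' @rdname plot_scanner_assoc
#' @export
plot_outcome_fit <- function(report) {
  df <- report$outcomes[!is.na(report$outcomes$fit), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$fit,
                                   colour = .data$model)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(y = "model fit (R2 for PFT, training AUC for VAS)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
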