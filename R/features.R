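#' @keywords internal
new_feature_matrix <- function(values, dataset_id, feature_info, excluded,
                               scaling = NULL) {
  structure(values,
            dataset_id = dataset_id, feature_info = feature_info,
            excluded = excluded, scaling = scaling,
            class = c("feature_matrix", class(values)))
}

#' Dataset identifier helpers
#'
#' A dataset is identified by data type (`empirical`, `exponential`,
#' `matern`), drift handling (`raw`, `linear`), registration
#' (`registered`, `unregistered`) and harmonization (`harmonized`,
#' `unharmonized`). [enumerate_datasets()] lists all 24 combinations.
#'
#' @param data_type,drift,registered,harmonized components of the id.
#' @return `dataset_id()`: a named list with a `label` string;
#'   `enumerate_datasets()`: a tibble with one row per dataset.
#' @export
dataset_id <- function(data_type, drift, registered, harmonized) {
  label <- paste(data_type, drift,
                 if (registered) "registered" else "unregistered",
                 if (harmonized) "harmonized" else "unharmonized",
                 sep = "_")
  list(data_type = data_type, drift = drift, registered = registered,
       harmonized = harmonized, label = label)
}

#' @rdname dataset_id
#' @export
enumerate_datasets <- function() {
  g <- tidyr::expand_grid(
    data_type = c("empirical", "exponential", "matern"),
    drift = c("raw", "linear"),
    registered = c(TRUE, FALSE),
    harmonized = c(FALSE, TRUE)
  )
  g$label <- purrr::pmap_chr(g, function(data_type, drift, registered,
                                         harmonized) {
    dataset_id(data_type, drift, registered, harmonized)$label
  })
  g
}

# per-subject masks for the requested registration variant
subject_masks <- function(cohort, i, registered) {
  if (registered) {
    cohort$template_mask
  } else {
    list(left = cohort$subjects[[i]]$mask_left,
         right = cohort$subjects[[i]]$mask_right)
  }
}

# empirical variograms for the 18 lung-decile slices of one subject; a
# classed failure from any stage is carried as a subject-level reason
subject_lung_variograms <- function(hu, masks, voxel_size_mm, drift, cutoff,
                                    n_bins, min_voxels) {
  out <- list()
  res <- tryCatch({
    for (lung in c("left", "right")) {
      mask <- masks[[lung]]
      counts <- apply(mask, 1, sum)
      retained <- trim_slices(counts, min_voxels)
      deciles <- select_decile_slices(retained)
      for (d in seq_len(9)) {
        s <- deciles[d]
        m <- mask[s, , ]
        idx <- which(m, arr.ind = TRUE)
        vals <- hu[s, , ][m]
        coords <- cbind(x = idx[, 2] * voxel_size_mm,
                        y = idx[, 1] * voxel_size_mm)
        ev <- empirical_variogram(vals, coords, cutoff, n_bins, drift)
        if (nrow(ev) < n_bins) {
          insufficient_data(sprintf("%s decile %d: empty variogram bin",
                                    lung, d))
        }
        out[[paste0(lung, "_d", d)]] <- ev
      }
    }
    list(ok = TRUE, vgs = out)
  }, variophen_insufficient_data = function(e) {
    list(ok = FALSE, reason = conditionMessage(e))
  })
  res
}

# variograms for every subject of one (registered, drift) variant
variant_variograms <- function(cohort, registered, drift, cutoff, n_bins,
                               min_voxels) {
  lapply(seq_along(cohort$subjects), function(i) {
    subj <- cohort$subjects[[i]]
    subject_lung_variograms(subj$hu, subject_masks(cohort, i, registered),
                            cohort$config$voxel_size_mm, drift, cutoff,
                            n_bins, min_voxels)
  })
}

# exponential and Matern WLS fits for every lung-decile variogram
variant_fits <- function(vgs, kappa_grid) {
  lapply(vgs, function(sv) {
    if (!sv$ok) return(sv)
    fits <- lapply(sv$vgs, function(ev) {
      list(exp = fit_variogram_wls(ev, "exponential"),
           mat = fit_variogram_wls(ev, "matern", kappa_grid))
    })
    bad <- !vapply(fits, function(f) f$exp$valid && f$mat$valid, logical(1))
    if (any(bad)) {
      list(ok = FALSE,
           reason = paste0("invalid (nonpositive or failed) variogram model ",
                           "fit at ", paste(names(fits)[bad], collapse = ", ")))
    } else {
      list(ok = TRUE, fits = fits)
    }
  })
}

feature_slots <- function(data_type, n_bins = 15) {
  kinds <- switch(data_type,
                  empirical = sprintf("g%02d", seq_len(n_bins)),
                  exponential = c("psill", "range"),
                  matern = c("psill", "range", "kappa"))
  grid <- tidyr::expand_grid(lung = c("left", "right"), decile = 1:9,
                             kind = kinds)
  grid$column <- paste0(grid$lung, "_d", grid$decile, "_", grid$kind)
  grid$index <- ifelse(grepl("^g", grid$kind),
                       as.integer(sub("^g", "", grid$kind)), NA_integer_)
  grid
}

assemble_empirical <- function(vgs, subject_ids, n_bins) {
  info <- feature_slots("empirical", n_bins)
  rows <- lapply(seq_along(vgs), function(i) {
    sv <- vgs[[i]]
    if (!sv$ok) return(NULL)
    vals <- unlist(lapply(c("left", "right"), function(lung) {
      unlist(lapply(1:9, function(d) sv$vgs[[paste0(lung, "_d", d)]]$gamma_hat))
    }))
    tibble::tibble(subject_id = subject_ids[i],
                   !!!setNames(as.list(vals), info$column))
  })
  dplyr::bind_rows(rows)
}

assemble_model <- function(fits, subject_ids, data_type) {
  info <- feature_slots(data_type)
  slot <- if (data_type == "exponential") "exp" else "mat"
  rows <- lapply(seq_along(fits), function(i) {
    sf <- fits[[i]]
    if (!sf$ok) return(NULL)
    vals <- unlist(lapply(c("left", "right"), function(lung) {
      unlist(lapply(1:9, function(d) {
        f <- sf$fits[[paste0(lung, "_d", d)]][[slot]]
        if (data_type == "exponential") c(f$psill, f$range)
        else c(f$psill, f$range, f$kappa)
      }))
    }))
    tibble::tibble(subject_id = subject_ids[i],
                   !!!setNames(as.list(vals), info$column))
  })
  dplyr::bind_rows(rows)
}

# log-transform psill/range then z-score per column over the retained
# subjects; kappa kept raw. Scaling statistics are frozen in the attribute.
transform_model_features <- function(values, info) {
  scaling <- NULL
  for (cn in info$column[info$kind %in% c("psill", "range")]) {
    x <- log(values[[cn]])
    mu <- mean(x)
    s <- sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    values[[cn]] <- (x - mu) / s
    scaling <- dplyr::bind_rows(scaling,
                                tibble::tibble(column = cn, mean = mu, sd = s))
  }
  list(values = values, scaling = scaling)
}

#' Build one engineered feature dataset from a cohort
#'
#' Runs the per-subject feature engineering for a single dataset variant:
#' slice trimming, decile slice selection, per-slice empirical variograms
#' (raw or linear-residual), and — for the model data types — exponential or
#' Matern WLS fits. Empirical datasets carry the 15 binned semivariances per
#' lung-decile (p = 270); exponential datasets the log-transformed,
#' z-scored partial sill and range (p = 36); Matern datasets additionally
#' the untransformed kappa (p = 54).
#'
#' Subjects failing any stage for this dataset (insufficient slice data, an
#' empty variogram bin, or an invalid model fit) are excluded and listed
#' with reasons. [engineer_features()] additionally applies the
#' cross-dataset exclusion rule (a subject invalid anywhere is removed from
#' every dataset) and should be preferred when building the full design.
#'
#' @param cohort a [generate_cohort()] result (or compatible list).
#' @param data_type `"empirical"`, `"exponential"` or `"matern"`.
#' @param drift `"raw"` or `"linear"`.
#' @param registered use the template masks (`TRUE`) or native masks.
#' @param cutoff,n_bins variogram estimation settings (mm / count).
#' @param min_voxels slice trimming threshold; defaults to the cohort
#'   config's value.
#' @param kappa_grid Matern smoothness grid.
#' @return a `feature_matrix`: tibble (`subject_id` + feature columns) with
#'   attributes `dataset_id`, `feature_info`, `excluded`, `scaling`.
#' @export
build_feature_matrix <- function(cohort, data_type = c("empirical",
                                                       "exponential",
                                                       "matern"),
                                 drift = c("raw", "linear"),
                                 registered = FALSE,
                                 cutoff = 25, n_bins = 15,
                                 min_voxels = cohort$config$min_voxels %||%
                                   1000,
                                 kappa_grid = default_kappa_grid()) {
  data_type <- match.arg(data_type)
  drift <- match.arg(drift)
  ids <- vapply(cohort$subjects, function(s) s$subject_id, character(1))
  vgs <- variant_variograms(cohort, registered, drift, cutoff, n_bins,
                            min_voxels)
  if (data_type == "empirical") {
    values <- assemble_empirical(vgs, ids, n_bins)
    stat <- vgs
    scaling <- NULL
  } else {
    fits <- variant_fits(vgs, kappa_grid)
    raw <- assemble_model(fits, ids, data_type)
    tr <- transform_model_features(raw, feature_slots(data_type))
    values <- tr$values
    scaling <- tr$scaling
    stat <- fits
  }
  excluded <- exclusion_table(stat, ids)
  new_feature_matrix(values,
                     dataset_id(data_type, drift, registered, FALSE),
                     feature_slots(data_type, n_bins), excluded, scaling)
}

exclusion_table <- function(stat, ids) {
  bad <- !vapply(stat, function(s) isTRUE(s$ok), logical(1))
  tibble::tibble(subject_id = ids[bad],
                 reason = vapply(stat[bad], function(s) s$reason,
                                 character(1)))
}

#' Build all twelve unharmonized feature datasets
#'
#' Computes the empirical variograms once per (registration, drift) variant,
#' fits the exponential and Matern models once per lung-decile slice, and
#' assembles the 12 unharmonized datasets (3 data types x 2 drift modes x 2
#' registration variants). A subject that fails any stage in any dataset —
#' including a negative (invalid) model fit — is excluded from all datasets,
#' so every dataset covers exactly the same subjects; the log/z-score
#' transform of sill and range is computed on that shared retained cohort
#' and frozen.
#'
#' @inheritParams build_feature_matrix
#' @return object of class `feature_set`: list with `datasets` (named list
#'   of 12 `feature_matrix` objects keyed by their `label`), `exclusions`
#'   (tibble of subject_id/reason), and `records` (the cohort records of the
#'   retained subjects).
#' @export
engineer_features <- function(cohort, cutoff = 25, n_bins = 15,
                              min_voxels = cohort$config$min_voxels %||% 1000,
                              kappa_grid = default_kappa_grid()) {
  ids <- vapply(cohort$subjects, function(s) s$subject_id, character(1))
  variants <- tidyr::expand_grid(registered = c(TRUE, FALSE),
                                 drift = c("raw", "linear"))
  vg_sets <- purrr::pmap(variants, function(registered, drift) {
    variant_variograms(cohort, registered, drift, cutoff, n_bins, min_voxels)
  })
  fit_sets <- lapply(vg_sets, variant_fits, kappa_grid = kappa_grid)
  # cross-dataset exclusion: union of failures over every variant and stage
  excl <- dplyr::bind_rows(
    purrr::map2(c(vg_sets, fit_sets),
                rep(seq_len(nrow(variants)), 2),
                function(stat, vi) {
      tab <- exclusion_table(stat, ids)
      if (nrow(tab) > 0) {
        tab$reason <- paste0(tab$reason, " [",
                             ifelse(variants$registered[vi], "registered",
                                    "unregistered"),
                             ", ", variants$drift[vi], "]")
      }
      tab
    })
  )
  excl <- dplyr::distinct(excl, .data$subject_id, .keep_all = TRUE)
  keep <- !(ids %in% excl$subject_id)
  datasets <- list()
  for (vi in seq_len(nrow(variants))) {
    registered <- variants$registered[vi]
    drift <- variants$drift[vi]
    for (data_type in c("empirical", "exponential", "matern")) {
      if (data_type == "empirical") {
        values <- assemble_empirical(vg_sets[[vi]][keep], ids[keep], n_bins)
        scaling <- NULL
      } else {
        raw <- assemble_model(fit_sets[[vi]][keep], ids[keep], data_type)
        tr <- transform_model_features(raw, feature_slots(data_type))
        values <- tr$values
        scaling <- tr$scaling
      }
      id <- dataset_id(data_type, drift, registered, FALSE)
      datasets[[id$label]] <- new_feature_matrix(
        values, id, feature_slots(data_type, n_bins), excl, scaling)
    }
  }
  records <- cohort$records[cohort$records$subject_id %in% ids[keep], ]
  structure(list(datasets = datasets, exclusions = excl, records = records),
            class = "feature_set")
}

#' @export
print.feature_matrix <- function(x, ...) {
  id <- attr(x, "dataset_id")
  cat(sprintf("<feature_matrix> %s: %d subjects x %d features\n",
              id$label, nrow(x), ncol(x) - 1L))
  NextMethod()
}
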