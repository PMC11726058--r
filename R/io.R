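# ---- serialization ----------------------------------------------------------

#' Write / read a feature matrix as CSV with a JSON sidecar
#'
#' The CSV holds `subject_id` plus one column per feature; the sidecar
#' (same path with extension `.json`) records the dataset id, the feature
#' metadata (lung, decile, kind), exclusions with reasons, and any frozen
#' standardization statistics, so a written dataset round-trips.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @return `write_feature_matrix()` the path, invisibly;
#'   `read_feature_matrix()` the reconstructed `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  readr::write_csv(tibble::as_tibble(fm), path)
  side <- list(
    dataset_id = attr(fm, "dataset_id"),
    feature_info = attr(fm, "feature_info"),
    excluded = attr(fm, "excluded"),
    scaling = attr(fm, "scaling")
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  values <- readr::read_csv(path, show_col_types = FALSE,
                            progress = FALSE)
  attr(values, "spec") <- NULL
  attr(values, "problems") <- NULL
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  id <- side$dataset_id
  fi <- tibble::as_tibble(side$feature_info)
  fi$decile <- as.integer(fi$decile)
  # all-NA columns are dropped by the JSON round-trip; restore them
  fi$index <- if ("index" %in% names(fi)) as.integer(fi$index) else
    NA_integer_
  ex <- side$excluded
  ex <- if (is.null(ex) || length(ex) == 0) {
    tibble::tibble(subject_id = character(), reason = character())
  } else tibble::as_tibble(ex)
  new_feature_matrix(values,
                     dataset_id(id$data_type, id$drift, id$registered,
                                id$harmonized),
                     fi, ex,
                     if (!is.null(side$scaling) && length(side$scaling))
                       tibble::as_tibble(side$scaling) else NULL)
}

#' Write a synthetic cohort to NIfTI volumes and a metadata CSV
#'
#' One HU volume and two mask volumes per subject (native masks), the shared
#' template masks, and `records.csv` with the subject records. Requires the
#' RNifti package. [read_cohort_nifti()] reconstructs a cohort list usable
#' by [engineer_features()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- rep(cohort$config$voxel_size_mm, 3)
  wr <- function(arr, path) {
    img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
    RNifti::pixdim(img) <- vox
    RNifti::writeNifti(img, path)
  }
  for (s in cohort$subjects) {
    base <- file.path(dir, s$subject_id)
    wr(s$hu, paste0(base, "_hu.nii.gz"))
    wr(s$mask_left + 0, paste0(base, "_mask_left.nii.gz"))
    wr(s$mask_right + 0, paste0(base, "_mask_right.nii.gz"))
  }
  wr(cohort$template_mask$left + 0, file.path(dir, "template_mask_left.nii.gz"))
  wr(cohort$template_mask$right + 0,
     file.path(dir, "template_mask_right.nii.gz"))
  readr::write_csv(cohort$records, file.path(dir, "records.csv"))
  invisible(dir)
}

#' @rdname write_cohort_nifti
#' @param voxel_size_mm voxel size to record; defaults to the NIfTI header
#'   value.
#' @param min_voxels trimming threshold stored on the reconstructed config.
#' @export
read_cohort_nifti <- function(dir, voxel_size_mm = NULL, min_voxels = 1000) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI import")
  }
  records <- readr::read_csv(file.path(dir, "records.csv"),
                             show_col_types = FALSE, progress = FALSE)
  rd <- function(path) {
    img <- RNifti::readNifti(path)
    aperm(as.array(img), c(3, 2, 1))
  }
  if (is.null(voxel_size_mm)) {
    hdr <- RNifti::niftiHeader(RNifti::readNifti(
      file.path(dir, paste0(records$subject_id[1], "_hu.nii.gz"))))
    voxel_size_mm <- hdr$pixdim[2]
  }
  subjects <- lapply(seq_len(nrow(records)), function(i) {
    sid <- records$subject_id[i]
    base <- file.path(dir, sid)
    list(hu = rd(paste0(base, "_hu.nii.gz")),
         mask_left = rd(paste0(base, "_mask_left.nii.gz")) > 0.5,
         mask_right = rd(paste0(base, "_mask_right.nii.gz")) > 0.5,
         scanner_id = records$scanner_id[i], subject_id = sid)
  })
  template <- list(
    left = rd(file.path(dir, "template_mask_left.nii.gz")) > 0.5,
    right = rd(file.path(dir, "template_mask_right.nii.gz")) > 0.5
  )
  structure(list(
    config = list(voxel_size_mm = voxel_size_mm, min_voxels = min_voxels),
    subjects = subjects, template_mask = template, records = records
  ), class = "lung_cohort")
}

#' Write a pipeline report bundle to disk
#'
#' Writes the 24 feature datasets (CSV + JSON sidecars), the cluster
#' assignments, the result tables (scanner association, robustness, cluster
#' consistency, covariate tests, outcome battery) and a JSON manifest. All
#' output is deterministic: rerunning an identical pipeline reproduces the
#' files byte for byte.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feat_dir <- file.path(dir, "features")
  dir.create(feat_dir, showWarnings = FALSE)
  for (label in names(report$datasets$datasets)) {
    write_feature_matrix(report$datasets$datasets[[label]],
                         file.path(feat_dir, paste0(label, ".csv")))
  }
  assignments <- purrr::imap_dfr(report$analyses, function(an, label) {
    tibble::tibble(analysis = label, dataset = an$dataset,
                   criterion = an$criterion,
                   subject_id = an$assignments$subject_id,
                   cluster = an$assignments$cluster)
  })
  readr::write_csv(assignments, file.path(dir, "assignments.csv"))
  models <- purrr::imap_dfr(report$analyses, function(an, label) {
    g <- glance(an$model)
    g$analysis <- label
    g
  })
  readr::write_csv(models, file.path(dir, "cluster_models.csv"))
  readr::write_csv(report$scanner_assoc, file.path(dir, "scanner_assoc.csv"))
  readr::write_csv(report$robustness, file.path(dir, "robustness.csv"))
  readr::write_csv(report$cluster_consistency,
                   file.path(dir, "cluster_consistency.csv"))
  readr::write_csv(report$cluster_covariates,
                   file.path(dir, "cluster_covariates.csv"))
  readr::write_csv(report$outcomes, file.path(dir, "outcomes.csv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
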