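#' Configuration of a synthetic lung CT cohort
#'
#' Bundles every knob of the synthetic-cohort generator: cohort size, image
#' grid, number and Matern texture parameters of the planted phenotype
#' clusters, scanner batch effects (additive HU shift and multiplicative
#' scale per scanner), planar drift, voxel noise, the outcome models linking
#' lung function (PFT) and visual scores (VAS) to cluster membership and
#' demographics, and the master seed. A config fully determines a cohort.
#'
#' The defaults describe the desk-scale study conditions used throughout the
#' package: 60 subjects, 30 axial slices of 48 x 48 voxels at 1 mm, 3 planted
#' clusters differing only in Matern parameters, 4 scanner models, mild
#' planar drift, and a slice-trimming threshold of 300 within-mask voxels:
#' the clinical-scale threshold of 1000 scaled to the smaller synthetic
#' slices, chosen so that every retained slice also spans the 25 mm
#' variogram cutoff.
#'
#' @param n_subjects number of subjects.
#' @param n_clusters_true number of planted phenotype clusters (>= 1).
#' @param grid_shape integer `(slices, rows, cols)`.
#' @param voxel_size_mm isotropic voxel edge length (mm).
#' @param scanner_levels number of scanner models.
#' @param scanner_effect list with numeric `shift` (additive HU per scanner)
#'   and `scale` (multiplicative, unitless >= 0), each of length
#'   `scanner_levels`.
#' @param cluster_texture_params tibble with columns `cluster`, `psill`
#'   (HU^2), `range` (mm), `kappa`; one row per cluster.
#' @param drift_slope numeric length 2: HU per mm along x and y.
#' @param noise_sd independent voxel noise SD (HU).
#' @param lung_mean_hu mean parenchymal HU level.
#' @param min_voxels slice-trimming threshold used downstream.
#' @param outcome_model coefficient lists for the PFT and VAS outcome
#'   models; see [default_outcome_model()].
#' @param p_missing probability that Scadding stage, a PFT value, or a VAS
#'   label is missing for a subject (exercises complete-case handling).
#' @param seed master integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60,
                          n_clusters_true = 3,
                          grid_shape = c(30, 48, 48),
                          voxel_size_mm = 1,
                          scanner_levels = 4,
                          scanner_effect = list(
                            shift = c(0, 15, -10, 25),
                            scale = c(1, 1.05, 0.95, 1.1)
                          ),
                          cluster_texture_params =
                            default_cluster_textures(n_clusters_true),
                          drift_slope = c(0.5, -0.5),
                          noise_sd = 5,
                          lung_mean_hu = -800,
                          min_voxels = 300,
                          outcome_model =
                            default_outcome_model(n_clusters_true),
                          p_missing = 0.03,
                          seed = 1) {
  stopifnot(n_clusters_true >= 1, length(grid_shape) == 3,
            all(grid_shape >= 4), scanner_levels >= 1, n_subjects >= 1,
            voxel_size_mm > 0, noise_sd >= 0, p_missing >= 0, p_missing < 1)
  stopifnot(length(scanner_effect$shift) == scanner_levels,
            length(scanner_effect$scale) == scanner_levels,
            all(scanner_effect$scale >= 0))
  ctp <- tibble::as_tibble(cluster_texture_params)
  stopifnot(nrow(ctp) == n_clusters_true,
            all(ctp$psill > 0), all(ctp$range > 0),
            all(ctp$kappa > 0), all(ctp$kappa <= 5))
  structure(list(
    n_subjects = n_subjects, n_clusters_true = n_clusters_true,
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    scanner_levels = scanner_levels, scanner_effect = scanner_effect,
    cluster_texture_params = ctp, drift_slope = drift_slope,
    noise_sd = noise_sd, lung_mean_hu = lung_mean_hu,
    min_voxels = min_voxels, outcome_model = outcome_model,
    p_missing = p_missing, seed = seed
  ), class = "cohort_config")
}

#' Default per-cluster Matern texture parameters
#'
#' Clusters differ in all three Matern parameters so that empirical, sill,
#' range and smoothness features all carry cluster signal: increasing partial
#' sill (texture variance), correlation range and smoothness from cluster 1
#' upward.
#'
#' @param k number of clusters.
#' @return tibble with columns `cluster`, `psill`, `range`, `kappa`.
#' @export
default_cluster_textures <- function(k) {
  base <- tibble::tibble(
    psill = c(400, 900, 1600, 650, 1200, 2000, 500, 1000),
    range = c(3, 6, 10, 4.5, 8, 12, 5, 7),
    kappa = c(0.5, 1.0, 1.5, 0.8, 1.2, 2.0, 0.6, 1.4)
  )
  idx <- rep_len(seq_len(nrow(base)), k)
  tibble::tibble(cluster = seq_len(k), base[idx, ])
}

#' Default outcome coefficient models
#'
#' Linear models for the four PFT measures (L, %, ml/min/mmHg) and logistic
#' models for the nine binary VAS abnormality labels, each a function of
#' planted cluster (effects per cluster), centered age (years, center 53),
#' sex (0/1), centered height (inches, center 67) and centered BMI (kg/m^2,
#' center 30). Default cluster effects on FEV1 are about two residual SDs
#' between extreme clusters, a strong planted phenotype signal.
#'
#' @param k number of clusters.
#' @return list with elements `pft` and `vas`.
#' @export
default_outcome_model <- function(k) {
  step <- function(by) seq(0, by = by, length.out = k)
  pft <- list(
    fev1 = list(intercept = 3.6, cluster = step(-0.5), age = -0.02,
                sex = 0.5, height = 0.03, bmi = -0.01, sd = 0.45),
    fvc = list(intercept = 4.4, cluster = step(-0.55), age = -0.02,
               sex = 0.6, height = 0.04, bmi = -0.015, sd = 0.5),
    fev1_fvc = list(intercept = 80, cluster = step(-4.5), age = -0.15,
                    sex = -1, height = 0, bmi = 0.1, sd = 5),
    dlco = list(intercept = 24, cluster = step(-3), age = -0.08,
                sex = 3, height = 0.2, bmi = 0.05, sd = 4)
  )
  vas_labels <- vas_label_names()
  intercepts <- c(-0.8, -0.5, -1.2, -1.8, -1.0, -1.4, -1.6, -1.1, -1.3)
  slopes <- c(0.6, 1.0, 1.1, 1.5, 1.2, 1.6, 0.9, 1.5, 1.5)
  vas <- purrr::map2(intercepts, slopes, function(b0, b1) {
    list(intercept = b0, cluster = seq(0, by = b1, length.out = k),
         age = 0.02, sex = 0.2, height = 0, bmi = 0.02)
  })
  names(vas) <- vas_labels
  list(pft = pft, vas = vas)
}

#' Names of the binary visual-assessment (VAS) labels
#' @return character vector of length 9.
#' @export
vas_label_names <- function() {
  c("lymphadenopathy", "micronodules", "ground_glass", "conglomerate_mass",
    "reticular", "fibrotic", "mosaic_attenuation",
    "architectural_distortion", "traction_bronchiectasis")
}

# elliptical two-lung masks for one slice; area ~ scale via sqrt on both
# axes. Axes are large relative to the 25 mm variogram cutoff so every
# slice that survives the trimming threshold spans the full lag range.
lung_slice_masks <- function(rows, cols, area_scale, jitter = NULL) {
  ax <- 0.19 * cols
  ay <- 0.46 * rows
  cy <- rows / 2
  cxl <- 0.28 * cols
  cxr <- 0.72 * cols
  fx <- 1; fy <- 1; dcy <- 0; dcxl <- 0; dcxr <- 0
  if (!is.null(jitter)) {
    fx <- jitter$fx; fy <- jitter$fy
    dcy <- jitter$dcy; dcxl <- jitter$dcxl; dcxr <- jitter$dcxr
  }
  s <- sqrt(area_scale)
  axs <- ax * s * fx
  ays <- ay * s * fy
  Y <- matrix(seq_len(rows), rows, cols)
  X <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  left <- ((X - (cxl + dcxl)) / axs)^2 + ((Y - (cy + dcy)) / ays)^2 <= 1
  right <- ((X - (cxr + dcxr)) / axs)^2 + ((Y - (cy + dcy)) / ays)^2 <= 1
  # masks must be disjoint; in the rare jittered overlap, left wins
  right[left] <- FALSE
  list(left = left, right = right)
}

# smooth cranio-caudal area profile, tapering below the trimming threshold
# at both ends
slice_area_profile <- function(n_slices) {
  s <- seq_len(n_slices)
  sin(pi * (s - 0.5) / n_slices)^1.5
}

build_lung_masks <- function(n_slices, rows, cols, jitter = NULL) {
  prof <- slice_area_profile(n_slices)
  left <- array(FALSE, c(n_slices, rows, cols))
  right <- array(FALSE, c(n_slices, rows, cols))
  for (s in seq_len(n_slices)) {
    m <- lung_slice_masks(rows, cols, prof[s], jitter)
    left[s, , ] <- m$left
    right[s, , ] <- m$right
  }
  list(left = left, right = right)
}

#' Construct and validate a masked lung image
#'
#' @param hu 3D numeric array (slices, rows, cols) of HU values.
#' @param mask_left,mask_right 3D logical arrays, same shape as `hu`,
#'   disjoint.
#' @param voxel_size_mm voxel edge length (mm).
#' @param scanner_id scanner label.
#' @param subject_id subject identifier.
#' @param registered whether the masks are the shared template variant.
#' @return object of class `masked_lung_image`.
#' @export
masked_lung_image <- function(hu, mask_left, mask_right, voxel_size_mm = 1,
                              scanner_id = "scanner1",
                              subject_id = "S001", registered = FALSE) {
  stopifnot(identical(dim(hu), dim(mask_left)),
            identical(dim(hu), dim(mask_right)),
            length(dim(hu)) == 3)
  if (any(mask_left & mask_right)) stop("lung masks must be disjoint")
  if (!all(is.finite(hu[mask_left | mask_right]))) {
    stop("hu must be finite within the masks")
  }
  structure(list(hu = hu, mask_left = mask_left, mask_right = mask_right,
                 voxel_size_mm = voxel_size_mm, scanner_id = scanner_id,
                 subject_id = subject_id, registered = registered),
            class = "masked_lung_image")
}

#' Generate one synthetic subject
#'
#' Draws a 3D masked lung image whose within-mask texture follows the
#' subject's cluster-specific Matern covariance on every axial slice (plus
#' drift and voxel noise), applies the scanner's location/scale effect to the
#' HU values, and samples the subject's demographic covariates and Scadding
#' stage. The `registered` variant uses the shared elliptical template mask;
#' the native variant perturbs the ellipse centers and axes
#' subject-specifically, so per-slice voxel counts (and hence trimming and
#' decile selection) differ across subjects.
#'
#' @param config a [cohort_config()].
#' @param cluster_id planted cluster (1-based, `<= n_clusters_true`).
#' @param scanner_id scanner index (1-based).
#' @param seed integer seed for this subject.
#' @param subject_id identifier string; also salts the mask perturbation, so
#'   two subjects sharing `seed` differ only by mask.
#' @param registered use the shared template mask instead of the perturbed
#'   native mask.
#' @param chol_factor optional precomputed [grf_cholesky_factor()] for this
#'   cluster's slice covariance.
#' @return list with elements `image` ([masked_lung_image]) and `record`
#'   (one-row tibble of covariates; outcomes filled by
#'   [generate_outcomes()]).
#' @export
generate_subject <- function(config, cluster_id, scanner_id, seed,
                             subject_id = "S001", registered = FALSE,
                             chol_factor = NULL) {
  stopifnot(cluster_id >= 1, cluster_id <= config$n_clusters_true,
            scanner_id >= 1, scanner_id <= config$scanner_levels)
  dims <- config$grid_shape
  n_slices <- dims[1]; rows <- dims[2]; cols <- dims[3]
  tex <- config$cluster_texture_params[cluster_id, ]
  matern <- c(psill = tex$psill, range = tex$range, kappa = tex$kappa)
  if (is.null(chol_factor) && rows * cols <= 128^2) {
    chol_factor <- grf_cholesky_factor(matern, c(rows, cols),
                                       config$voxel_size_mm)
  }
  shift <- config$scanner_effect$shift[scanner_id]
  scale <- config$scanner_effect$scale[scanner_id]
  hu <- array(0, dims)
  for (s in seq_len(n_slices)) {
    fld <- simulate_grf_slice(matern, c(rows, cols),
                              drift_slope = config$drift_slope,
                              noise_sd = config$noise_sd,
                              seed = derive_seed(seed, s),
                              voxel_size_mm = config$voxel_size_mm,
                              chol_factor = chol_factor)
    hu[s, , ] <- scale * (config$lung_mean_hu + fld) + shift
  }
  jitter <- NULL
  if (!registered) {
    salt <- sum(utf8ToInt(as.character(subject_id)))
    jitter <- with_seed(derive_seed(seed, 100003 + salt), list(
      fx = runif(1, 0.92, 1.08), fy = runif(1, 0.92, 1.08),
      dcy = runif(1, -1.5, 1.5), dcxl = runif(1, -1.5, 1.5),
      dcxr = runif(1, -1.5, 1.5)
    ))
  }
  masks <- build_lung_masks(n_slices, rows, cols, jitter)
  image <- masked_lung_image(hu, masks$left, masks$right,
                             config$voxel_size_mm,
                             scanner_id = paste0("scanner", scanner_id),
                             subject_id = subject_id,
                             registered = registered)
  record <- with_seed(derive_seed(seed, 424243), {
    scad_probs <- scadding_probs(config$n_clusters_true)[cluster_id, ]
    tibble::tibble(
      subject_id = subject_id,
      cluster_true = cluster_id,
      scanner_id = paste0("scanner", scanner_id),
      age = rnorm(1, 53, 10),
      sex = rbinom(1, 1, 0.46),
      height = rnorm(1, 67, 4),
      bmi = rnorm(1, 30.5, 6),
      scadding = if (runif(1) < config$p_missing) NA_integer_ else
        sample(0:4, 1, prob = scad_probs)
    )
  })
  list(image = image, record = record)
}

# Scadding stage distribution per cluster: later clusters skew to higher
# stages, giving harmonization a real covariate signal to preserve
scadding_probs <- function(k) {
  t(vapply(seq_len(k), function(c) {
    w <- (c - 1) / max(k - 1, 1)
    p0 <- c(0.35, 0.30, 0.20, 0.10, 0.05)
    p1 <- c(0.05, 0.10, 0.25, 0.25, 0.35)
    (1 - w) * p0 + w * p1
  }, numeric(5)))
}

#' Fill PFT and VAS outcomes for a cohort's subject records
#'
#' PFT values are linear in cluster indicators and centered demographics with
#' Gaussian noise; each VAS label is Bernoulli with a logit linear in the
#' same terms. Coefficients come from `config$outcome_model`. A small
#' fraction of values (`config$p_missing`) is set missing per assessment to
#' exercise complete-case analyses downstream.
#'
#' @param records tibble of subject records with `cluster_true` and
#'   demographics.
#' @param config the [cohort_config()].
#' @param seed integer seed.
#' @return `records` with `fev1`, `fvc`, `fev1_fvc`, `dlco` and the nine
#'   `vas_*` columns appended.
#' @export
generate_outcomes <- function(records, config, seed) {
  om <- config$outcome_model
  n <- nrow(records)
  age_c <- records$age - 53
  hgt_c <- records$height - 67
  bmi_c <- records$bmi - 30
  k <- records$cluster_true
  with_seed(seed, {
    for (nm in names(om$pft)) {
      m <- om$pft[[nm]]
      mu <- m$intercept + m$cluster[k] + m$age * age_c + m$sex * records$sex +
        m$height * hgt_c + m$bmi * bmi_c
      val <- mu + rnorm(n, sd = m$sd)
      val[runif(n) < config$p_missing] <- NA_real_
      records[[nm]] <- val
    }
    for (nm in names(om$vas)) {
      m <- om$vas[[nm]]
      eta <- m$intercept + m$cluster[k] + m$age * age_c + m$sex * records$sex +
        m$height * hgt_c + m$bmi * bmi_c
      lab <- rbinom(n, 1, plogis(eta))
      lab[runif(n) < config$p_missing] <- NA_integer_
      records[[paste0("vas_", nm)]] <- lab
    }
    records
  })
}

#' Generate a full synthetic cohort
#'
#' Assigns planted clusters and scanners (balanced, shuffled), draws each
#' subject's image and covariates with [generate_subject()], and fills
#' outcomes with [generate_outcomes()]. Identical config implies a
#' bit-identical cohort. Per-cluster slice-covariance Cholesky factors are
#' computed once and shared across subjects.
#'
#' @param config a [cohort_config()].
#' @return object of class `lung_cohort`: list with `config`, `subjects`
#'   (per-subject list of `hu`, native `mask_left`/`mask_right`,
#'   `scanner_id`, `subject_id`), `template_mask` (shared `left`/`right`
#'   arrays), and `records` (tibble).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  assign_seed <- derive_seed(config$seed, 1)
  clusters <- with_seed(assign_seed,
                        sample(rep_len(seq_len(config$n_clusters_true), n)))
  scanners <- with_seed(derive_seed(config$seed, 2),
                        sample(rep_len(seq_len(config$scanner_levels), n)))
  dims <- config$grid_shape
  factors <- lapply(seq_len(config$n_clusters_true), function(c) {
    tex <- config$cluster_texture_params[c, ]
    if (dims[2] * dims[3] <= 128^2) {
      grf_cholesky_factor(c(psill = tex$psill, range = tex$range,
                            kappa = tex$kappa),
                          dims[2:3], config$voxel_size_mm)
    } else NULL
  })
  subjects <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    gs <- generate_subject(config, clusters[i], scanners[i],
                           seed = derive_seed(config$seed, 100 + i),
                           subject_id = sid, registered = FALSE,
                           chol_factor = factors[[clusters[i]]])
    subjects[[i]] <- gs$image
    records[[i]] <- gs$record
  }
  records <- dplyr::bind_rows(records)
  records <- generate_outcomes(records, config,
                               seed = derive_seed(config$seed, 3))
  template <- build_lung_masks(dims[1], dims[2], dims[3], jitter = NULL)
  structure(list(config = config, subjects = subjects,
                 template_mask = template, records = records),
            class = "lung_cohort")
}

#' @export
print.lung_cohort <- function(x, ...) {
  cat(sprintf("<lung_cohort> %d subjects, grid %s, %d clusters, %d scanners\n",
              length(x$subjects),
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_clusters_true, x$config$scanner_levels))
  invisible(x)
}
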