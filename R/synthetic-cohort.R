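# Seeded synthetic multimodal cohorts: ellipsoidal tumor phantoms, a
# seven-feature clinical table with dataset-like imbalance and missingness,
# and a Bernoulli label model with a planted imaging x clinical interaction
# (on HER2 status) so that the two modalities carry genuinely complementary
# signal.

#' Specify a tumor phantom volume
#'
#' Describes a single-channel 3D intensity volume containing one ellipsoidal
#' "tumor" at elevated mean intensity over a Gaussian-noise background.
#' Phantoms stand in for DCE-MRI inputs at desk scale; they make no attempt
#' to mimic contrast kinetics or scanner artifacts.
#'
#' @param shape integer length-3, volume dimensions (H, W, D); each >= 8.
#' @param tumor_center fractional coordinates of the tumor center in
#'   `[0, 1]^3` (relative to each axis length).
#' @param tumor_radii per-axis ellipsoid radii in voxels (>= 0; all zero
#'   gives a tumor-free volume).
#' @param tumor_contrast intensity offset added inside the tumor.
#' @param heterogeneity within-tumor intensity standard deviation.
#' @param noise_sd background Gaussian noise standard deviation (>= 0).
#' @param seed integer RNG seed; identical specs produce bit-identical
#'   volumes.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 16L),
                         tumor_center = c(0.5, 0.5, 0.5),
                         tumor_radii = c(6, 6, 4),
                         tumor_contrast = 2,
                         heterogeneity = 0.5,
                         noise_sd = 1,
                         seed = 1L) {
  stop_if_not(length(shape) == 3L && all(shape >= 8), "shape components must be >= 8")
  stop_if_not(all(tumor_radii >= 0), "tumor radii must be >= 0")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(all(tumor_center >= 0 & tumor_center <= 1),
              "tumor_center must lie in [0,1]^3")
  structure(list(shape = as.integer(shape), tumor_center = tumor_center,
                 tumor_radii = tumor_radii, tumor_contrast = tumor_contrast,
                 heterogeneity = heterogeneity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a tumor phantom volume
#'
#' Renders the ellipsoid described by a [phantom_spec()]: background voxels
#' are `N(0, noise_sd^2)`, tumor voxels additionally receive the contrast
#' offset plus per-voxel heterogeneity noise.  A tumor whose bounding box
#' extends beyond the volume is rejected.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (3D array) and `mask` (binary 3D array
#'   marking tumor voxels).
#' @export
generate_phantom_volume <- function(spec) {
  stop_if_not(inherits(spec, "phantom_spec"), "`spec` must be a phantom_spec")
  shp <- spec$shape
  ctr <- spec$tumor_center * (shp - 1) + 1      # voxel coordinates, 1-based
  r <- spec$tumor_radii
  if (any(r > 0)) {
    lo <- ctr - r
    hi <- ctr + r
    if (any(lo < 1) || any(hi > shp)) {
      stop("tumor extends beyond volume bounds: center ",
           paste(round(ctr, 1), collapse = ","), " radii ",
           paste(r, collapse = ","), " in shape ",
           paste(shp, collapse = "x"), call. = FALSE)
    }
  }
  mask <- array(FALSE, dim = shp)
  if (all(r > 0)) {
    ix <- ((seq_len(shp[1]) - ctr[1]) / r[1])^2
    iy <- ((seq_len(shp[2]) - ctr[2]) / r[2])^2
    iz <- ((seq_len(shp[3]) - ctr[3]) / r[3])^2
    mask <- outer(outer(ix, iy, `+`), iz, `+`) <= 1
  }
  vol <- with_seed(spec$seed, {
    v <- array(rnorm(prod(shp), sd = spec$noise_sd), dim = shp)
    n_in <- sum(mask)
    if (n_in > 0) {
      v[mask] <- v[mask] + spec$tumor_contrast +
        rnorm(n_in, sd = spec$heterogeneity)
    }
    v
  })
  list(volume = vol, mask = mask * 1L)
}

#' Specify a synthetic cohort
#'
#' Cohort-level knobs: size, target pCR prevalence (defaults emulate the
#' roughly 29% prevalence typical of neoadjuvant-chemotherapy cohorts),
#' label-model coefficients including the planted imaging x HER2
#' interaction, and per-feature missingness rates (ER/PR default to the
#' ~66.8% missingness seen in large multi-center clinical tables).
#'
#' @param n number of patients (>= 2).
#' @param pcr_rate_target target pCR prevalence in (0, 1).
#' @param beta_img coefficient on the standardized imaging score.
#' @param beta_clin named numeric coefficients on raw clinical features
#'   (any of `age, race, er, pr, hr, her2, subtype`; age enters
#'   standardized).
#' @param gamma_interaction coefficient on `imaging_score x her2`.
#' @param missing_rates named per-feature missingness probabilities in
#'   `[0, 1]`.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 151L,
                        pcr_rate_target = 0.285,
                        beta_img = 1.2,
                        beta_clin = c(er = -0.8, her2 = 0.8),
                        gamma_interaction = 2,
                        missing_rates = c(er = 0.668, pr = 0.668),
                        seed = 1L) {
  stop_if_not(n >= 2, "n must be >= 2")
  stop_if_not(pcr_rate_target > 0 && pcr_rate_target < 1,
              "pcr_rate_target must be in (0,1)")
  stop_if_not(all(missing_rates >= 0 & missing_rates <= 1),
              "missing rates must be in [0,1]")
  stop_if_not(all(is.finite(c(beta_img, beta_clin, gamma_interaction))),
              "coefficients must be finite")
  structure(list(n = as.integer(n), pcr_rate_target = pcr_rate_target,
                 beta_img = beta_img, beta_clin = beta_clin,
                 gamma_interaction = gamma_interaction,
                 missing_rates = missing_rates, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Probability of pCR under the planted label model
#'
#' `p = logistic(intercept + beta_img * s + sum(beta_clin * x) +
#' gamma * s * her2)` where `s` is the imaging score.  The interaction is
#' planted on HER2 because HER2 status is the clinical marker most strongly
#' linked to chemosensitivity.
#'
#' @param imaging_score scalar or vector of standardized imaging scores.
#' @param clinical data.frame or named list with the raw clinical features
#'   (at least the ones named in `beta_clin`); `age` is standardized
#'   internally when present in `beta_clin`.
#' @param coeffs list with `intercept`, `beta_img`, `beta_clin` (named),
#'   `gamma_interaction`.
#' @return probabilities in (0, 1).
#' @export
label_probability <- function(imaging_score, clinical, coeffs) {
  stop_if_not(all(is.finite(unlist(coeffs))), "coefficients must be finite")
  eta <- coeffs$intercept + coeffs$beta_img * imaging_score
  bc <- coeffs$beta_clin
  for (nm in names(bc)) {
    v <- clinical[[nm]]
    if (nm == "age") v <- as.numeric(scale(v))
    eta <- eta + bc[[nm]] * v
  }
  her2 <- clinical[["her2"]]
  if (is.null(her2)) her2 <- 0
  eta <- eta + coeffs$gamma_interaction * imaging_score * her2
  sigmoid(eta)
}

# imaging score used by the label model: standardized tumor volume fraction
# plus standardized within-tumor heterogeneity, renormalized to unit scale
imaging_score_from_params <- function(volume_fraction, heterogeneity) {
  z <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  (z(volume_fraction) + z(heterogeneity)) / sqrt(2)
}

#' Generate a synthetic multimodal cohort
#'
#' Draws per-patient tumor geometry (radii, contrast, heterogeneity) around
#' a template phantom, renders the phantom volumes, samples the
#' seven-feature clinical table, computes the imaging score (standardized
#' tumor volume fraction plus heterogeneity), calibrates the label-model
#' intercept by root finding so the expected pCR rate matches
#' `spec$pcr_rate_target`, draws Bernoulli labels, and finally injects
#' missingness into the clinical table.  Labels always use the complete
#' (pre-missingness) features.
#'
#' @param spec a [cohort_spec()].
#' @param phantom_template a [phantom_spec()] providing the volume shape
#'   and baseline tumor parameters around which patients vary.
#' @return list with `volumes` (list of 3D arrays), `clinical`
#'   (data.frame: age, race, er, pr, hr, her2, subtype), `labels` (0/1
#'   vector), and `truth` (ground-truth parameters: imaging scores,
#'   calibrated intercept, achieved rate, per-patient tumor parameters,
#'   the complete clinical table, seed).
#' @export
generate_cohort <- function(spec, phantom_template = phantom_spec()) {
  stop_if_not(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  n <- spec$n
  shp <- phantom_template$shape

  out <- with_seed(spec$seed, {
    # per-patient tumor geometry around the template
    base_r <- phantom_template$tumor_radii
    radii <- matrix(0, n, 3)
    for (ax in 1:3) {
      radii[, ax] <- pmax(1.5, base_r[ax] * runif(n, 0.5, 1.4))
    }
    het <- pmax(0.05, phantom_template$heterogeneity * runif(n, 0.4, 2))
    contrast <- phantom_template$tumor_contrast * runif(n, 0.8, 1.2)
    centers <- matrix(runif(n * 3, 0.35, 0.65), n, 3)
    vol_seeds <- sample.int(.Machine$integer.max - 1L, n)

    # clinical table (complete); HR is positive when either ER or PR is
    race <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    er <- rbinom(n, 1, 0.55)
    pr <- rbinom(n, 1, 0.45)
    hr <- pmax(er, pr)
    her2 <- rbinom(n, 1, 0.3)
    subtype <- ifelse(hr == 1 & her2 == 0, 0L,
               ifelse(hr == 1 & her2 == 1, 1L,
               ifelse(hr == 0 & her2 == 1, 2L, 3L)))
    age <- round(rnorm(n, mean = 49, sd = 10), 1)
    clin <- data.frame(age = age, race = race, er = er, pr = pr,
                       hr = hr, her2 = her2, subtype = subtype)

    # render volumes
    volumes <- vector("list", n)
    vfrac <- numeric(n)
    for (i in seq_len(n)) {
      # shrink radii where the sampled ellipsoid would poke out of the volume
      ctr_vox <- centers[i, ] * (shp - 1) + 1
      radii[i, ] <- pmax(1, pmin(radii[i, ], ctr_vox - 1, shp - ctr_vox))
      ps <- phantom_spec(shape = shp, tumor_center = centers[i, ],
                         tumor_radii = radii[i, ],
                         tumor_contrast = contrast[i],
                         heterogeneity = het[i],
                         noise_sd = phantom_template$noise_sd,
                         seed = vol_seeds[i])
      pv <- generate_phantom_volume(ps)
      volumes[[i]] <- pv$volume
      vfrac[i] <- sum(pv$mask) / prod(shp)
    }
    s_img <- imaging_score_from_params(vfrac, het)

    # linear predictor without intercept, then calibrate the intercept so
    # the expected prevalence hits the target
    coeffs0 <- list(intercept = 0, beta_img = spec$beta_img,
                    beta_clin = spec$beta_clin,
                    gamma_interaction = spec$gamma_interaction)
    eta0 <- stats::qlogis(label_probability(s_img, clin, coeffs0))
    f <- function(b0) mean(sigmoid(b0 + eta0)) - spec$pcr_rate_target
    intercept <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
    p <- sigmoid(intercept + eta0)
    labels <- rbinom(n, 1, p)
    if (length(unique(labels)) < 2) {
      warning(sprintf(
        "degenerate label model: all labels are %d (achieved rate %.3f)",
        labels[1], mean(labels)))
    }

    # inject missingness (NA) into the observed table only
    clin_obs <- clin
    for (nm in names(spec$missing_rates)) {
      rate <- spec$missing_rates[[nm]]
      if (rate > 0) {
        miss <- runif(n) < rate
        clin_obs[[nm]][miss] <- NA
      }
    }

    list(volumes = volumes, clinical = clin_obs, labels = labels,
         truth = list(imaging_score = s_img, volume_fraction = vfrac,
                      heterogeneity = het, radii = radii,
                      contrast = contrast, centers = centers,
                      intercept = intercept, probabilities = p,
                      achieved_rate = mean(labels),
                      clinical_complete = clin, seed = spec$seed))
  })
  out
}

#' Write a synthetic cohort to disk
#'
#' Volumes go to `vol_<patient>.nii.gz`, the clinical table plus label to
#' `clinical.csv` (columns `age, race, er, pr, hr, her2, subtype, pcr`),
#' and ground-truth parameters plus seed to `truth.json`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort$volumes)
  for (i in seq_len(n)) {
    write_nifti_volume(cohort$volumes[[i]],
                       file.path(dir, sprintf("vol_%04d.nii.gz", i)))
  }
  tab <- cohort$clinical
  tab$pcr <- cohort$labels
  utils::write.csv(tab, file.path(dir, "clinical.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$radii <- as.data.frame(truth$radii)
  truth$centers <- as.data.frame(truth$centers)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `volumes`, `clinical`, `labels`, `truth`.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "^vol_.*\\.nii(\\.gz)?$",
                           full.names = TRUE))
  volumes <- lapply(files, read_nifti_volume)
  tab <- utils::read.csv(file.path(dir, "clinical.csv"))
  labels <- tab$pcr
  tab$pcr <- NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                            simplifyVector = TRUE)
           else NULL
  list(volumes = volumes, clinical = tab, labels = labels, truth = truth)
}
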