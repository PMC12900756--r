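#' Configuration of the synthetic tumor cohort generator
#'
#' The generator emulates corticomedullary-phase contrast-enhanced kidney
#' tumor volumes: a deformed ellipsoidal tumor inside a parenchyma slab, with
#' three concentric intensity-distinct subregions (enhancing rim, necrotic
#' core, transitional shell), dual-reader mask variability, a smooth
#' multiplicative bias field, and grade-linked clinical covariates. Defaults
#' give a high-grade prevalence of 27%, larger and more necrotic high-grade
#' tumors, and a strong association between high grade and low
#' corticomedullary enhancement.
#'
#' @param n_patients number of patients (>= 0).
#' @param high_grade_prevalence probability of WHO/ISUP high grade (III-IV).
#' @param k_true number of planted habitats (default 3).
#' @param subregion_means intensity level per planted habitat, ordered
#'   rim / core / transitional (arbitrary units around a parenchyma level of
#'   100).
#' @param subregion_noise_sd SD of the white (voxel-independent) noise
#'   component, recycled per habitat.
#' @param texture_sd SD of the spatially correlated texture component,
#'   recycled per habitat (MRI tissue texture is correlated, not white; the
#'   necrotic core is given the largest value by default, matching its
#'   radiological heterogeneity).
#' @param texture_smoothing_mm correlation length of the texture component.
#' @param tumor_radius_range_mm list with `low` and `high` grade radius
#'   ranges (mm).
#' @param necrosis_fraction_range list with `low` and `high` grade necrotic
#'   volume-fraction ranges.
#' @param rim_fraction radial coordinate where the enhancing rim starts.
#' @param deformation relative amplitude of the smooth random boundary
#'   deformation (0 = perfect ellipsoid).
#' @param reader2_perturbation_mm boundary jitter magnitude of the second
#'   reader's mask.
#' @param bias_field_amplitude log-scale amplitude of the multiplicative
#'   low-order bias field.
#' @param enhancement_effect named probabilities `c(low = , high = )` of a
#'   "low enhancement" radiological rating given grade.
#' @param grid_dim cubic grid size in voxels (1 mm spacing).
#' @param seed RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 40,
                          high_grade_prevalence = 0.27,
                          k_true = 3,
                          subregion_means = c(130, 75, 105),
                          subregion_noise_sd = c(25, 50, 8),
                          texture_sd = c(18, 28, 5),
                          texture_smoothing_mm = 1.2,
                          tumor_radius_range_mm = list(low = c(19, 24),
                                                       high = c(21, 28)),
                          necrosis_fraction_range = list(low = c(0.05, 0.20),
                                                         high = c(0.15, 0.40)),
                          rim_fraction = 0.70,
                          deformation = 0.06,
                          reader2_perturbation_mm = 1.0,
                          bias_field_amplitude = 0.15,
                          enhancement_effect = c(low = 0.20, high = 0.65),
                          grid_dim = 72,
                          seed = 1L) {
  if (n_patients < 0) stop("n_patients must be >= 0")
  if (high_grade_prevalence < 0 || high_grade_prevalence > 1)
    stop("high_grade_prevalence must be a probability")
  if (k_true < 1) stop("k_true must be >= 1")
  if (any(unlist(tumor_radius_range_mm) <= 0))
    stop("tumor radius ranges must be positive")
  structure(list(n_patients = as.integer(n_patients),
                 high_grade_prevalence = high_grade_prevalence,
                 k_true = as.integer(k_true),
                 subregion_means = subregion_means,
                 subregion_noise_sd = subregion_noise_sd,
                 texture_sd = texture_sd,
                 texture_smoothing_mm = texture_smoothing_mm,
                 tumor_radius_range_mm = tumor_radius_range_mm,
                 necrosis_fraction_range = necrosis_fraction_range,
                 rim_fraction = rim_fraction,
                 deformation = deformation,
                 reader2_perturbation_mm = reader2_perturbation_mm,
                 bias_field_amplitude = bias_field_amplitude,
                 enhancement_effect = enhancement_effect,
                 grid_dim = as.integer(grid_dim),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Low-resolution Gaussian noise upsampled to the full grid: a cheap smooth
# random field used for boundary deformation and reader jitter.
smooth_field <- function(grid_dim, coarse = 5L) {
  f <- array(rnorm(coarse^3), dim = rep(coarse, 3))
  out <- resample_cpp(as.numeric(f), rep(coarse, 3L), rep(1, 3), rep(0, 3),
                      rep(grid_dim, 3L), rep((coarse - 1) / (grid_dim - 1), 3),
                      rep(0, 3), nearest = FALSE)
  array(out, rep(grid_dim, 3L))
}

#' Generate a seeded synthetic cohort
#'
#' Same configuration and seed give a bit-identical cohort. Clinical tables
#' are identical whether or not images are rendered (`images = FALSE` skips
#' the voxel work, for covariate-level simulations).
#'
#' @param config a [cohort_config()].
#' @param images render volumes and masks (default TRUE).
#' @return List of patients; each has `id`, `grade`, `clinical` (one-row
#'   data.frame) and, when rendered, `volume`, `mask_reader1`, `mask_reader2`,
#'   `habitat_truth` (integer array, 0 background / 1..k inside the reader-1
#'   mask).
#' @export
generate_cohort <- function(config, images = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  if (n == 0) return(list())
  set.seed(config$seed)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    grade <- rbinom(1, 1, config$high_grade_prevalence)
    rr <- config$tumor_radius_range_mm[[if (grade == 1) "high" else "low"]]
    nf <- config$necrosis_fraction_range[[if (grade == 1) "high" else "low"]]
    radius <- runif(1, rr[1], rr[2])
    axes <- runif(3, 0.9, 1.1)
    necrosis <- runif(1, nf[1], nf[2])
    enh_p <- config$enhancement_effect[[if (grade == 1) "high" else "low"]]
    clinical <- data.frame(
      id = sprintf("P%03d", i),
      grade = grade,
      age = round(rnorm(1, 55 + 3 * grade, 12)),
      sex = if (runif(1) < 105 / 154) "M" else "F",
      diameter_mm = round(2 * radius * max(axes) + rnorm(1, 0, 1), 1),
      enhancement_low = rbinom(1, 1, enh_p),
      diabetes = rbinom(1, 1, 0.15),
      stringsAsFactors = FALSE)
    params[[i]] <- list(id = clinical$id, grade = grade, radius = radius,
                        axes = axes, necrosis = necrosis,
                        center_jitter = runif(3, -1.5, 1.5),
                        clinical = clinical,
                        image_seed = sample.int(.Machine$integer.max - 1, 1))
  }
  lapply(params, function(p) {
    pat <- list(id = p$id, grade = p$grade, clinical = p$clinical)
    if (images) pat <- c(pat, render_patient(p, config))
    pat
  })
}

render_patient <- function(p, config) {
  set.seed(p$image_seed)
  g <- config$grid_dim
  d <- rep(g, 3L)
  ctr <- (g - 1) / 2 + p$center_jitter

  ax <- arrayInd(seq_len(g^3), d)
  radii <- p$radius * p$axes
  u2 <- ((ax[, 1] - 1 - ctr[1]) / radii[1])^2 +
        ((ax[, 2] - 1 - ctr[2]) / radii[2])^2 +
        ((ax[, 3] - 1 - ctr[3]) / radii[3])^2
  u <- sqrt(u2)
  deform <- 1 + config$deformation * as.numeric(smooth_field(g))
  u_norm <- u / deform
  tumor <- u_norm <= 1

  # concentric habitats on the deformed radial coordinate, with a small
  # smooth wobble so boundaries are not perfect shells
  wobble <- 0.4 * config$deformation * as.numeric(smooth_field(g))
  # cap the necrotic core so the transitional shell keeps a minimum
  # thickness (the radiological reading always has a zone between rim and
  # core)
  core_r <- min(p$necrosis^(1 / 3), config$rim_fraction - 0.2)
  hab <- integer(g^3)
  hab[tumor] <- 3L                                   # transitional
  hab[tumor & (u_norm + wobble) <= core_r] <- 2L     # necrotic core
  hab[tumor & (u_norm + wobble) > config$rim_fraction] <- 1L  # enhancing rim

  # parenchyma slab: large centered ball; air elsewhere
  pc2 <- rowSums(sweep(ax - 1, 2, (g - 1) / 2)^2)
  paren <- pc2 <= (g / 2 - 2)^2

  # correlated tissue texture: smoothed white noise rescaled to unit SD,
  # then scaled per habitat (necrotic cores are more heterogeneous than
  # enhancing tissue)
  tex <- gaussian_smooth(array(rnorm(g^3), d), rep(1, 3),
                         config$texture_smoothing_mm)
  tex <- as.numeric(tex) / sd(tex)
  tex_sd <- rep_len(config$texture_sd, config$k_true)
  white_sd <- rep_len(config$subregion_noise_sd, config$k_true)

  arr <- abs(rnorm(g^3, 2, 1))
  arr[paren] <- 100 + 9 * tex[paren] + rnorm(sum(paren), 0, 5)
  for (h in seq_len(config$k_true)) {
    idx <- hab == h
    arr[idx] <- config$subregion_means[h] + tex_sd[h] * tex[idx] +
      rnorm(sum(idx), 0, white_sd[h])
  }

  # smooth multiplicative bias field
  bf <- as.numeric(smooth_field(g, coarse = 3L))
  bf <- bf - mean(bf)
  bf <- bf / max(abs(bf), 1e-12)
  arr <- arr * exp(config$bias_field_amplitude * bf)

  vol <- volume(array(arr, d))
  m1 <- region_mask(array(tumor, d), role = "tumor")

  # reader 2: jitter the boundary by a smooth signed-distance offset
  d_out <- sqrt(edt_sq_cpp(array(tumor, d), d, rep(1, 3)))
  d_in <- sqrt(edt_sq_cpp(array(!tumor, d), d, rep(1, 3)))
  signed <- d_out - d_in                      # positive outside the tumor
  eta <- as.numeric(smooth_field(g))
  eta <- config$reader2_perturbation_mm * eta / max(sd(eta), 1e-12)
  eta <- pmin(pmax(eta, -config$reader2_perturbation_mm),
              config$reader2_perturbation_mm)
  m2 <- region_mask(array(signed <= eta, d), role = "tumor")

  list(volume = vol, mask_reader1 = m1, mask_reader2 = m2,
       habitat_truth = array(hab, d))
}

#' Dice overlap of two masks
#' @param a,b [region_mask()] objects on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  2 * sum(a$array & b$array) / (sum(a$array) + sum(b$array))
}

#' Split a cohort into training and test sets
#'
#' @param patients list from [generate_cohort()] (or any list whose elements
#'   have `id` and `grade`).
#' @param ratio training fraction (default 0.7, the study's 7:3 split).
#' @param stratified preserve class fractions to within rounding.
#' @param seed RNG seed for the assignment.
#' @return list(train, test) of patient ids; disjoint and exhaustive.
#' @export
split_cohort <- function(patients, ratio = 0.7, stratified = TRUE, seed = 1L) {
  stopifnot(ratio >= 0, ratio <= 1)
  ids <- vapply(patients, `[[`, "", "id")
  grades <- vapply(patients, `[[`, 0, "grade")
  set.seed(seed)
  if (stratified) {
    if (length(unique(grades)) < 2 && length(ids) > 0)
      stop("stratified split requires both classes present")
    test <- character(0)
    for (gl in sort(unique(grades))) {
      cls <- ids[grades == gl]
      n_test <- round((1 - ratio) * length(cls))
      test <- c(test, sample(cls, n_test))
    }
    train <- setdiff(ids, test)
  } else {
    n_train <- round(ratio * length(ids))
    train <- sample(ids, n_train)
    test <- setdiff(ids, train)
  }
  list(train = sort(train), test = sort(test))
}

#' Write a rendered cohort to disk
#'
#' Volumes and masks as NIfTI (`.nii.gz`), plus a cohort CSV (one row per
#' patient: id, grade, covariates, file paths).
#'
#' @param patients list from [generate_cohort()] with images rendered.
#' @param dir output directory (created if needed).
#' @return Path to the cohort CSV, invisibly.
#' @export
write_cohort <- function(patients, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(patients, function(p) {
    vp <- file.path(dir, paste0(p$id, "_volume.nii.gz"))
    m1 <- file.path(dir, paste0(p$id, "_mask1.nii.gz"))
    m2 <- file.path(dir, paste0(p$id, "_mask2.nii.gz"))
    write_volume(p$volume, vp)
    write_volume(volume(p$mask_reader1$array + 0, p$mask_reader1$spacing,
                        p$mask_reader1$origin), m1)
    write_volume(volume(p$mask_reader2$array + 0, p$mask_reader2$spacing,
                        p$mask_reader2$origin), m2)
    cbind(p$clinical, volume_path = vp, mask1_path = m1, mask2_path = m2)
  })
  csv <- file.path(dir, "cohort.csv")
  write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}
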