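#' Simulation configuration for the synthetic PET cohort
#'
#' Bundles every parameter of the phantom generator. Defaults reproduce the
#' study conditions the pipeline is designed for: 52 normative controls, 62
#' patients on a 40x48x40 grid of 2 mm voxels, focal hypometabolic lesions
#' in the Rolandic strip, and a logistic link from the ground-truth resected
#' Rolandic mean T-value to the motor-deficit outcome calibrated so the true
#' model discriminates at AUC ~0.82 with deficit prevalence ~26/62.
#'
#' @param seed Integer RNG seed; every random draw in the generator flows
#'   from it through per-subject substreams.
#' @param n_controls Number of normative controls (>= 4; default 52).
#' @param n_patients Number of patients (>= 4; default 62).
#' @param grid A `volume_grid` (default 40x48x40, 2 mm).
#' @param baseline_uptake Mean in-brain uptake, arbitrary units (default 100).
#' @param noise_sd Additive voxel noise SD, same units (default 10).
#' @param lesion_effect Mean fractional uptake reduction inside the lesion,
#'   in \[0, 1\] (default 0.3); per-patient effects are drawn around it with
#'   SD `lesion_effect / 3`, truncated to \[0, 0.95\].
#' @param age_effect Uptake change per year of age (default 0.2).
#' @param gender_effect Additive uptake shift for gender code 1 (default 1).
#' @param logit_intercept,logit_slope Logistic link from the ground-truth
#'   resected-Rolandic mean T to deficit probability,
#'   `P(deficit) = plogis(logit_intercept + logit_slope * trueMeanT)`.
#' @param reorg_shift_mm Activation-centroid displacement in mm per unit of
#'   metabolic deficit magnitude in the classical ROI (default 40).
#' @param lesion_radius_mm Length-2 range (mm) for lesion ellipsoid
#'   semi-axes (default c(4, 9), giving resected Rolandic overlaps on the
#'   cm^3 scale).
#' @param act_radius_mm Radius of the rasterized activation blob (default 3).
#' @param fwhm_mm Analysis smoothing FWHM the ground truth is expressed
#'   against (default 8).
#' @param n_fmri Number of patients flagged as having undergone task fMRI
#'   (default 15); activation maps are generated for everyone, the flag
#'   selects the reorganization-analysis subgroup.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_controls = 52L,
                       n_patients = 62L,
                       grid = volume_grid(c(40L, 48L, 40L), c(2, 2, 2)),
                       baseline_uptake = 100,
                       noise_sd = 10,
                       lesion_effect = 0.3,
                       age_effect = 0.2,
                       gender_effect = 1,
                       logit_intercept = 4.01,
                       logit_slope = 0.29,
                       reorg_shift_mm = 150,
                       lesion_radius_mm = c(4, 9),
                       act_radius_mm = 3,
                       fwhm_mm = 8,
                       n_fmri = 15L) {
  cfg <- structure(
    list(seed = as.integer(seed), n_controls = as.integer(n_controls),
         n_patients = as.integer(n_patients), grid = grid,
         baseline_uptake = baseline_uptake, noise_sd = noise_sd,
         lesion_effect = lesion_effect, age_effect = age_effect,
         gender_effect = gender_effect, logit_intercept = logit_intercept,
         logit_slope = logit_slope, reorg_shift_mm = reorg_shift_mm,
         lesion_radius_mm = lesion_radius_mm, act_radius_mm = act_radius_mm,
         fwhm_mm = fwhm_mm, n_fmri = as.integer(n_fmri)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg$grid, "volume_grid"))
  if (cfg$n_controls < 4 || cfg$n_patients < 4) {
    stop("config error: need at least 4 controls and 4 patients",
         call. = FALSE)
  }
  if (cfg$lesion_effect < 0 || cfg$lesion_effect > 1) {
    stop("config error: lesion_effect must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$baseline_uptake <= 0) {
    stop("config error: baseline_uptake must be positive and noise_sd ",
         "nonnegative", call. = FALSE)
  }
  # deterministic part of uptake must stay positive over the age range
  lo <- cfg$baseline_uptake - abs(cfg$age_effect) * (40 - 3) -
    abs(cfg$gender_effect)
  if (lo <= 0) {
    stop("config error: covariate effects produce nonpositive uptake",
         call. = FALSE)
  }
  if (cfg$reorg_shift_mm < 0) {
    stop("config error: reorg_shift_mm must be nonnegative", call. = FALSE)
  }
  max_semi_vox <- cfg$lesion_radius_mm[2] / cfg$grid$voxel_size_mm
  hemi_vox <- prod(cfg$grid$dims) / 2
  if ((4 / 3) * pi * prod(max_semi_vox) >= hemi_vox) {
    stop("config error: lesion larger than hemisphere", call. = FALSE)
  }
  invisible(cfg)
}

# reference age: midpoint of the uniform[3, 40] simulated age range
.ref_age <- 21.5

# deterministic covariate part of a subject's uptake field
subject_signal <- function(cfg, age, gender) {
  cfg$baseline_uptake + cfg$age_effect * (age - .ref_age) +
    cfg$gender_effect * gender
}

draw_noise_volume <- function(cfg, brain) {
  v <- array(0, dim = cfg$grid$dims)
  v[brain$inside] <- stats::rnorm(sum(brain$inside), 0, cfg$noise_sd)
  v
}

#' Simulate the normative control cohort
#'
#' Each control volume is `baseline + age_effect*(age - 21.5) +
#' gender_effect*gender + N(0, noise_sd)` inside the brain mask and zero
#' outside, with ages drawn uniform on \[3, 40\] years and gender Bernoulli
#' 0.5 from per-subject substreams of `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @param atlas A `label_atlas` on `cfg$grid` (used for its grid/mask only).
#' @return List with `volumes` (named list of `brain_volume`) and
#'   `covariates` (tibble: subject_id, group, age, gender).
#' @export
simulate_control_cohort <- function(cfg, atlas) {
  validate_sim_config(cfg)
  brain <- brain_mask_for_grid(cfg$grid)
  ids <- sprintf("control_%03d", seq_len(cfg$n_controls))
  rows <- vector("list", cfg$n_controls)
  vols <- vector("list", cfg$n_controls)
  for (i in seq_along(ids)) {
    out <- with_substream(cfg$seed, ids[i], {
      age <- stats::runif(1, 3, 40)
      gender <- stats::rbinom(1, 1, 0.5)
      noise <- draw_noise_volume(cfg, brain)
      list(age = age, gender = gender, noise = noise)
    })
    v <- array(0, dim = cfg$grid$dims)
    v[brain$inside] <- subject_signal(cfg, out$age, out$gender) +
      out$noise[brain$inside]
    v[brain$inside] <- pmax(v[brain$inside], 1e-8)
    vols[[i]] <- brain_volume(v, cfg$grid)
    rows[[i]] <- tibble::tibble(subject_id = ids[i], group = "control",
                                age = out$age, gender = out$gender)
  }
  names(vols) <- ids
  list(volumes = vols, covariates = dplyr::bind_rows(rows))
}

# ground-truth T scale: first-order expected t for a fractional signal
# change after normalization and smoothing (see methods vignette)
true_t_scale <- function(cfg) {
  if (cfg$noise_sd <= 0) {
    stop("patient simulation requires noise_sd > 0 (the ground-truth ",
         "T scale is defined relative to the noise level)", call. = FALSE)
  }
  (cfg$noise_sd / cfg$baseline_uptake) *
    smoothing_noise_factor(cfg$grid, cfg$fwhm_mm) *
    sqrt(1 + 1 / cfg$n_controls)
}

# noise-free expected T field for one patient's lesion
true_t_field <- function(cfg, brain, lesion, effect) {
  f <- array(0, dim = cfg$grid$dims)
  f[brain$inside] <- cfg$baseline_uptake
  f[lesion$inside] <- f[lesion$inside] * (1 - effect)
  fn <- normalize_global_mean(brain_volume(f, cfg$grid), brain)
  s <- smooth_gaussian(fn, brain, cfg$fwhm_mm)
  delta <- s$values - 1
  delta[!brain$inside] <- 0
  delta / true_t_scale(cfg)
}

#' Simulate the patient cohort with ground truth
#'
#' Each patient receives an ellipsoidal hypometabolic lesion centred inside
#' one Rolandic strip label, with a patient-specific fractional effect drawn
#' around `cfg$lesion_effect`; a resection mask (lesion dilated one voxel
#' with a random 10% of the added shell removed, so the resection always
#' covers the lesion); a deficit label drawn Bernoulli on the logistic link
#' from the ground-truth resected-Rolandic mean T; and, for deficit
#' patients, a muscle strength grade in {2, 3, 4} assigned by tercile of the
#' true mean T (highest T, i.e. least preserved contrast with controls,
#' worst grade).
#'
#' @param cfg A `sim_config`.
#' @param atlas A `label_atlas` on `cfg$grid`.
#' @return List with `volumes`, `lesions`, `resections` (named lists),
#'   `covariates` (tibble), `records` (tibble: patient_id, age, gender,
#'   side, limb, deficit, strength_grade, has_fmri), and `ground_truth`
#'   (tibble of per-patient generator truth).
#' @export
simulate_patient_cohort <- function(cfg, atlas) {
  validate_sim_config(cfg)
  check_same_grid(cfg$grid, atlas)
  brain <- brain_mask_for_grid(cfg$grid)
  rolandic <- label_mask(atlas, "rolandic")
  half <- floor(cfg$grid$dims[1] / 2)
  hemi <- list(
    L = region_mask(voxel_index_arrays(cfg$grid$dims)$x < half,
                    cfg$grid, "hemisphere_L"),
    R = region_mask(voxel_index_arrays(cfg$grid$dims)$x >= half,
                    cfg$grid, "hemisphere_R")
  )
  # candidate lesion centres: the whole Rolandic area of each side,
  # including the hand-knob and paracentral sublabels (Rolandic FCD
  # frequently sits in the classical motor representations themselves)
  strip_vox <- list(
    L = which(atlas$labels %in% atlas$legend[c("rolandic_L", "handknob_L",
                                               "paracentral_L")]),
    R = which(atlas$labels %in% atlas$legend[c("rolandic_R", "handknob_R",
                                               "paracentral_R")])
  )

  ids <- sprintf("patient_%03d", seq_len(cfg$n_patients))
  vols <- lesions <- resections <- vector("list", cfg$n_patients)
  cov_rows <- rec_rows <- gt_rows <- vector("list", cfg$n_patients)

  for (i in seq_along(ids)) {
    id <- ids[i]
    res <- with_substream(cfg$seed, id, {
      age <- stats::runif(1, 3, 40)
      gender <- stats::rbinom(1, 1, 0.5)
      side <- if (stats::runif(1) < 0.5) "L" else "R"
      center_idx <- strip_vox[[side]][
        sample.int(length(strip_vox[[side]]), 1)]
      semi_mm <- stats::runif(3, cfg$lesion_radius_mm[1],
                              cfg$lesion_radius_mm[2])
      effect <- stats::rnorm(1, cfg$lesion_effect, cfg$lesion_effect / 3)
      effect <- min(max(effect, 0), 0.95)

      center_vox <- arrayInd(center_idx, cfg$grid$dims) - 1
      les <- ellipsoid_mask(cfg$grid, as.numeric(center_vox),
                            semi_mm / cfg$grid$voxel_size_mm)
      les <- region_mask(les$inside & brain$inside & hemi[[side]]$inside,
                         cfg$grid, paste0(id, "_lesion"))
      dil <- dilate1(les)
      dil <- region_mask(dil$inside & brain$inside & hemi[[side]]$inside,
                         cfg$grid, paste0(id, "_resection"))
      shell <- which(dil$inside & !les$inside)
      n_drop <- floor(0.1 * length(shell))
      if (n_drop > 0) {
        drop <- shell[sample.int(length(shell), n_drop)]
        rs <- dil$inside
        rs[drop] <- FALSE
        dil <- region_mask(rs, cfg$grid, paste0(id, "_resection"))
      }

      noise <- draw_noise_volume(cfg, brain)
      u_deficit <- stats::runif(1)
      list(age = age, gender = gender, side = side, semi_mm = semi_mm,
           effect = effect, lesion = les, resection = dil, noise = noise,
           u_deficit = u_deficit)
    })

    # uptake: multiplicative lesion on the deterministic signal, then noise
    sig <- array(0, dim = cfg$grid$dims)
    sig[brain$inside] <- subject_signal(cfg, res$age, res$gender)
    sig[res$lesion$inside] <- sig[res$lesion$inside] * (1 - res$effect)
    sig[brain$inside] <- pmax(sig[brain$inside] + res$noise[brain$inside],
                              1e-8)
    vols[[i]] <- brain_volume(sig, cfg$grid)
    lesions[[i]] <- res$lesion
    resections[[i]] <- res$resection

    # ground-truth T and deficit draw
    tt <- true_t_field(cfg, brain, res$lesion, res$effect)
    roi <- res$resection$inside & rolandic$inside
    stopifnot(sum(roi) > 0)
    true_mean_t <- mean(tt[roi])
    p_def <- stats::plogis(cfg$logit_intercept +
                             cfg$logit_slope * true_mean_t)
    deficit <- as.integer(res$u_deficit < p_def)

    # metabolic deficit magnitude in the classical ROIs (smoothed
    # fractional-reduction field), driving activation displacement
    efield <- array(0, dim = cfg$grid$dims)
    efield[res$lesion$inside] <- res$effect
    es <- smooth_gaussian(brain_volume(efield, cfg$grid), brain,
                          cfg$fwhm_mm)$values
    hk <- label_mask(atlas, paste0("handknob_", res$side))
    pc <- label_mask(atlas, paste0("paracentral_", res$side))
    mag_upper <- mean(es[hk$inside])
    mag_lower <- mean(es[pc$inside])

    cov_rows[[i]] <- tibble::tibble(subject_id = id, group = "patient",
                                    age = res$age, gender = res$gender)
    rec_rows[[i]] <- tibble::tibble(
      patient_id = id, age = res$age, gender = res$gender, side = res$side,
      limb = if (mag_upper >= mag_lower) "upper" else "lower",
      deficit = deficit, has_fmri = i <= cfg$n_fmri
    )
    gt_rows[[i]] <- tibble::tibble(
      patient_id = id, lesion_effect_true = res$effect,
      lesion_voxels = sum(res$lesion$inside),
      resection_voxels = sum(res$resection$inside),
      true_mean_t = true_mean_t, deficit_prob = p_def, deficit = deficit,
      mag_upper = mag_upper, mag_lower = mag_lower
    )
  }
  names(vols) <- names(lesions) <- names(resections) <- ids
  records <- dplyr::bind_rows(rec_rows)
  gt <- dplyr::bind_rows(gt_rows)

  # strength grades: terciles of true mean T among deficit patients,
  # highest T -> grade 2 (worst), lowest -> grade 4
  records$strength_grade <- NA_integer_
  def_idx <- which(records$deficit == 1)
  if (length(def_idx) > 0) {
    tvals <- gt$true_mean_t[def_idx]
    r <- rank(-tvals, ties.method = "first")
    grade <- 2L + as.integer(floor(3 * (r - 1) / length(r)))
    records$strength_grade[def_idx] <- grade
  }

  list(volumes = vols, lesions = lesions, resections = resections,
       covariates = dplyr::bind_rows(cov_rows), records = records,
       ground_truth = gt)
}

#' Displacement vector of a simulated activation centroid
#'
#' Pure geometry: displacement (mm) = `reorg_shift_mm * magnitude` along the
#' canonical reorganization direction — posterior-inferior for the upper
#' limb (hand), anterior for the lower limb (foot).
#'
#' @param magnitude Metabolic deficit magnitude in the classical ROI
#'   (mean smoothed fractional uptake reduction, unitless).
#' @param reorg_shift_mm Displacement per unit magnitude, mm.
#' @param limb `"upper"` or `"lower"`.
#' @return Numeric length-3 displacement in mm (x, y, z).
#' @export
activation_displacement_mm <- function(magnitude, reorg_shift_mm, limb) {
  limb <- match.arg(limb, c("upper", "lower"))
  dir <- if (limb == "upper") c(0, -1, -1) / sqrt(2) else c(0, 1, 0)
  reorg_shift_mm * magnitude * dir
}

#' Simulate one motor activation map
#'
#' Rasterizes a compact spherical activation blob whose centroid is the
#' classical ROI centroid (hand-knob for the upper limb, paracentral lobule
#' for the lower limb, on the patient's lesion side) displaced by
#' [activation_displacement_mm()] scaled by that patient's metabolic deficit
#' magnitude in the ROI. A displacement that would push the blob off the
#' grid is clamped with a warning.
#'
#' @param patient One row of the patient `records`/`ground_truth` join (must
#'   carry `patient_id`, `side`, `mag_upper`, `mag_lower`).
#' @param atlas A `label_atlas`.
#' @param cfg The `sim_config`.
#' @param limb `"upper"` or `"lower"`.
#' @return An `activation_map`: list with logical array `active`, `grid`,
#'   `limb`, `side`, and the pre-rasterization `displacement_mm`.
#' @export
simulate_activation_map <- function(patient, atlas, cfg,
                                    limb = c("upper", "lower")) {
  limb <- match.arg(limb)
  grid <- atlas$grid
  brain <- brain_mask_for_grid(grid)
  roi_name <- paste0(if (limb == "upper") "handknob_" else "paracentral_",
                     patient$side)
  roi <- label_mask(atlas, roi_name)
  ctr <- mask_centroid_vox(roi)
  mag <- if (limb == "upper") patient$mag_upper else patient$mag_lower
  disp <- activation_displacement_mm(mag, cfg$reorg_shift_mm, limb)
  center <- ctr + disp / grid$voxel_size_mm
  r_vox <- cfg$act_radius_mm / grid$voxel_size_mm
  lo <- r_vox
  hi <- grid$dims - 1 - r_vox
  clamped <- pmin(pmax(center, lo), hi)
  if (any(abs(clamped - center) > 1e-9)) {
    warning("activation displacement for ", patient$patient_id, " (", limb,
            ") clamped to stay on the grid", call. = FALSE)
  }
  blob <- ellipsoid_mask(grid, clamped, r_vox)
  active <- blob$inside & brain$inside
  # a blob clamped into a grid corner can leave the brain entirely; walk
  # it back toward the ROI centroid until it regains brain coverage
  steps <- 0
  while (!any(active) && steps < 30) {
    clamped <- (clamped + ctr) / 2
    blob <- ellipsoid_mask(grid, clamped, r_vox)
    active <- blob$inside & brain$inside
    steps <- steps + 1
  }
  structure(
    list(active = active, grid = grid, limb = limb, side = patient$side,
         displacement_mm = disp),
    class = "activation_map"
  )
}

#' Simulate a complete phantom cohort
#'
#' Atlas, controls, patients, and per-patient activation maps (both limbs)
#' in one deterministic object.
#'
#' @param cfg A `sim_config`.
#' @return A `pet_cohort` list: `config`, `atlas`, `brain_mask`, `controls`,
#'   `patients`, `lesions`, `resections`, `activations`, `covariates`,
#'   `records`, `ground_truth`.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(seed = 7, n_controls = 6,
#'                                      n_patients = 4,
#'                                      grid = volume_grid(c(24, 28, 24))))
#' cohort$records
#' }
simulate_cohort <- function(cfg) {
  atlas <- build_atlas_phantom(cfg$grid)
  ctl <- simulate_control_cohort(cfg, atlas)
  pat <- simulate_patient_cohort(cfg, atlas)
  gt_join <- dplyr::left_join(pat$records, pat$ground_truth,
                              by = "patient_id")
  acts <- lapply(seq_len(nrow(gt_join)), function(i) {
    row <- gt_join[i, ]
    list(upper = simulate_activation_map(row, atlas, cfg, "upper"),
         lower = simulate_activation_map(row, atlas, cfg, "lower"))
  })
  names(acts) <- pat$records$patient_id
  structure(
    list(config = cfg, atlas = atlas,
         brain_mask = brain_mask_for_grid(cfg$grid),
         controls = ctl$volumes, patients = pat$volumes,
         lesions = pat$lesions, resections = pat$resections,
         activations = acts,
         covariates = dplyr::bind_rows(ctl$covariates, pat$covariates),
         records = pat$records, ground_truth = pat$ground_truth),
    class = "pet_cohort"
  )
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf(
    "<pet_cohort> %d controls, %d patients (%d deficit) on %s grid, seed %d\n",
    length(x$controls), length(x$patients), sum(x$records$deficit),
    paste(x$config$grid$dims, collapse = "x"), x$config$seed))
  invisible(x)
}
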