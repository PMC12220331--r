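#' Write a simulated cohort to disk
#'
#' Lays out a self-contained dataset directory: NIfTI-1 volumes
#' (uncompressed `.nii`, so re-writing is byte-identical), CSV tables, and
#' JSON ground truth, config and manifest. The manifest's `volumes` section
#' lists the analysis volumes (one PET per control, one PET + one resection
#' + two activation maps per patient, plus the atlas) with MD5 checksums;
#' auxiliary files (brain mask, lesion masks, tables) are listed separately.
#'
#' @param cohort A `pet_cohort`.
#' @param path Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_dataset <- function(cohort, path) {
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    stop("cannot create dataset directory: ", path, call. = FALSE)
  }
  dir.create(file.path(path, "controls"), showWarnings = FALSE)
  dir.create(file.path(path, "patients"), showWarnings = FALSE)

  vol_files <- character(0)
  write_volume(cohort$atlas_volume %||%
                 brain_volume(cohort$atlas$labels, cohort$config$grid),
               file.path(path, "atlas.nii"))
  vol_files <- c(vol_files, "atlas.nii")
  for (id in names(cohort$controls)) {
    f <- file.path("controls", paste0(id, ".nii"))
    write_volume(cohort$controls[[id]], file.path(path, f))
    vol_files <- c(vol_files, f)
  }
  for (id in names(cohort$patients)) {
    fs <- file.path("patients", paste0(id, c("_pet.nii", "_resection.nii",
                                             "_act_upper.nii",
                                             "_act_lower.nii")))
    write_volume(cohort$patients[[id]], file.path(path, fs[1]))
    write_volume(cohort$resections[[id]], file.path(path, fs[2]))
    write_volume(region_mask(cohort$activations[[id]]$upper$active,
                             cohort$config$grid),
                 file.path(path, fs[3]))
    write_volume(region_mask(cohort$activations[[id]]$lower$active,
                             cohort$config$grid),
                 file.path(path, fs[4]))
    vol_files <- c(vol_files, fs)
  }

  aux_files <- "brain_mask.nii"
  write_volume(cohort$brain_mask, file.path(path, "brain_mask.nii"))
  for (id in names(cohort$lesions)) {
    f <- file.path("patients", paste0(id, "_lesion.nii"))
    write_volume(cohort$lesions[[id]], file.path(path, f))
    aux_files <- c(aux_files, f)
  }
  utils::write.csv(cohort$covariates, file.path(path, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$records, file.path(path, "records.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass_deep(cohort$config),
         legend = as.list(cohort$atlas$legend),
         ground_truth = cohort$ground_truth),
    file.path(path, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  aux_files <- c(aux_files, "covariates.csv", "records.csv",
                 "ground_truth.json")

  manifest <- list(
    config_hash = config_hash(cohort$config),
    volumes = data.frame(
      path = vol_files,
      md5 = file_md5(file.path(path, vol_files))),
    auxiliary = data.frame(
      path = aux_files,
      md5 = file_md5(file.path(path, aux_files)))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a dataset directory against its manifest
#'
#' @param path Dataset directory containing `manifest.json`.
#' @return The parsed manifest, invisibly; errors if any listed file is
#'   missing or its checksum has changed.
#' @export
validate_manifest <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("no manifest.json in ", path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  files <- rbind(manifest$volumes, manifest$auxiliary)
  full <- file.path(path, files$path)
  missing <- !file.exists(full)
  if (any(missing)) {
    stop("manifest validation failed; missing file(s): ",
         paste(files$path[missing], collapse = ", "), call. = FALSE)
  }
  changed <- file_md5(full) != files$md5
  if (any(changed)) {
    stop("manifest validation failed; checksum mismatch: ",
         paste(files$path[changed], collapse = ", "), call. = FALSE)
  }
  invisible(manifest)
}

#' Read a dataset directory back into a `pet_cohort`
#'
#' Inverse of [write_dataset()]; validates the manifest first.
#'
#' @param path Dataset directory.
#' @return A `pet_cohort`.
#' @export
read_dataset <- function(path) {
  validate_manifest(path)
  gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                            simplifyVector = TRUE)
  cfgl <- gt$config
  cfg <- sim_config(
    seed = cfgl$seed, n_controls = cfgl$n_controls,
    n_patients = cfgl$n_patients,
    grid = volume_grid(unlist(cfgl$grid$dims), unlist(cfgl$grid$voxel_size_mm),
                       affine = if (is.matrix(cfgl$grid$affine)) {
                         cfgl$grid$affine
                       } else {
                         do.call(rbind, lapply(cfgl$grid$affine, unlist))
                       }),
    baseline_uptake = cfgl$baseline_uptake, noise_sd = cfgl$noise_sd,
    lesion_effect = cfgl$lesion_effect, age_effect = cfgl$age_effect,
    gender_effect = cfgl$gender_effect,
    logit_intercept = cfgl$logit_intercept, logit_slope = cfgl$logit_slope,
    reorg_shift_mm = cfgl$reorg_shift_mm,
    lesion_radius_mm = unlist(cfgl$lesion_radius_mm),
    act_radius_mm = cfgl$act_radius_mm, fwhm_mm = cfgl$fwhm_mm,
    n_fmri = cfgl$n_fmri)

  atlas_vol <- read_volume(file.path(path, "atlas.nii"))
  legend <- unlist(gt$legend)
  atlas <- structure(
    list(labels = array(as.integer(round(atlas_vol$values)),
                        dim = cfg$grid$dims),
         grid = cfg$grid, legend = legend[names(atlas_labels)]),
    class = "label_atlas")

  covs <- tibble::as_tibble(utils::read.csv(file.path(path,
                                                      "covariates.csv")))
  records <- tibble::as_tibble(utils::read.csv(file.path(path,
                                                         "records.csv")))
  ctl_ids <- covs$subject_id[covs$group == "control"]
  pat_ids <- records$patient_id

  rd <- function(f) brain_volume(read_volume(file.path(path, f))$values,
                                 cfg$grid)
  rm_ <- function(f, prov) region_mask(
    read_volume(file.path(path, f))$values > 0.5, cfg$grid, prov)
  controls <- lapply(ctl_ids,
                     function(id) rd(file.path("controls",
                                               paste0(id, ".nii"))))
  names(controls) <- ctl_ids
  patients <- lapply(pat_ids,
                     function(id) rd(file.path("patients",
                                               paste0(id, "_pet.nii"))))
  names(patients) <- pat_ids
  lesions <- lapply(pat_ids, function(id)
    rm_(file.path("patients", paste0(id, "_lesion.nii")),
        paste0(id, "_lesion")))
  names(lesions) <- pat_ids
  resections <- lapply(pat_ids, function(id)
    rm_(file.path("patients", paste0(id, "_resection.nii")),
        paste0(id, "_resection")))
  names(resections) <- pat_ids
  activations <- lapply(pat_ids, function(id) {
    side <- records$side[records$patient_id == id]
    list(
      upper = structure(
        list(active = rm_(file.path("patients",
                                    paste0(id, "_act_upper.nii")),
                          "act")$inside,
             grid = cfg$grid, limb = "upper", side = side),
        class = "activation_map"),
      lower = structure(
        list(active = rm_(file.path("patients",
                                    paste0(id, "_act_lower.nii")),
                          "act")$inside,
             grid = cfg$grid, limb = "lower", side = side),
        class = "activation_map"))
  })
  names(activations) <- pat_ids

  structure(
    list(config = cfg, atlas = atlas,
         brain_mask = rm_("brain_mask.nii", "brain"),
         controls = controls, patients = patients, lesions = lesions,
         resections = resections, activations = activations,
         covariates = covs, records = records,
         ground_truth = tibble::as_tibble(gt$ground_truth)),
    class = "pet_cohort")
}
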