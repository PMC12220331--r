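#' Intersect a resection mask with an atlas label
#'
#' Voxel-wise AND of the resection with the named label; `"rolandic"`
#' (and the other bilateral shorthands) take the union of left and right —
#' resections are unilateral, so the intersection is naturally confined to
#' the operated side. An empty intersection is returned flagged, not thrown:
#' such patients are excluded from the prediction analysis upstream.
#'
#' @param resection A `region_mask`.
#' @param atlas A `label_atlas` on the same grid.
#' @param label_name Label or bilateral shorthand (e.g. `"rolandic"`).
#' @return A `region_mask` with attribute `empty` set if no voxel survives.
#' @export
intersect_resection_with_label <- function(resection, atlas, label_name) {
  check_same_grid(resection, atlas, "resection and atlas")
  lab <- label_mask(atlas, label_name)
  out <- region_mask(resection$inside & lab$inside, resection$grid,
                     paste0(resection$provenance, "&", label_name))
  attr(out, "empty") <- sum(out$inside) == 0
  out
}

#' Mean T-value inside a region
#'
#' Arithmetic mean of the unthresholded T-map over the region's voxels;
#' zero-variance voxels (flagged t = 0) are included at value 0, so the
#' region mean stays defined on noise-free phantoms.
#'
#' @param tmap A `t_map`.
#' @param region A nonempty `region_mask` inside the analysis mask.
#' @return One-row tibble: `region`, `n_voxels`, `volume_mm3`, `mean_t`.
#' @export
mean_t_in_region <- function(tmap, region) {
  check_same_grid(tmap, region, "t-map and region")
  n <- sum(region$inside)
  if (n == 0) {
    stop("empty region '", region$provenance,
         "': mean T is undefined (patient should be excluded)",
         call. = FALSE)
  }
  vals <- tmap$t[region$inside]
  if (anyNA(vals)) {
    stop("region '", region$provenance,
         "' extends outside the analysis mask", call. = FALSE)
  }
  vol_mm3 <- n * voxel_volume_mm3(region$grid)
  tibble::tibble(region = region$provenance, n_voxels = n,
                 volume_mm3 = vol_mm3, mean_t = mean(vals))
}

#' Activation overlap rate with a classical motor ROI
#'
#' `rate = |activation AND roi| / |activation|`: the fraction of the
#' patient's activation volume captured by the classical ROI. A rate near 1
#' means no reorganization; near 0, full displacement. A Dice variant
#' (`2|A&R| / (|A|+|R|)`) is available for sensitivity analysis.
#'
#' @param act An `activation_map` (nonempty).
#' @param atlas A `label_atlas`.
#' @param roi_name ROI label; must match the activation's limb (upper limb
#'   to a hand-knob label, lower to a paracentral label).
#' @param rate_type `"activation"` (default) or `"dice"`.
#' @return One-row tibble: `roi`, `rate`, `n_activation`, `n_intersection`.
#' @export
activation_overlap_rate <- function(act, atlas, roi_name,
                                    rate_type = c("activation", "dice")) {
  rate_type <- match.arg(rate_type)
  check_same_grid(act, atlas, "activation and atlas")
  n_act <- sum(act$active)
  if (n_act == 0) {
    stop("empty activation map: overlap rate undefined", call. = FALSE)
  }
  expected <- if (act$limb == "upper") "handknob" else "paracentral"
  if (!startsWith(roi_name, expected)) {
    stop("ROI '", roi_name, "' does not match a ", act$limb,
         "-limb activation (expected a ", expected, " label)",
         call. = FALSE)
  }
  roi <- label_mask(atlas, roi_name)
  n_int <- sum(act$active & roi$inside)
  rate <- switch(rate_type,
                 activation = n_int / n_act,
                 dice = 2 * n_int / (n_act + sum(roi$inside)))
  tibble::tibble(roi = roi_name, rate = rate, n_activation = n_act,
                 n_intersection = n_int, rate_type = rate_type)
}

#' Mean T-value inside a classical atlas ROI
#'
#' @param tmap A `t_map`.
#' @param atlas A `label_atlas`.
#' @param roi_name Label or bilateral shorthand.
#' @return One-row tibble as [mean_t_in_region()].
#' @export
roi_mean_t <- function(tmap, atlas, roi_name) {
  mean_t_in_region(tmap, label_mask(atlas, roi_name))
}

#' Per-patient resected-Rolandic mean T and overlap rates
#'
#' The extraction stage: intersects every patient's resection with the
#' Rolandic area, computes the mean T-value there (the outcome-model
#' predictor), and, for patients in the fMRI subgroup, the activation
#' overlap rates and classical-ROI mean T per limb. Patients with an empty
#' resection-Rolandic intersection are dropped with a warning.
#'
#' @param tmaps Named list of `t_map`s from [compute_patient_tmaps()].
#' @param cohort The `pet_cohort`.
#' @return Tibble: one row per patient with `mean_t`, region sizes,
#'   deficit/grade columns, and `overlap_upper`, `overlap_lower`,
#'   `roi_t_upper`, `roi_t_lower` (NA outside the fMRI subgroup).
#' @export
extract_patient_metrics <- function(tmaps, cohort) {
  atlas <- cohort$atlas
  rows <- lapply(cohort$records$patient_id, function(id) {
    rec <- cohort$records[cohort$records$patient_id == id, ]
    inter <- intersect_resection_with_label(cohort$resections[[id]],
                                            atlas, "rolandic")
    if (isTRUE(attr(inter, "empty"))) {
      warning("patient ", id, " has empty resection-Rolandic overlap; ",
              "excluded from prediction analysis", call. = FALSE)
      return(NULL)
    }
    mt <- mean_t_in_region(tmaps[[id]], inter)
    out <- tibble::tibble(
      patient_id = id, deficit = rec$deficit,
      strength_grade = rec$strength_grade, has_fmri = rec$has_fmri,
      side = rec$side, limb = rec$limb,
      n_voxels = mt$n_voxels, volume_mm3 = mt$volume_mm3,
      mean_t = mt$mean_t,
      overlap_upper = NA_real_, overlap_lower = NA_real_,
      roi_t_upper = NA_real_, roi_t_lower = NA_real_
    )
    if (rec$has_fmri) {
      hk <- paste0("handknob_", rec$side)
      pc <- paste0("paracentral_", rec$side)
      out$overlap_upper <- activation_overlap_rate(
        cohort$activations[[id]]$upper, atlas, hk)$rate
      out$overlap_lower <- activation_overlap_rate(
        cohort$activations[[id]]$lower, atlas, pc)$rate
      out$roi_t_upper <- roi_mean_t(tmaps[[id]], atlas, hk)$mean_t
      out$roi_t_lower <- roi_mean_t(tmaps[[id]], atlas, pc)$mean_t
    }
    out
  })
  dplyr::bind_rows(rows)
}
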