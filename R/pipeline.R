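#' Pipeline run configuration
#'
#' Everything a full phantom-to-prediction run needs. All randomness flows
#' from `sim$seed` (data generation) and `cv_seed` (fold assignment).
#'
#' @param out_dir Output directory for all stages.
#' @param sim A `sim_config`.
#' @param fwhm_mm Analysis smoothing FWHM (default 8 mm).
#' @param k_folds Cross-validation folds (default 5).
#' @param cv_seed Fold-assignment seed (default `sim$seed + 1`).
#' @return A validated `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(), fwhm_mm = 8,
                       k_folds = 5, cv_seed = sim$seed + 1L) {
  stopifnot(inherits(sim, "sim_config"), fwhm_mm >= 0, k_folds >= 2)
  structure(
    list(out_dir = out_dir, sim = sim, fwhm_mm = fwhm_mm,
         k_folds = as.integer(k_folds), cv_seed = as.integer(cv_seed)),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Schema-validated: unknown keys at either level are rejected before any
#' stage runs.
#'
#' @param path YAML file with keys `out_dir`, `fwhm_mm`, `k_folds`,
#'   `cv_seed` and a `sim` block of [sim_config()] arguments (`grid` given
#'   as `dims` + `voxel_size_mm`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top_keys <- c("out_dir", "sim", "fwhm_mm", "k_folds", "cv_seed")
  unknown <- setdiff(names(raw), top_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$out_dir)) stop("config needs out_dir", call. = FALSE)
  sim_args <- raw$sim %||% list()
  sim_keys <- setdiff(names(formals(sim_config)), "grid")
  unknown <- setdiff(names(sim_args), c(sim_keys, "dims", "voxel_size_mm"))
  if (length(unknown)) {
    stop("unknown sim key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grid <- volume_grid(unlist(sim_args$dims %||% c(40, 48, 40)),
                      unlist(sim_args$voxel_size_mm %||% c(2, 2, 2)))
  sim_args <- sim_args[setdiff(names(sim_args), c("dims", "voxel_size_mm"))]
  sim_args <- lapply(sim_args, unlist)
  sim <- do.call(sim_config, c(sim_args, list(grid = grid)))
  args <- list(out_dir = raw$out_dir, sim = sim)
  for (kk in c("fwhm_mm", "k_folds", "cv_seed")) {
    if (!is.null(raw[[kk]])) args[[kk]] <- raw[[kk]]
  }
  do.call(run_config, args)
}

manifest_path <- function(out_dir) file.path(out_dir, "run_manifest.json")

read_run_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (!file.exists(p)) return(list(stages = list()))
  jsonlite::read_json(p, simplifyVector = TRUE)
}

# run one stage with content-addressed skipping: a stage re-executes only
# when its input signature changed or any declared output is missing/stale
run_stage <- function(state, name, input_files, fn, output_files) {
  out_dir <- state$cfg$out_dir
  sig_src <- c(state$config_hash,
               if (length(input_files)) file_md5(input_files))
  sig <- paste(sig_src, collapse = ";")
  prev <- state$manifest$stages[[name]]
  outputs_full <- file.path(out_dir, output_files)
  up_to_date <- !is.null(prev) && identical(prev$input_sig, sig) &&
    identical(sort(unlist(prev$outputs$path)), sort(output_files)) &&
    all(file.exists(outputs_full)) &&
    identical(unname(file_md5(file.path(out_dir, prev$outputs$path))),
              unlist(prev$outputs$md5))
  if (up_to_date) {
    state$executed[[name]] <- FALSE
    return(state)
  }
  message("[petmotor] running stage: ", name)
  fn()
  missing <- !file.exists(outputs_full)
  if (any(missing)) {
    stop("stage '", name, "' failed to produce: ",
         paste(output_files[missing], collapse = ", "), call. = FALSE)
  }
  state$manifest$stages[[name]] <- list(
    input_sig = sig,
    outputs = data.frame(path = output_files,
                         md5 = file_md5(outputs_full)))
  state$executed[[name]] <- TRUE
  state
}

#' Run the full phantom-to-prediction pipeline
#'
#' Stages: `simulate` (phantom dataset), `tmap` (per-patient normalized,
#' smoothed, GLM T-maps), `extract` (resection-Rolandic mean T + overlap
#' rates), `analyze` (group statistics, reorganization correlation, cohort
#' table), `predict` (cross-validated logistic model, OR, ROC), `report`
#' (Markdown summary). Stages whose inputs and outputs are
#' checksum-unchanged are skipped, so an unchanged re-run performs no
#' recomputation and the run manifest (which carries no timestamps) is
#' byte-identical.
#'
#' @param cfg A `run_config`.
#' @return The run manifest (list), with attribute `executed` naming which
#'   stages actually ran.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tmaps"), showWarnings = FALSE)
  state <- new.env()
  state$cfg <- cfg
  state$config_hash <- config_hash(list(sim = unclass_deep(cfg$sim),
                                        fwhm_mm = cfg$fwhm_mm,
                                        k_folds = cfg$k_folds,
                                        cv_seed = cfg$cv_seed))
  state$manifest <- read_run_manifest(out_dir)
  state$executed <- list()

  ds_dir <- file.path(out_dir, "dataset")
  n_pat <- cfg$sim$n_patients
  n_ctl <- cfg$sim$n_controls
  pat_ids <- sprintf("patient_%03d", seq_len(n_pat))
  ctl_ids <- sprintf("control_%03d", seq_len(n_ctl))
  ds_files <- file.path("dataset", c(
    "atlas.nii", "brain_mask.nii", "covariates.csv", "records.csv",
    "ground_truth.json", "manifest.json",
    file.path("controls", paste0(ctl_ids, ".nii")),
    file.path("patients",
              c(paste0(pat_ids, "_pet.nii"),
                paste0(pat_ids, "_resection.nii"),
                paste0(pat_ids, "_act_upper.nii"),
                paste0(pat_ids, "_act_lower.nii"),
                paste0(pat_ids, "_lesion.nii")))))

  state <- run_stage(state, "simulate", character(0), function() {
    cohort <- simulate_cohort(cfg$sim)
    write_dataset(cohort, ds_dir)
  }, ds_files)

  tmap_files <- c(file.path("tmaps", paste0(pat_ids, "_tmap.nii")),
                  file.path("tmaps", "meta.json"))
  state <- run_stage(state, "tmap",
                     file.path(out_dir, ds_files), function() {
    cohort <- read_dataset(ds_dir)
    tmaps <- compute_patient_tmaps(cohort, fwhm_mm = cfg$fwhm_mm)
    for (id in names(tmaps)) {
      arr <- tmaps[[id]]$t
      arr[is.na(arr)] <- 0
      write_volume(brain_volume(arr, cohort$config$grid),
                   file.path(out_dir, "tmaps", paste0(id, "_tmap.nii")))
    }
    jsonlite::write_json(
      list(df = tmaps[[1]]$df, contrast = tmaps[[1]]$contrast,
           fwhm_mm = cfg$fwhm_mm, seed = cfg$sim$seed,
           config_hash = attr(tmaps, "config_hash")),
      file.path(out_dir, "tmaps", "meta.json"),
      auto_unbox = TRUE, digits = NA)
  }, tmap_files)

  metrics_file <- "metrics.csv"
  state <- run_stage(state, "extract",
                     file.path(out_dir, c(ds_files, tmap_files)),
                     function() {
    cohort <- read_dataset(ds_dir)
    tmaps <- read_tmaps(out_dir, cohort)
    metrics <- extract_patient_metrics(tmaps, cohort)
    utils::write.csv(metrics, file.path(out_dir, metrics_file),
                     row.names = FALSE)
  }, metrics_file)

  analysis_files <- c("analysis.json", "cohort_summary.csv")
  state <- run_stage(state, "analyze",
                     file.path(out_dir, metrics_file), function() {
    metrics <- tibble::as_tibble(
      utils::read.csv(file.path(out_dir, metrics_file)))
    analyze_metrics(metrics, out_dir)
  }, analysis_files)

  predict_files <- c("cv_report.json", "predictions.csv", "roc.csv")
  state <- run_stage(state, "predict",
                     file.path(out_dir, metrics_file), function() {
    metrics <- tibble::as_tibble(
      utils::read.csv(file.path(out_dir, metrics_file)))
    predict_outcomes(metrics, out_dir, k = cfg$k_folds,
                     seed = cfg$cv_seed)
  }, predict_files)

  state <- run_stage(state, "report",
                     file.path(out_dir,
                               c(analysis_files, predict_files,
                                 metrics_file)),
                     function() {
    writeLines(render_report(out_dir), file.path(out_dir, "report.md"))
  }, "report.md")

  manifest <- state$manifest
  manifest$config_hash <- state$config_hash
  jsonlite::write_json(manifest, manifest_path(out_dir),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "executed") <-
    names(Filter(isTRUE, state$executed))
  invisible(manifest)
}

read_tmaps <- function(out_dir, cohort) {
  meta <- jsonlite::read_json(file.path(out_dir, "tmaps", "meta.json"),
                              simplifyVector = TRUE)
  mask <- cohort$brain_mask
  tmaps <- lapply(cohort$records$patient_id, function(id) {
    v <- read_volume(file.path(out_dir, "tmaps", paste0(id, "_tmap.nii")))
    arr <- v$values
    arr[!mask$inside] <- NA_real_
    structure(list(t = arr, df = meta$df, contrast = meta$contrast,
                   zero_variance = array(FALSE, cohort$config$grid$dims),
                   grid = cohort$config$grid),
              class = "t_map")
  })
  names(tmaps) <- cohort$records$patient_id
  tmaps
}

analyze_metrics <- function(metrics, out_dir) {
  def <- metrics$mean_t[metrics$deficit == 1]
  non <- metrics$mean_t[metrics$deficit == 0]
  res <- list()
  if (length(def) && length(non)) {
    res$mw_deficit <- unclass(mann_whitney_u(def, non))[
      c("method", "statistic", "p_value", "exact")]
    res$group_means <- list(deficit = mean(def), non_deficit = mean(non))
  }
  grades <- metrics[metrics$deficit == 1 & !is.na(metrics$strength_grade), ]
  if (length(unique(grades$strength_grade)) >= 2) {
    kw <- kruskal_wallis(split(grades$mean_t, grades$strength_grade))
    res$kw_grades <- unclass(kw)[c("method", "statistic", "p_value",
                                   "exact")]
    res$grade_means <- lapply(split(grades$mean_t,
                                    grades$strength_grade), mean)
  }
  fm <- metrics[metrics$has_fmri %in% c(TRUE, "TRUE", "True"), ]
  if (nrow(fm) >= 4) {
    pooled_t <- c(fm$roi_t_upper, fm$roi_t_lower)
    pooled_r <- c(fm$overlap_upper, fm$overlap_lower)
    cor_pooled <- tryCatch(pearson_r_ci(pooled_t, pooled_r),
                           error = function(e) NULL)
    res$reorg_correlation <- if (is.null(cor_pooled)) {
      list(note = "undefined (zero variance in overlap or ROI T)")
    } else {
      unclass(cor_pooled)[c("r", "ci_low", "ci_high", "p_value", "n")]
    }
    res$overlap_mean_upper <- mean(fm$overlap_upper)
    res$overlap_mean_lower <- mean(fm$overlap_lower)
    if (stats::sd(fm$roi_t_upper) > 0 && stats::sd(fm$overlap_upper) > 0) {
      res$reorg_correlation_upper <-
        unclass(pearson_r_ci(fm$roi_t_upper, fm$overlap_upper))[
          c("r", "p_value", "n")]
    }
  }
  jsonlite::write_json(res, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_tab <- if (length(unique(metrics$deficit)) == 2) {
    summarize_cohort(metrics, group_col = "deficit",
                     continuous = c("mean_t", "volume_mm3"),
                     categorical = c("side", "has_fmri"))
  } else {
    tibble::tibble(variable = "deficit", level = NA_character_,
                   group0 = NA_character_, group1 = NA_character_,
                   overall = as.character(nrow(metrics)),
                   p_value = NA_real_,
                   test = "(single outcome class: no group comparison)")
  }
  utils::write.csv(summary_tab, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  invisible(res)
}

predict_outcomes <- function(metrics, out_dir, k = 5, seed = 1) {
  if (length(unique(metrics$deficit)) < 2) {
    out <- list(skipped = "prediction stage skipped: only one outcome class")
    jsonlite::write_json(out, file.path(out_dir, "cv_report.json"),
                         auto_unbox = TRUE)
    utils::write.csv(data.frame(), file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(), file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    return(invisible(out))
  }
  k_eff <- min(k, table(metrics$deficit))
  if (k_eff < k) {
    message("reducing folds to k = ", k_eff,
            " (smallest outcome class size)")
  }
  if (k_eff < 2) {
    out <- list(skipped = "prediction stage skipped: a class has < 2 members")
    jsonlite::write_json(out, file.path(out_dir, "cv_report.json"),
                         auto_unbox = TRUE)
    utils::write.csv(data.frame(), file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(), file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    return(invisible(out))
  }
  cv <- cross_validated_report(metrics, "mean_t", "deficit", k = k_eff,
                               seed = seed)
  fit <- fit_logistic_mle(metrics$mean_t, metrics$deficit)
  or_unit <- if (fit$converged) odds_ratio_ci(fit, scale = 1) else NULL
  or_sd <- if (fit$converged) {
    odds_ratio_ci(fit, scale = stats::sd(metrics$mean_t))
  } else NULL
  out <- c(glance.cv_report(cv),
           list(folds = cv$folds,
                or_per_unit = or_unit, or_per_sd = or_sd,
                logit = list(coef = as.list(fit$coefficients),
                             se = fit$se, converged = fit$converged,
                             separated = fit$separated)))
  jsonlite::write_json(out, file.path(out_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA)
  preds <- cv$predictions
  preds$patient_id <- metrics$patient_id
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$roc, file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  invisible(out)
}

#' Render the run report
#'
#' Deterministic Markdown summary of a completed (or partial) run:
#' cohort table, group statistics, reorganization correlation, odds ratio,
#' cross-validated ROC performance, and ground-truth-versus-estimate
#' recovery for synthetic runs. Regeneration from the same artifacts is
#' byte-identical.
#'
#' @param out_dir A pipeline output directory.
#' @return Character vector of Markdown lines, invisibly; also written by
#'   the pipeline's `report` stage.
#' @export
pipeline_report <- function(out_dir) {
  lines <- render_report(out_dir)
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(lines)
}

render_report <- function(out_dir) {
  lines <- c("# Phantom PET motor-outcome pipeline report", "")
  f_an <- file.path(out_dir, "analysis.json")
  f_cv <- file.path(out_dir, "cv_report.json")
  f_sum <- file.path(out_dir, "cohort_summary.csv")
  partial <- !all(file.exists(c(f_an, f_cv, f_sum)))
  if (partial) {
    warning("incomplete run: report is partial", call. = FALSE)
    lines <- c(lines, "*Partial report: some stages have not run.*", "")
  }
  if (file.exists(f_sum)) {
    tab <- utils::read.csv(f_sum)
    lines <- c(lines, "## Cohort characteristics (by deficit group)", "",
               paste0("| ", paste(names(tab), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(tab)), collapse = "|"),
                      "|"),
               apply(tab, 1, function(r)
                 paste0("| ", paste(r, collapse = " | "), " |")),
               "")
  }
  if (file.exists(f_an)) {
    an <- jsonlite::read_json(f_an, simplifyVector = TRUE)
    lines <- c(lines, "## Group statistics", "")
    if (!is.null(an$mw_deficit)) {
      lines <- c(lines, sprintf(
        paste0("- Resected-Rolandic mean T, deficit vs non-deficit: %s p",
               " = %.4g (means %.2f vs %.2f)"),
        an$mw_deficit$method, an$mw_deficit$p_value,
        an$group_means$deficit, an$group_means$non_deficit))
    }
    if (!is.null(an$kw_grades)) {
      lines <- c(lines, sprintf(
        "- Mean T across strength grades: %s p = %.4g",
        an$kw_grades$method, an$kw_grades$p_value))
    }
    if (!is.null(an$reorg_correlation$r)) {
      rr <- an$reorg_correlation
      lines <- c(lines, sprintf(
        paste0("- Overlap rate vs classical-ROI mean T (pooled limbs): r ",
               "= %.3f (95%% CI %.3f to %.3f), p = %.4g, n = %d"),
        rr$r, rr$ci_low, rr$ci_high, rr$p_value, rr$n))
    }
    lines <- c(lines, "")
  }
  if (file.exists(f_cv)) {
    cv <- jsonlite::read_json(f_cv, simplifyVector = TRUE)
    lines <- c(lines, "## Outcome prediction", "")
    if (!is.null(cv$skipped)) {
      lines <- c(lines, paste0("- ", cv$skipped), "")
    } else {
      lines <- c(lines, sprintf(
        paste0("- %d-fold cross-validation: AUC = %.3f, sensitivity = ",
               "%.3f, specificity = %.3f (Youden threshold %.3f)"),
        cv$k, cv$auc, cv$sensitivity, cv$specificity, cv$threshold),
        if (!is.null(cv$or_per_unit)) sprintf(
          "- Odds ratio per unit T: %.3f (95%% CI %.3f to %.3f)",
          cv$or_per_unit$or, cv$or_per_unit$ci_low,
          cv$or_per_unit$ci_high),
        "")
    }
  }
  gt_path <- file.path(out_dir, "dataset", "ground_truth.json")
  if (file.exists(gt_path) && file.exists(f_cv)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    cv <- jsonlite::read_json(f_cv, simplifyVector = TRUE)
    if (is.null(cv$skipped)) {
      truth_slope <- gt$config$logit_slope
      est_slope <- cv$logit$coef$slope
      lines <- c(lines, "## Ground-truth recovery (synthetic run)", "",
                 "| quantity | truth | estimate |",
                 "|---|---|---|",
                 sprintf("| logistic slope per unit T | %.4g | %.4g |",
                         truth_slope, est_slope),
                 sprintf("| logistic intercept | %.4g | %.4g |",
                         gt$config$logit_intercept, cv$logit$coef$intercept),
                 "")
    }
  }
  lines
}
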