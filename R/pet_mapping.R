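#' Global-mean intensity normalization
#'
#' Divides a PET volume by its mean uptake inside the brain mask, removing
#' inter-subject global scale differences, so the in-mask mean of the result
#' is exactly 1.
#'
#' @param vol A `brain_volume`.
#' @param mask A `region_mask` on the same grid.
#' @return A normalized `brain_volume`.
#' @export
normalize_global_mean <- function(vol, mask) {
  check_same_grid(vol, mask, "volume and mask")
  m <- mean(vol$values[mask$inside])
  if (!is.finite(m) || m <= 0) {
    stop("normalization error: in-mask mean uptake is not positive (",
         format(m), ")", call. = FALSE)
  }
  brain_volume(vol$values / m, vol$grid)
}

#' Convert Gaussian FWHM to standard deviation
#'
#' sigma = FWHM / (2 sqrt(2 ln 2)).
#'
#' @param fwhm_mm Full width at half maximum, mm (>= 0).
#' @return Standard deviation in mm.
#' @export
#' @examples
#' fwhm_to_sigma(8)  # ~3.3973 mm
fwhm_to_sigma <- function(fwhm_mm) {
  if (any(fwhm_mm < 0)) stop("FWHM must be nonnegative", call. = FALSE)
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

# discrete 1-D Gaussian kernel, truncated at 4 sigma, normalized to sum 1
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- ceiling(4 * sigma_vox)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve a 3-D array along one axis with kernel k (zero padding)
conv_axis <- function(arr, k, axis) {
  if (length(k) == 1) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  r <- (length(k) - 1) / 2
  # band matrix K[i, j] = k[i - j + r + 1]
  idx <- outer(seq_len(n), seq_len(n), function(i, j) i - j + r + 1)
  K <- matrix(0, n, n)
  ok <- idx >= 1 & idx <= length(k)
  K[ok] <- k[idx[ok]]
  out <- K %*% m
  aperm(array(out, dim = d[perm]), order(perm))
}

#' Mask-renormalized Gaussian smoothing
#'
#' Separable Gaussian convolution (kernel truncated at 4 sigma), honouring
#' anisotropic voxel sizes, with edge renormalization: the masked image and
#' the mask are convolved separately and divided, so a constant in-mask
#' image is a fixed point and no signal bleeds in from outside the mask.
#'
#' @param vol A `brain_volume`.
#' @param mask A `region_mask` on the same grid.
#' @param fwhm_mm Smoothing kernel FWHM in mm (scalar, >= 0; 0 = identity).
#' @return A smoothed `brain_volume`, zero outside the mask.
#' @export
smooth_gaussian <- function(vol, mask, fwhm_mm) {
  check_same_grid(vol, mask, "volume and mask")
  if (fwhm_mm < 0) stop("FWHM must be nonnegative", call. = FALSE)
  if (fwhm_mm == 0) {
    v <- vol$values
    v[!mask$inside] <- 0
    return(brain_volume(v, vol$grid))
  }
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / vol$grid$voxel_size_mm
  num <- vol$values * mask$inside
  den <- mask$inside * 1
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[ax])
    num <- conv_axis(num, k, ax)
    den <- conv_axis(den, k, ax)
  }
  out <- array(0, dim = vol$grid$dims)
  out[mask$inside] <- num[mask$inside] / den[mask$inside]
  brain_volume(out, vol$grid)
}

#' Residual-SD shrinkage factor of the smoothing kernel
#'
#' The L2 norm of the discrete separable smoothing kernel: white noise of
#' standard deviation s becomes (approximately, away from mask edges) noise
#' of standard deviation `s * smoothing_noise_factor(...)` after
#' `smooth_gaussian`. Used by the phantom generator to express ground-truth
#' effects on the T-score scale.
#'
#' @param grid A `volume_grid`.
#' @param fwhm_mm Kernel FWHM in mm.
#' @return Scalar in (0, 1].
#' @export
smoothing_noise_factor <- function(grid, fwhm_mm) {
  if (fwhm_mm == 0) return(1)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / grid$voxel_size_mm
  prod(vapply(sigma_vox,
              function(s) sqrt(sum(gaussian_kernel_1d(s)^2)), 0))
}

#' Voxel-wise two-sample GLM T-map of one patient versus a control cohort
#'
#' At every in-mask voxel, fits an ordinary-least-squares linear model of
#' normalized smoothed uptake on (intercept, group indicator with patient
#' coded 1, centered age, gender) across the patient plus all controls, and
#' returns the t statistic for the group contrast (patient minus controls).
#' Hypometabolism in the patient therefore yields negative t. The map is
#' unthresholded. Voxels with zero residual variance get t = 0 and are
#' flagged.
#'
#' @param patient A normalized, smoothed `brain_volume` for the patient.
#' @param controls Named list of normalized, smoothed `brain_volume`s, names
#'   matching `covariates$subject_id`.
#' @param covariates Data frame with columns `subject_id`, `group`
#'   (`"patient"`/`"control"`), `age`, `gender` (0/1). Exactly one patient
#'   row; at least 3 control rows.
#' @param mask Analysis `region_mask`.
#' @param covariate_cols Character vector of covariate columns to adjust
#'   for; default `c("age", "gender")`. Use `character(0)` for the plain
#'   two-sample t-test.
#' @return A `t_map`: list with array `t` (`NA` outside the mask), `df`,
#'   `contrast`, logical array `zero_variance`, `grid`, `n_subjects`.
#' @export
fit_voxelwise_tmap <- function(patient, controls, covariates, mask,
                               covariate_cols = c("age", "gender")) {
  stopifnot(is.data.frame(covariates))
  covariates <- as.data.frame(covariates)
  pat_rows <- which(covariates$group == "patient")
  if (length(pat_rows) != 1) {
    stop("covariate table must contain exactly one patient row", call. = FALSE)
  }
  ctl_ids <- covariates$subject_id[covariates$group == "control"]
  if (length(ctl_ids) < 3) {
    stop("need at least 3 control rows", call. = FALSE)
  }
  missing_ctl <- setdiff(ctl_ids, names(controls))
  if (length(missing_ctl)) {
    stop("control volumes missing for: ",
         paste(missing_ctl, collapse = ", "), call. = FALSE)
  }
  for (id in ctl_ids) check_same_grid(patient, controls[[id]])
  check_same_grid(patient, mask, "volumes and mask")

  grp <- as.numeric(covariates$group == "patient")
  X <- cbind(intercept = 1, group = grp)
  if ("age" %in% covariate_cols) {
    X <- cbind(X, age = covariates$age - mean(covariates$age))
  }
  if ("gender" %in% covariate_cols) {
    X <- cbind(X, gender = as.numeric(covariates$gender))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X)
  df <- n - ncol(X)
  if (df <= 0) {
    stop("insufficient data: ", n, " subjects leave no residual degrees ",
         "of freedom for a ", ncol(X), "-column design", call. = FALSE)
  }

  inside <- which(mask$inside)
  Y <- matrix(0, nrow = n, ncol = length(inside))
  for (i in seq_len(n)) {
    vol <- if (i == pat_rows) patient else controls[[covariates$subject_id[i]]]
    Y[i, ] <- vol$values[inside]
  }

  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  rss <- colSums(res^2)
  sigma2 <- rss / df
  XtXinv <- solve(crossprod(X))
  c_var <- XtXinv[2, 2]   # contrast selects the group column
  scale_ref <- colMeans(Y^2) + 1
  zero_var <- rss <= scale_ref * 1e-18
  se <- sqrt(sigma2 * c_var)
  tvals <- ifelse(zero_var, 0, beta[2, ] / se)

  t_arr <- array(NA_real_, dim = patient$grid$dims)
  t_arr[inside] <- tvals
  zv_arr <- array(FALSE, dim = patient$grid$dims)
  zv_arr[inside] <- zero_var
  structure(
    list(t = t_arr, df = df, contrast = "patient_minus_controls",
         zero_variance = zv_arr, grid = patient$grid, n_subjects = n,
         covariates = covariate_cols),
    class = "t_map"
  )
}

#' @export
print.t_map <- function(x, ...) {
  cat(sprintf("<t_map> %s (df = %d, contrast = %s), t range [%.2f, %.2f]\n",
              paste(x$grid$dims, collapse = "x"), x$df, x$contrast,
              min(x$t, na.rm = TRUE), max(x$t, na.rm = TRUE)))
  invisible(x)
}

#' Compute normalized smoothed volumes and per-patient T-maps for a cohort
#'
#' Pipeline composition normalize -> smooth -> voxel-wise GLM: each patient
#' is contrasted against the whole control cohort (single-subject SPM-style
#' comparison), with age and gender covariates, yielding one unthresholded
#' T-map per patient.
#'
#' @param cohort A `pet_cohort` from [simulate_cohort()] or [read_dataset()].
#' @param fwhm_mm Smoothing FWHM in mm (default 8).
#' @return Named list of `t_map`s (one per patient id), with attributes
#'   `seed` and `config_hash` recording provenance.
#' @export
compute_patient_tmaps <- function(cohort, fwhm_mm = 8) {
  mask <- cohort$brain_mask
  prep <- function(vol) smooth_gaussian(normalize_global_mean(vol, mask),
                                        mask, fwhm_mm)
  ctl_prep <- lapply(cohort$controls, prep)
  covs_ctl <- cohort$covariates[cohort$covariates$group == "control", ,
                                drop = FALSE]
  tmaps <- lapply(names(cohort$patients), function(pid) {
    pat <- prep(cohort$patients[[pid]])
    covs <- rbind(covs_ctl,
                  cohort$covariates[cohort$covariates$subject_id == pid, ,
                                    drop = FALSE])
    fit_voxelwise_tmap(pat, ctl_prep, covs, mask)
  })
  names(tmaps) <- names(cohort$patients)
  attr(tmaps, "seed") <- cohort$config$seed
  attr(tmaps, "config_hash") <- config_hash(cohort$config)
  tmaps
}
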