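test_that("global-mean normalization follows the arithmetic contract", {
  g <- volume_grid(c(8, 8, 8))
  mask <- full_mask(g)
  const <- brain_volume(array(5, g$dims), g)
  expect_true(all(normalize_global_mean(const, mask)$values == 1))

  g3 <- volume_grid(c(8, 9, 8))   # voxel count divisible by 3
  v <- array(rep(c(2, 4, 6), length.out = prod(g3$dims)), g3$dims)
  out <- normalize_global_mean(brain_volume(v, g3), full_mask(g3))
  expect_equal(sort(unique(as.vector(out$values))), c(0.5, 1, 1.5))

  r <- random_volume(g, seed = 1, mean = 50, sd = 5)
  out <- normalize_global_mean(r, mask)
  expect_equal(mean(out$values[mask$inside]), 1, tolerance = 1e-12)

  zero <- brain_volume(array(0, g$dims), g)
  expect_error(normalize_global_mean(zero, mask), "not positive")
})

test_that("FWHM-to-sigma conversion is the closed form", {
  expect_equal(fwhm_to_sigma(0), 0)
  expect_equal(fwhm_to_sigma(8), 8 / (2 * sqrt(2 * log(2))))
  expect_equal(fwhm_to_sigma(8), 3.39728, tolerance = 1e-5)
  f <- c(1.3, 4.7, 11)
  expect_equal(fwhm_to_sigma(2 * f), 2 * fwhm_to_sigma(f))
  expect_error(fwhm_to_sigma(-1), "nonnegative")
})

test_that("smoothing: identity at FWHM 0, constants are fixed points", {
  g <- small_grid()
  brain <- brain_mask_for_grid(g)
  v <- random_volume(g, seed = 2)
  out0 <- smooth_gaussian(v, brain, 0)
  expect_equal(out0$values[brain$inside], v$values[brain$inside])

  const <- array(0, g$dims)
  const[brain$inside] <- 7.5
  sm <- smooth_gaussian(brain_volume(const, g), brain, 8)
  expect_equal(sm$values[brain$inside],
               rep(7.5, sum(brain$inside)), tolerance = 1e-10)
  expect_true(all(sm$values[!brain$inside] == 0))
})

test_that("impulse response equals the explicit truncated 3-D Gaussian", {
  # interior voxel far enough from every edge that the kernel support
  # (and hence the mask renormalization) never touches the boundary
  g <- volume_grid(c(30, 30, 30), c(2, 2, 2))
  mask <- full_mask(g)
  imp <- array(0, g$dims)
  ctr <- c(15, 15, 15)
  imp[ctr[1], ctr[2], ctr[3]] <- 1
  out <- smooth_gaussian(brain_volume(imp, g), mask, 8)

  # independent oracle: evaluate the normalized per-axis kernels directly
  sigma_vox <- (8 / (2 * sqrt(2 * log(2)))) / 2
  r <- ceiling(4 * sigma_vox)
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k1 <- k1 / sum(k1)
  expected <- array(0, g$dims)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    expected[ctr[1] + dx, ctr[2] + dy, ctr[3] + dz] <-
      k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1]
  }
  expect_lt(max(abs(out$values - expected)), 1e-8)
})

test_that("anisotropic voxels get per-axis kernel widths", {
  g <- volume_grid(c(16, 16, 16), c(1, 2, 4))
  mask <- full_mask(g)
  imp <- array(0, g$dims)
  imp[8, 8, 8] <- 1
  out <- smooth_gaussian(brain_volume(imp, g), mask, 8)$values
  # spread (in voxels) must shrink as voxel size grows
  sd_axis <- function(ax) {
    p <- apply(out, ax, sum)
    idx <- seq_along(p)
    sqrt(sum(p * (idx - sum(p * idx))^2))
  }
  expect_gt(sd_axis(1), sd_axis(2))
  expect_gt(sd_axis(2), sd_axis(3))
})

make_tmap_inputs <- function(seed, n_controls = 6, dims = c(8, 8, 8),
                             patient_equal = FALSE) {
  g <- volume_grid(dims)
  ids <- sprintf("c%02d", seq_len(n_controls))
  controls <- lapply(seq_len(n_controls),
                     function(i) random_volume(g, seed + i))
  names(controls) <- ids
  patient <- if (patient_equal) controls[[1]] else
    random_volume(g, seed + 999)
  covs <- withr::with_seed(seed, data.frame(
    subject_id = c(ids, "pat"),
    group = c(rep("control", n_controls), "patient"),
    age = runif(n_controls + 1, 3, 40),
    gender = rbinom(n_controls + 1, 1, 0.5)))
  list(grid = g, patient = patient, controls = controls, covs = covs,
       mask = full_mask(g))
}

test_that("voxelwise GLM t matches the textbook two-sample t without covariates", {
  inp <- make_tmap_inputs(seed = 11, n_controls = 6, dims = c(8, 8, 8))
  tm <- fit_voxelwise_tmap(inp$patient, inp$controls, inp$covs, inp$mask,
                           covariate_cols = character(0))
  expect_equal(tm$df, 7 - 2)
  Y <- sapply(inp$controls, function(v) as.vector(v$values))
  xp <- as.vector(inp$patient$values)
  for (vox in seq(1, 512, by = 19)) {
    yc <- Y[vox, ]
    sp2 <- sum((yc - mean(yc))^2) / (1 + 6 - 2)   # group-of-1 contributes 0
    t_ref <- (xp[vox] - mean(yc)) / sqrt(sp2 * (1 / 1 + 1 / 6))
    expect_equal(as.vector(tm$t)[vox], t_ref, tolerance = 1e-10)
  }
})

test_that("GLM t equals brute-force normal-equations OLS everywhere", {
  inp <- make_tmap_inputs(seed = 23, n_controls = 8, dims = c(8, 8, 8))
  tm <- fit_voxelwise_tmap(inp$patient, inp$controls, inp$covs, inp$mask)
  X <- cbind(1, as.numeric(inp$covs$group == "patient"),
             inp$covs$age - mean(inp$covs$age), inp$covs$gender)
  XtXi <- solve(t(X) %*% X)
  n <- nrow(X)
  for (vox in seq(1, 512, by = 7)) {
    y <- c(vapply(inp$controls, function(v) as.vector(v$values)[vox], 0),
           as.vector(inp$patient$values)[vox])
    # rows of X are controls then patient, matching covs order
    beta <- XtXi %*% t(X) %*% y
    resid <- y - X %*% beta
    s2 <- sum(resid^2) / (n - 4)
    t_ref <- beta[2] / sqrt(s2 * XtXi[2, 2])
    expect_equal(as.vector(tm$t)[vox], t_ref, tolerance = 1e-8)
  }
  expect_equal(tm$df, n - 4)
})

test_that("degenerate designs and data raise informative errors", {
  inp <- make_tmap_inputs(seed = 5)
  covs <- inp$covs
  covs$gender <- 0   # constant column, collinear with the intercept
  expect_error(fit_voxelwise_tmap(inp$patient, inp$controls, covs,
                                  inp$mask),
               "gender")
  inp2 <- make_tmap_inputs(seed = 6, n_controls = 3)
  inp2$covs$gender <- c(0, 1, 0, 1)   # full-rank design, but df = 0
  expect_error(fit_voxelwise_tmap(inp2$patient, inp2$controls, inp2$covs,
                                  inp2$mask),
               "insufficient data")
  covs2 <- inp$covs
  covs2$group[1] <- "patient"
  expect_error(fit_voxelwise_tmap(inp$patient, inp$controls, covs2,
                                  inp$mask),
               "exactly one patient")
})

test_that("zero-variance voxels get t = 0 and a flag, not NaN", {
  inp <- make_tmap_inputs(seed = 7, patient_equal = TRUE)
  g <- inp$grid
  const <- brain_volume(array(3, g$dims), g)
  controls <- lapply(inp$controls, function(v) const)
  covs <- inp$covs
  covs$age <- seq_len(nrow(covs))   # keep design full rank
  covs$gender <- rep(c(0, 1), length.out = nrow(covs))
  tm <- fit_voxelwise_tmap(const, controls, covs, inp$mask)
  expect_true(all(tm$t[inp$mask$inside] == 0))
  expect_true(all(tm$zero_variance[inp$mask$inside]))
})

test_that("no finite t escapes the analysis mask", {
  inp <- make_tmap_inputs(seed = 9)
  mask <- region_mask(array(c(TRUE, FALSE), inp$grid$dims), inp$grid)
  tm <- fit_voxelwise_tmap(inp$patient, inp$controls, inp$covs, mask)
  expect_true(all(is.na(tm$t[!mask$inside])))
  expect_true(all(is.finite(tm$t[mask$inside])))
})

test_that("the T-map is invariant to global rescaling of any input", {
  cohort <- fixture_cohort()
  tm1 <- compute_patient_tmaps(cohort, fwhm_mm = 8)[[1]]
  cohort2 <- cohort
  cohort2$patients[[1]] <-
    brain_volume(3.7 * cohort$patients[[1]]$values, cohort$config$grid)
  cohort2$controls[[2]] <-
    brain_volume(0.25 * cohort$controls[[2]]$values, cohort$config$grid)
  tm2 <- compute_patient_tmaps(cohort2, fwhm_mm = 8)[[1]]
  expect_equal(tm1$t, tm2$t, tolerance = 1e-9)
})

test_that("tmap pipeline is deterministic and detects lesion effects", {
  cfg <- small_cfg(seed = 55, n_controls = 10, n_patients = 8,
                   lesion_effect = 0.35)
  cohort <- simulate_cohort(cfg)
  tmaps <- compute_patient_tmaps(cohort, fwhm_mm = 8)
  tmaps2 <- compute_patient_tmaps(cohort, fwhm_mm = 8)
  expect_identical(tmaps[[3]]$t, tmaps2[[3]]$t)
  in_lesion_t <- vapply(names(tmaps), function(id) {
    mean(tmaps[[id]]$t[cohort$lesions[[id]]$inside])
  }, 0)
  # hypometabolic lesions must show strongly negative t
  expect_true(mean(in_lesion_t) < -2)
})
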