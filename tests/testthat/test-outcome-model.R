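test_that("logistic MLE matches glm and a grid-search oracle", {
  # small printed fixture, n = 12
  x <- c(-2.1, -1.4, -0.8, -0.6, -0.2, 0.1, 0.3, 0.7, 1.1, 1.6, 2.0, 2.4)
  y <- c(0, 0, 0, 1, 0, 0, 1, 1, 0, 1, 1, 1)
  fit <- fit_logistic_mle(x, y)
  expect_true(fit$converged)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-7)
  expect_equal(fit$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)

  # brute-force likelihood grid around the MLE
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  b0s <- seq(fit$coefficients[1] - 0.5, fit$coefficients[1] + 0.5,
             length.out = 201)
  b1s <- seq(fit$coefficients[2] - 0.5, fit$coefficients[2] + 0.5,
             length.out = 201)
  grid_ll <- outer(b0s, b1s, Vectorize(ll))
  best <- arrayInd(which.max(grid_ll), dim(grid_ll))
  expect_lt(abs(b0s[best[1]] - fit$coefficients[1]), 1e-2 + 0.0051)
  expect_lt(abs(b1s[best[2]] - fit$coefficients[2]), 1e-2 + 0.0051)
})

test_that("a symmetric design gives a zero intercept", {
  x <- c(-2, -1, 1, 2, -2, -1, 1, 2)
  y <- c(0, 0, 1, 1, 1, 0, 1, 0)
  # classes balance at every |x|; the configuration is antisymmetric
  fit <- fit_logistic_mle(x, y)
  expect_lt(abs(fit$coefficients[["intercept"]]), 1e-6)
})

test_that("a null slope is recovered as approximately zero", {
  withr::with_seed(101, {
    x <- rnorm(500)
    y <- rbinom(500, 1, 0.5)
  })
  fit <- fit_logistic_mle(x, y)
  expect_lt(abs(fit$coefficients[["slope"]]), 0.2)
})

test_that("separation is flagged as a distinct condition", {
  x <- c(-3, -2, -1, 1, 2, 3, -1.5, 1.5)
  y <- as.numeric(x > 0)
  fit <- fit_logistic_mle(x, y)
  expect_true(fit$separated)
  expect_false(fit$converged)
  expect_error(odds_ratio_ci(fit), "converged")
})

test_that("degenerate outcomes are rejected", {
  expect_error(fit_logistic_mle(rnorm(10), rep(1, 10)), "one class")
  expect_error(fit_logistic_mle(rnorm(4), c(0, 1, 0, 1)), "at least 6")
  expect_error(fit_logistic_mle(rnorm(6), c(0, 1, 0, 1, 2, 0)), "0/1")
})

test_that("slope bias shrinks as the sample grows", {
  est <- function(n, reps = 20) {
    mean(vapply(seq_len(reps), function(i) {
      withr::with_seed(1000 * n + i, {
        x <- rnorm(n)
        y <- rbinom(n, 1, plogis(0.2 + 0.8 * x))
      })
      fit_logistic_mle(x, y)$coefficients[["slope"]]
    }, 0))
  }
  bias <- abs(vapply(c(60, 200, 1000), est, 0) - 0.8)
  expect_lt(bias[3], 0.1)
  expect_lt(bias[3], bias[1] + 0.05)
})

test_that("odds ratio and Wald CI follow the closed form", {
  x <- c(-2.1, -1.4, -0.8, -0.6, -0.2, 0.1, 0.3, 0.7, 1.1, 1.6, 2.0, 2.4)
  y <- c(0, 0, 0, 1, 0, 0, 1, 1, 0, 1, 1, 1)
  fit <- fit_logistic_mle(x, y)
  or <- odds_ratio_ci(fit)
  b <- fit$coefficients[["slope"]]
  expect_equal(or$or, exp(b))
  expect_equal(or$ci_low, exp(b - qnorm(0.975) * fit$se[2]))
  expect_equal(or$ci_high, exp(b + qnorm(0.975) * fit$se[2]))
  # per-SD scaling
  or_sd <- odds_ratio_ci(fit, scale = sd(x))
  expect_equal(or_sd$or, exp(b * sd(x)))
  expect_true(or$ci_low <= or$or && or$or <= or$ci_high)
})

test_that("a truly null slope yields OR CIs containing 1", {
  withr::with_seed(55, {
    x <- rnorm(300)
    y <- rbinom(300, 1, 0.4)
  })
  or <- odds_ratio_ci(fit_logistic_mle(x, y))
  expect_true(or$ci_low <= 1 && 1 <= or$ci_high)
})

test_that("stratified folds balance classes and are deterministic", {
  y <- rep(c(1, 0), c(5, 5))
  f <- stratified_kfold(y, k = 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  for (i in 1:5) {
    expect_equal(sum(f == i & y == 1), 1)
    expect_equal(sum(f == i & y == 0), 1)
  }
  expect_identical(f, stratified_kfold(y, k = 5, seed = 3))
  expect_false(identical(f, stratified_kfold(y, k = 5, seed = 4)))

  # the study's 26/36 split: fold sizes 13,13,12,12,12, 5-6 deficits each
  y62 <- rep(c(1, 0), c(26, 36))
  f62 <- stratified_kfold(y62, k = 5, seed = 11)
  sizes <- as.vector(table(f62))
  expect_equal(sort(sizes, decreasing = TRUE), c(13, 13, 12, 12, 12))
  def_counts <- vapply(1:5, function(i) sum(f62 == i & y62 == 1), 0)
  expect_true(all(def_counts %in% 5:6))

  expect_error(stratified_kfold(rep(c(1, 0), c(3, 20)), k = 5, seed = 1),
               "stratification error")
})

test_that("rank AUC equals the trapezoidal ROC integral, ties included", {
  trapezoid_auc <- function(scores, labels) {
    roc <- roc_curve(scores, labels)
    fpr <- 1 - roc$specificity
    tpr <- roc$sensitivity
    o <- order(fpr, tpr)
    sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
  }
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- 40
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      scores <- round(rnorm(n, labels), 1)   # rounding induces ties
      expect_equal(auc_rank(scores, labels),
                   trapezoid_auc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly monotone transforms", {
  withr::with_seed(18, {
    scores <- rnorm(50)
    labels <- rbinom(50, 1, plogis(scores))
  })
  a <- auc_rank(scores, labels)
  expect_equal(auc_rank(plogis(3 * scores - 1), labels), a)
  expect_equal(auc_rank(exp(scores), labels), a)
})

test_that("cross-validation is deterministic and nails separable data", {
  d <- tibble::tibble(mean_t = c(seq(-10, -6, length.out = 10),
                                 seq(2, 6, length.out = 10)),
                      deficit = rep(c(0, 1), each = 10))
  cv <- cross_validated_report(d, k = 5, seed = 2)
  expect_equal(cv$auc, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  cv2 <- cross_validated_report(d, k = 5, seed = 2)
  expect_identical(glance(cv), glance(cv2))
  expect_equal(nrow(tidy(cv)), 20)
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("cross-validation recovers the generator's operating point", {
  withr::with_seed(77, {
    x <- rnorm(400, -15, 6)
    y <- rbinom(400, 1, plogis(4.01 + 0.29 * x))
  })
  cv <- cross_validated_report(tibble::tibble(mean_t = x, deficit = y),
                               k = 5, seed = 5)
  expect_gt(cv$auc, 0.7)
  expect_true(cv$sensitivity + cv$specificity > 1.2)
  fit <- fit_logistic_mle(x, y)
  expect_equal(fit$coefficients[["slope"]], 0.29, tolerance = 0.35)
})

test_that("pooled CV AUC tracks the generator's analytic AUC", {
  # analytic AUC implied by the ground-truth probabilities: the chance a
  # random (weighted) deficit patient outranks a non-deficit one
  analytic_auc <- function(gt) {
    p <- gt$deficit_prob
    t <- gt$true_mean_t
    o <- order(t)
    ps <- p[o]
    den <- sum(p) * sum(1 - p) - sum(p * (1 - p))
    sum(ps[-1] * cumsum(1 - ps)[-length(ps)]) / den
  }
  diffs <- vapply(1:5, function(seed) {
    cfg <- sim_config(seed = seed, n_controls = 16, n_patients = 62,
                      grid = volume_grid(c(24, 28, 24)))
    cohort <- simulate_cohort(cfg)
    tmaps <- compute_patient_tmaps(cohort, fwhm_mm = 8)
    metrics <- extract_patient_metrics(tmaps, cohort)
    cv <- cross_validated_report(metrics, k = 5, seed = seed)
    cv$auc - analytic_auc(cohort$ground_truth)
  }, 0)
  expect_lt(abs(mean(diffs)), 0.08)
})

test_that("rank AUC agrees with an independent ROC library", {
  withr::with_seed(29, {
    scores <- round(rnorm(80), 1)
    labels <- rbinom(80, 1, plogis(scores))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-12)
})
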