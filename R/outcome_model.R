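#' Univariate logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `P(y = 1) = plogis(beta0 + beta1 * x)`.
#' Convergence when the maximum absolute score (gradient) falls below 1e-8,
#' capped at 100 iterations. Complete/quasi-complete separation — diverging
#' coefficients with a non-vanishing gradient — is detected and reported as
#' a distinct condition: estimates are returned capped but flagged unusable
#' for Wald inference.
#'
#' @param x Numeric predictor.
#' @param y 0/1 outcome; both classes must be present, n >= 6.
#' @param max_iter,tol IRLS controls.
#' @return A `logit_fit`: coefficients, standard errors, 2x2 covariance,
#'   `converged`/`separated` flags, `loglik`, `n`.
#' @export
fit_logistic_mle <- function(x, y, max_iter = 100, tol = 1e-8) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: only one class present", call. = FALSE)
  }
  if (length(y) < 6) stop("need at least 6 observations", call. = FALSE)
  X <- cbind(1, x)
  beta <- c(stats::qlogis(mean(y)), 0)
  converged <- FALSE
  separated <- FALSE
  # coefficients large enough to pin every fitted probability at 0/1
  # signal (quasi-)separation rather than a finite MLE
  eta_cap <- 30
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    if (all(abs(y - p) < 1e-6) || max(abs(eta)) > 4 * eta_cap) {
      separated <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-12)
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) {
      separated <- TRUE
      break
    }
    beta <- beta + step
  }
  if (!converged && !separated) {
    separated <- max(abs(drop(X %*% beta))) > eta_cap
  }
  eta <- drop(X %*% beta)
  p <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  loglik <- sum(y * log(p) + (1 - y) * log(1 - p))
  vcov <- matrix(NA_real_, 2, 2)
  se <- c(NA_real_, NA_real_)
  if (converged) {
    w <- p * (1 - p)
    vcov <- unname(solve(crossprod(X, X * w)))
    se <- unname(sqrt(diag(vcov)))
  }
  beta <- unname(beta)
  structure(
    list(coefficients = c(intercept = beta[1], slope = beta[2]),
         se = se, vcov = vcov, converged = converged,
         separated = separated, loglik = loglik, n = length(y),
         x = x, y = y),
    class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf(
    "<logit_fit> n = %d, beta0 = %.4g, beta1 = %.4g%s\n", x$n,
    x$coefficients[1], x$coefficients[2],
    if (x$separated) " [SEPARATED: Wald inference unusable]"
    else if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @rdname fit_logistic_mle
#' @param object,x,... A `logit_fit` (broom-style accessors).
#' @export
tidy.logit_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = x$se,
    statistic = unname(x$coefficients) / x$se,
    p.value = 2 * stats::pnorm(-abs(unname(x$coefficients) / x$se)))
}

#' @rdname fit_logistic_mle
#' @export
glance.logit_fit <- function(x, ...) {
  tibble::tibble(n = x$n, logLik = x$loglik, converged = x$converged,
                 separated = x$separated)
}

#' Odds ratio with Wald confidence interval
#'
#' `OR = exp(beta1 * scale)`; Wald CI `exp((beta1 +/- z * SE) * scale)`.
#' `scale = 1` gives the per-unit-predictor OR; pass the predictor's SD for
#' a per-SD OR.
#'
#' @param model A converged `logit_fit`.
#' @param scale Predictor-units multiplier (default 1).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `or`, `ci_low`, `ci_high`, `scale`, `level`.
#' @export
odds_ratio_ci <- function(model, scale = 1, level = 0.95) {
  if (!inherits(model, "logit_fit") || !model$converged) {
    stop("odds_ratio_ci requires a converged logit_fit", call. = FALSE)
  }
  b <- model$coefficients[["slope"]]
  se <- model$se[2]
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- exp((b - z * se) * scale)
  hi <- exp((b + z * se) * scale)
  tibble::tibble(or = exp(b * scale), ci_low = min(lo, hi),
                 ci_high = max(lo, hi), scale = scale, level = level)
}

#' Stratified k-fold assignment
#'
#' Deterministic given the seed: within each class, subjects are shuffled
#' and dealt so that every fold's class count differs from exact
#' proportionality by at most one; the per-class remainders go to the folds
#' with the smallest running totals, keeping overall fold sizes within one
#' of each other.
#'
#' @param y Class labels (any type, 2+ classes allowed).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), same length as `y`.
#' @export
stratified_kfold <- function(y, k = 5, seed = 1) {
  classes <- unique(y)
  counts <- table(factor(y, classes))
  if (any(counts < k)) {
    stop("stratification error: every class needs at least k = ", k,
         " members", call. = FALSE)
  }
  folds <- integer(length(y))
  totals <- numeric(k)
  # larger classes first so remainders interleave across folds
  for (cl in classes[order(-counts)]) {
    idx <- which(y == cl)
    idx <- with_substream(seed, paste0("fold_", cl),
                          idx[sample.int(length(idx))])
    base <- length(idx) %/% k
    rem <- length(idx) %% k
    extra_folds <- order(totals, seq_len(k))[seq_len(rem)]
    sizes <- rep(base, k)
    sizes[extra_folds] <- sizes[extra_folds] + 1L
    fold_of <- rep(seq_len(k), times = sizes)
    folds[idx] <- fold_of
    totals <- totals + sizes
  }
  folds
}

#' AUC by the rank (Mann-Whitney) formulation
#'
#' `AUC = (sum of midranks of positive scores - n1(n1+1)/2) / (n1 n0)`;
#' ties handled by midranks, equal to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric predictions (higher = more positive).
#' @param labels 0/1 outcomes.
#' @return Scalar AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' One row per candidate threshold (each unique score, plus sentinels),
#' classifying `score >= threshold` as positive.
#'
#' @param scores,labels As [auc_rank()].
#' @return Tibble: `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n0, 0)
  tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Cross-validated logistic prediction report
#'
#' Five-fold (by default) stratified cross-validation of the univariate
#' logistic model: each fold is predicted by a model fit on the other
#' folds, the out-of-fold probabilities are pooled, and AUC (rank
#' formulation), sensitivity and specificity are computed on the pooled
#' predictions. The operating threshold maximizes Youden's J on the pooled
#' ROC (ties broken toward higher sensitivity); sensitivity/specificity at
#' a fixed 0.5 probability cut are reported alongside.
#'
#' @param data Data frame holding predictor and outcome columns.
#' @param predictor,outcome Column names (defaults `"mean_t"`,
#'   `"deficit"`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A `cv_report`: `k`, `seed`, `folds`, `predictions` tibble,
#'   `auc`, `sensitivity`, `specificity`, `threshold`, `sens_at_05`,
#'   `spec_at_05`, `per_fold` tibble.
#' @export
cross_validated_report <- function(data, predictor = "mean_t",
                                   outcome = "deficit", k = 5, seed = 1) {
  stopifnot(predictor %in% names(data), outcome %in% names(data))
  x <- data[[predictor]]
  y <- as.numeric(data[[outcome]])
  folds <- NULL
  for (attempt in 0:9) {
    f <- stratified_kfold(y, k = k, seed = seed + attempt)
    train_ok <- vapply(seq_len(k), function(i) {
      length(unique(y[f != i])) == 2
    }, TRUE)
    if (all(train_ok)) {
      folds <- f
      if (attempt > 0) {
        message("refolded with seed offset ", attempt,
                " to keep both classes in every training set")
      }
      break
    }
  }
  if (is.null(folds)) {
    stop("could not build folds with both classes in every training set",
         call. = FALSE)
  }
  prob <- numeric(length(y))
  for (i in seq_len(k)) {
    fit <- fit_logistic_mle(x[folds != i], y[folds != i])
    b <- fit$coefficients
    prob[folds == i] <- stats::plogis(b[1] + b[2] * x[folds == i])
  }
  roc <- roc_curve(prob, y)
  auc <- auc_rank(prob, y)
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(roc$sensitivity[best])]
  per_fold <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
    yi <- y[folds == i]
    pi <- prob[folds == i]
    tibble::tibble(
      fold = i, n = length(yi), n_deficit = sum(yi),
      auc = if (length(unique(yi)) == 2) auc_rank(pi, yi) else NA_real_)
  }))
  structure(
    list(k = k, seed = seed, folds = folds,
         predictions = tibble::tibble(
           id = seq_along(y), fold = folds, prob = prob, y = y),
         roc = roc, auc = auc,
         threshold = roc$threshold[best],
         sensitivity = roc$sensitivity[best],
         specificity = roc$specificity[best],
         sens_at_05 = sum(prob >= 0.5 & y == 1) / sum(y == 1),
         spec_at_05 = sum(prob < 0.5 & y == 0) / sum(y == 0),
         per_fold = per_fold),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    paste0("<cv_report> %d-fold (seed %d): AUC = %.3f, sensitivity = %.3f,",
           " specificity = %.3f at threshold %.3f\n"),
    x$k, x$seed, x$auc, x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' @rdname cross_validated_report
#' @param x,object,... A `cv_report` (broom-style accessors / plotting).
#' @export
tidy.cv_report <- function(x, ...) x$predictions

#' @rdname cross_validated_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(k = x$k, seed = x$seed, auc = x$auc,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 threshold = x$threshold, sens_at_05 = x$sens_at_05,
                 spec_at_05 = x$spec_at_05)
}

#' @rdname cross_validated_report
#' @export
autoplot.cv_report <- function(object, ...) {
  roc <- object$roc
  ggplot2::ggplot(roc,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Pooled %d-fold CV ROC (AUC = %.2f)", object$k,
                      object$auc)) +
    ggplot2::theme_minimal()
}
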