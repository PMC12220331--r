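# All tests here are implemented from first principles (midranks,
# hypergeometric enumeration, Fisher z) and cross-checked against
# independent implementations in the test suite.

test_result <- function(method, statistic, p_value, n, exact,
                        details = list()) {
  structure(
    c(list(method = method, statistic = statistic,
           p_value = min(max(p_value, 0), 1), n = n, exact = exact),
      details),
    class = "pet_test_result")
}

#' @export
print.pet_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n = %s)\n", x$method,
              x$statistic, x$p_value,
              if (x$exact) "exact" else "approximate",
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' @export
tidy.pet_test_result <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p.value = x$p_value, exact = x$exact)
}

# exact null distribution of the Mann-Whitney U statistic: number of ways
# to obtain each U with group sizes m, n (classic DP over the Gaussian
# binomial recurrence)
mwu_exact_counts <- function(m, n) {
  counts <- c(1, rep(0, m * n))   # counts[u + 1], polynomial in q
  # product_{i=1..m} (1 - q^(n+i)) / (1 - q^i), built incrementally
  for (i in seq_len(m)) {
    # multiply by 1/(1 - q^i): prefix sums with stride i
    for (u in seq_len(m * n - i + 1)) {
      counts[u + i] <- counts[u + i] + counts[u]
    }
    # multiply by (1 - q^(n+i))
    for (u in rev(seq_len(m * n - n - i + 1))) {
      counts[u + n + i] <- counts[u + n + i] - counts[u]
    }
  }
  counts
}

#' Mann-Whitney U test (midranks, exact or corrected normal approximation)
#'
#' U is computed from midranks. The two-sided p-value comes from exact
#' enumeration of the null distribution when `n_x * n_y <= 400` and there
#' are no ties, and otherwise from the normal approximation with tie
#' correction and continuity correction. The `exact` flag records which
#' path ran.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param method `"auto"` (exact when feasible), `"exact"` (requires no
#'   ties), or `"approx"`.
#' @param continuity Apply the continuity correction on the approximate
#'   path (default TRUE).
#' @return A `pet_test_result` with `statistic` = U of the first sample.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 by enumeration
mann_whitney_u <- function(x, y, method = c("auto", "exact", "approx"),
                           continuity = TRUE) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (method == "exact" && ties) {
    stop("exact Mann-Whitney p-value requires tie-free data",
         call. = FALSE)
  }
  use_exact <- method == "exact" ||
    (method == "auto" && !ties && m * n <= 400)
  if (use_exact) {
    counts <- mwu_exact_counts(m, n)
    probs <- counts / sum(counts)
    mu <- m * n / 2
    # distribution is symmetric about mu: two-sided tail by distance
    p <- sum(probs[abs(seq(0, m * n) - mu) >= abs(u - mu) - 1e-9])
    return(test_result("Mann-Whitney U (exact)", u, p, c(m, n), TRUE,
                       list(u = u)))
  }
  mu <- m * n / 2
  tie_tab <- table(c(x, y))
  N <- m + n
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(test_result("Mann-Whitney U (normal approx.)", u, 1,
                       c(m, n), FALSE))
  }
  cc <- if (continuity) 0.5 else 0
  z <- (u - mu - sign(u - mu) * cc) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  test_result("Mann-Whitney U (normal approx.)", u, p, c(m, n), FALSE,
              list(u = u, z = z))
}

#' Kruskal-Wallis rank test
#'
#' H with tie correction, referred to a chi-square with k-1 degrees of
#' freedom; for tiny problems (total n <= 10) an exact permutation p-value
#' over all group assignments can be requested.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @param exact Logical; full permutation enumeration (total n <= 10 only).
#' @return A `pet_test_result` with `statistic` = H.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need at least 2 nonempty groups", call. = FALSE)
  }
  ns <- lengths(groups)
  N <- sum(ns)
  vals <- unlist(groups)
  r <- rank(vals)
  idx <- rep(seq_along(groups), ns)
  h_of <- function(r) {
    rsums <- tapply(r, idx, sum)
    12 / (N * (N + 1)) * sum(rsums^2 / ns) - 3 * (N + 1)
  }
  h <- h_of(r)
  tie_tab <- table(vals)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr > 0) h <- h / corr
  df <- length(groups) - 1
  if (exact) {
    if (N > 10) stop("exact Kruskal-Wallis only for total n <= 10",
                     call. = FALSE)
    p <- kw_exact_p(r, ns, h, corr)
    return(test_result("Kruskal-Wallis (exact)", h, p, ns, TRUE,
                       list(df = df)))
  }
  p <- stats::pchisq(h, df, lower.tail = FALSE)
  test_result("Kruskal-Wallis (chi-square approx.)", h, p, ns, FALSE,
              list(df = df))
}

# exact Kruskal-Wallis p by enumerating all distinct group assignments
kw_exact_p <- function(r, ns, h_obs, corr) {
  N <- length(r)
  total <- 0L
  ge <- 0L
  rec <- function(remaining, gi, rsums) {
    if (gi == length(ns)) {
      rsums <- c(rsums, sum(r[remaining]))
      h <- 12 / (N * (N + 1)) * sum(rsums^2 / ns) - 3 * (N + 1)
      if (corr > 0) h <- h / corr
      total <<- total + 1L
      if (h >= h_obs - 1e-9) ge <<- ge + 1L
      return(invisible())
    }
    cmb <- utils::combn(remaining, ns[gi])
    for (j in seq_len(ncol(cmb))) {
      rec(setdiff(remaining, cmb[, j]), gi + 1L,
          c(rsums, sum(r[cmb[, j]])))
    }
    invisible()
  }
  rec(seq_len(N), 1L, numeric(0))
  ge / total
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass rule: with margins fixed, sum the
#' hypergeometric probabilities of every table whose probability does not
#' exceed that of the observed table (within a 1e-12 relative slack).
#'
#' @param tab 2x2 matrix of nonnegative counts (rows = groups,
#'   columns = categories).
#' @return A `pet_test_result` with `statistic` = the odds-ratio estimate
#'   `ad/bc` (Inf/NaN allowed for degenerate margins).
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 21, 10, 26), 2))$p_value  # ~0.55
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  or <- (a * d) / (b * c_)
  test_result("Fisher exact", or, p, c(m, n), TRUE,
              list(table = tab))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' r by the product-moment formula; two-sided p from
#' `t = r * sqrt((n-2)/(1-r^2))` against t(n-2); CI by the Fisher
#' z-transform.
#'
#' @param x,y Numeric vectors of equal length (n >= 4, nonzero variance).
#' @param level Confidence level (default 0.95).
#' @return A `correlation_result`: list with `r`, `ci_low`, `ci_high`,
#'   `p_value`, `n`.
#' @export
pearson_r_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop("undefined correlation: zero variance in x or y", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  z <- atanh(r)
  zse <- 1 / sqrt(n - 3)
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(r = r, ci_low = tanh(z - zcrit * zse),
         ci_high = tanh(z + zcrit * zse), p_value = p, n = n,
         level = level),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (%d%% CI %.3f-%.3f), p = %.3g, n = %d\n",
              x$r, round(100 * x$level), x$ci_low, x$ci_high, x$p_value,
              x$n))
  invisible(x)
}

#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(estimate = x$r, conf.low = x$ci_low,
                 conf.high = x$ci_high, p.value = x$p_value, n = x$n)
}

#' Clinical-characteristics summary table by outcome group
#'
#' For each requested variable, produces the two group summaries
#' (mean +/- SD for continuous variables, count and half-up one-decimal
#' percentage for binary categorical ones) and the matching test p-value:
#' Mann-Whitney U for continuous, Fisher's exact for two-level categorical.
#' Categorical variables with more than two levels get their counts but an
#' NA p-value.
#'
#' @param records Data frame of patient records.
#' @param group_col Name of the binary grouping column (default
#'   `"deficit"`).
#' @param continuous,categorical Character vectors of column names to
#'   summarize; defaults cover the phantom's record schema.
#' @return A tibble with one row per variable (or variable level):
#'   `variable`, `level`, `group0`, `group1`, `overall`, `p_value`, `test`.
#' @export
summarize_cohort <- function(records,
                             group_col = "deficit",
                             continuous = intersect(c("age", "mean_t"),
                                                    names(records)),
                             categorical = intersect(
                               c("gender", "side", "has_fmri"),
                               names(records))) {
  stopifnot(group_col %in% names(records))
  g <- records[[group_col]]
  glev <- sort(unique(g))
  if (length(glev) != 2) {
    stop("grouping column must have exactly two levels", call. = FALSE)
  }
  rows <- list()
  for (v in continuous) {
    vals <- records[[v]]
    if (!is.numeric(vals)) stop("variable '", v, "' is not numeric",
                                call. = FALSE)
    x0 <- vals[g == glev[1]]; x1 <- vals[g == glev[2]]
    p <- mann_whitney_u(x0, x1)$p_value
    fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, level = NA_character_, group0 = fmt(x0),
      group1 = fmt(x1), overall = fmt(vals), p_value = p,
      test = "Mann-Whitney U")
  }
  for (v in categorical) {
    vals <- records[[v]]
    if (is.numeric(vals) && length(unique(vals)) > 8) {
      stop("variable '", v, "' looks continuous, not categorical",
           call. = FALSE)
    }
    levs <- sort(unique(vals))
    tab <- table(factor(g, glev), factor(vals, levs))
    p <- if (length(levs) == 2) fisher_exact(tab)$p_value else NA_real_
    for (lv in levs) {
      n0 <- sum(vals == lv & g == glev[1])
      n1 <- sum(vals == lv & g == glev[2])
      nt <- n0 + n1
      fmt <- function(cnt, tot) sprintf("%d (%.1f%%)", cnt, pct(cnt, tot))
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, level = as.character(lv),
        group0 = fmt(n0, sum(g == glev[1])),
        group1 = fmt(n1, sum(g == glev[2])),
        overall = fmt(nt, length(g)),
        p_value = if (lv == levs[1]) p else NA_real_,
        test = if (length(levs) == 2) "Fisher exact" else
          "(not tested: >2 levels)")
    }
  }
  dplyr::bind_rows(rows)
}
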