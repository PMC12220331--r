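test_that("Mann-Whitney exact path reproduces full enumeration", {
  # complete separation 3 vs 3: only 2 of the 20 assignments are as extreme
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)

  # independent oracle: enumerate every assignment of the pooled sample
  withr::with_seed(14, {
    for (rep in 1:5) {
      x <- rnorm(5)
      y <- rnorm(6)
      res <- mann_whitney_u(x, y)
      pooled <- c(x, y)
      r <- rank(pooled)
      u_obs <- sum(r[1:5]) - 5 * 6 / 2
      mu <- 5 * 6 / 2
      combs <- combn(11, 5)
      us <- apply(combs, 2, function(ix) sum(r[ix]) - 5 * 6 / 2)
      p_ref <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
      expect_equal(res$p_value, p_ref, tolerance = 1e-12)
    }
  })
})

test_that("identical samples give a null Mann-Whitney result", {
  x <- c(3, 1, 4, 1, 5)
  expect_gte(mann_whitney_u(x, x)$p_value, 0.99)
})

test_that("approximate path tracks the exact path on small samples", {
  withr::with_seed(20, {
    for (rep in 1:20) {
      x <- rnorm(8)
      y <- rnorm(8)
      p_exact <- mann_whitney_u(x, y, method = "exact")$p_value
      p_approx <- mann_whitney_u(x, y, method = "approx")$p_value
      expect_lt(abs(p_exact - p_approx), 0.02)
    }
  })
})

test_that("Mann-Whitney agrees with an independent implementation", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      x <- rnorm(7)
      y <- rnorm(9)
      expect_equal(mann_whitney_u(x, y)$p_value,
                   wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-10)
      # tied data exercise the corrected normal approximation
      xt <- sample(1:4, 15, TRUE)
      yt <- sample(1:4, 12, TRUE)
      expect_equal(mann_whitney_u(xt, yt)$p_value,
                   wilcox.test(xt, yt, exact = FALSE,
                               correct = TRUE)$p.value,
                   tolerance = 1e-10)
    }
  })
})

test_that("Kruskal-Wallis degenerate and hand-computed cases", {
  expect_error(kruskal_wallis(list(c(1, 2))), "at least 2")
  res <- kruskal_wallis(list(rep(2, 4), rep(2, 5), rep(2, 3)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # hand-rank oracle, 3 groups of 3, values 1..9 so ranks are the values
  groups <- list(c(1, 4, 9), c(2, 5, 8), c(3, 6, 7))
  rsums <- c(1 + 4 + 9, 2 + 5 + 8, 3 + 6 + 7)
  h_ref <- 12 / (9 * 10) * sum(rsums^2 / 3) - 3 * 10
  res <- kruskal_wallis(groups)
  expect_equal(res$statistic, h_ref, tolerance = 1e-12)
  expect_equal(res$p_value,
               pchisq(h_ref, df = 2, lower.tail = FALSE))
})

test_that("Kruskal-Wallis matches kruskal.test with ties", {
  withr::with_seed(7, {
    g <- list(sample(1:5, 8, TRUE), sample(1:5, 6, TRUE),
              sample(1:5, 7, TRUE))
  })
  res <- kruskal_wallis(g)
  ref <- kruskal.test(g)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis is the squared Mann-Whitney z", {
  withr::with_seed(8, {
    x <- rnorm(12)
    y <- rnorm(15) + 0.5
  })
  p_kw <- kruskal_wallis(list(x, y))$p_value
  p_mw <- mann_whitney_u(x, y, method = "approx",
                         continuity = FALSE)$p_value
  expect_lt(abs(p_kw - p_mw), 0.01)
})

test_that("exact Kruskal-Wallis agrees with chi-square on a tiny case", {
  groups <- list(c(0.3, 1.2), c(2.4, 0.1), c(5.5, 0.9))
  ex <- kruskal_wallis(groups, exact = TRUE)
  ap <- kruskal_wallis(groups)
  expect_true(ex$exact)
  expect_equal(ex$statistic, ap$statistic)
  expect_true(ex$p_value >= 0 && ex$p_value <= 1)
})

test_that("Fisher's exact test reproduces the published tables", {
  # deficit incidence, fMRI (5/15) vs no-fMRI (21/47) subgroups
  p1 <- fisher_exact(matrix(c(5, 21, 10, 26), 2))$p_value
  expect_equal(round(p1, 2), 0.55)
  # gender by outcome group: 17/19 vs 12/14
  p2 <- fisher_exact(matrix(c(17, 12, 19, 14), 2))$p_value
  expect_gt(p2, 0.99)
  # degenerate margins
  expect_equal(fisher_exact(matrix(c(0, 5, 0, 7), 2))$p_value, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("Fisher p is invariant under row swap and double swap", {
  tab <- matrix(c(3, 9, 7, 2), 2)
  p <- fisher_exact(tab)$p_value
  expect_equal(fisher_exact(tab[2:1, ])$p_value, p, tolerance = 1e-12)
  expect_equal(fisher_exact(tab[2:1, 2:1])$p_value, p, tolerance = 1e-12)
})

test_that("Fisher matches fisher.test across random tables", {
  withr::with_seed(9, {
    for (rep in 1:25) {
      tab <- matrix(rpois(4, 8), 2)
      if (sum(tab) == 0) next
      expect_equal(fisher_exact(tab)$p_value,
                   fisher.test(tab)$p.value, tolerance = 1e-7)
    }
  })
})

test_that("Pearson correlation handles exact linearity and the z CI", {
  x <- seq_len(20)
  res <- pearson_r_ci(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p_value, 1e-12)

  # data constructed with sample r exactly 0.5, n = 30
  n <- 30
  withr::with_seed(3, e <- rnorm(n))
  x <- scale(seq_len(n))[, 1]
  e <- scale(residuals(lm(e ~ x)))[, 1]
  y <- 0.5 * x + sqrt(1 - 0.25) * e
  res <- pearson_r_ci(x, y)
  expect_equal(res$r, 0.5, tolerance = 1e-10)
  # closed-form Fisher-z interval evaluated independently
  expect_equal(res$ci_low, tanh(atanh(0.5) - qnorm(0.975) / sqrt(27)),
               tolerance = 1e-10)
  expect_equal(res$ci_high, tanh(atanh(0.5) + qnorm(0.975) / sqrt(27)),
               tolerance = 1e-10)
  expect_lt(abs(res$ci_low - 0.168), 0.005)
  expect_lt(abs(res$ci_high - 0.729), 0.005)
  expect_equal(res$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)
})

test_that("independent data leave the correlation CI around zero", {
  hits <- 0
  for (seed in 1:40) {
    withr::with_seed(seed, {
      x <- rnorm(100)
      y <- sample(x)
    })
    res <- pearson_r_ci(x, y)
    if (abs(res$r) < 0.3 && res$ci_low <= 0 && res$ci_high >= 0) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 36)  # ~95% of seeds
})

test_that("correlation guards degenerate inputs", {
  expect_error(pearson_r_ci(1:3, c(2, 3, 4)), "at least 4")
  expect_error(pearson_r_ci(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("cohort summary reproduces printed-style percentages and tests", {
  records <- tibble::tibble(
    deficit = rep(c(0, 1), c(36, 26)),
    age = c(rnorm(36, 16, 10), rnorm(26, 14, 10)),
    gender = c(rep(c(1, 0), c(17, 19)), rep(c(1, 0), c(12, 14))))
  tab <- summarize_cohort(records, continuous = "age",
                          categorical = "gender")
  gender_rows <- tab[tab$variable == "gender", ]
  expect_equal(gender_rows$group0[gender_rows$level == "1"], "17 (47.2%)")
  expect_equal(gender_rows$group1[gender_rows$level == "1"], "12 (46.2%)")
  p_gender <- gender_rows$p_value[!is.na(gender_rows$p_value)]
  expect_gt(p_gender, 0.99)
  expect_equal(tab$test[tab$variable == "age"], "Mann-Whitney U")

  # an all-equal continuous variable yields a null test column
  records$flat <- 1
  records$flat[1] <- 1  # still constant
  tab2 <- summarize_cohort(records, continuous = "flat",
                           categorical = character(0))
  expect_gte(tab2$p_value[tab2$variable == "flat"], 0.99)

  records$bad <- c("a", rep(1, 61))
  expect_error(summarize_cohort(records, continuous = "bad",
                                categorical = character(0)),
               "not numeric")
})

test_that("half-up percentage rounding matches the published table", {
  expect_equal(pct(29, 62), 46.8)   # female fraction
  expect_equal(pct(41, 62), 66.1)   # MRI negative
  expect_equal(pct(51, 62), 82.3)   # Engel I
  expect_equal(pct(13, 26), 50)     # upper-limb deficits
  expect_equal(pct(5, 26), 19.2)    # strength grade 2
  expect_equal(pct(35, 62), 56.5)   # right-sided lesions
  # 27/62 = 43.548...%: half-up rounding gives 43.5 (one printed source
  # shows 43.6, which is inconsistent with its own 56.5% complement)
  expect_equal(pct(27, 62), 43.5)
  expect_equal(pct(5, 1000), 0.5)
  expect_equal(petmotor:::round_half_up(0.25, 1), 0.3)
})
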