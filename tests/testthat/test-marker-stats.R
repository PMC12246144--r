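test_that("grade trend test behaves under null and ordered alternatives", {
  # null: p-values roughly uniform, not systematically small
  pvals <- withr::with_seed(31, vapply(1:200, function(i) {
    grade_trend_test(list(g0 = rnorm(40), g1 = rnorm(20), g2 = rnorm(8)))
  }, numeric(1)))
  expect_gt(mean(pvals < 0.05), 0.0)  # sanity: it can reject
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals), 0.4)

  # strongly ordered shifted groups at replica-like sizes
  withr::with_seed(32, {
    p <- grade_trend_test(list(
      g0 = rlnorm(150, 0, 0.25) - 1,
      g1 = 3 * rlnorm(60, 0, 0.25) - 1,
      g2 = 7 * rlnorm(10, 0, 0.25) - 1,
      g3 = 19 * rlnorm(10, 0, 0.25) - 1))
    expect_lt(p, 0.001)
  })

  expect_error(grade_trend_test(list(a = 1:3)), "at least 2")
})

test_that("two-group trend test agrees with an independent rank-sum", {
  withr::with_seed(33, {
    x <- rnorm(15); y <- rnorm(12, 0.8)
  })
  p_kw <- grade_trend_test(list(a = x, b = y))
  # independent: Wilcoxon rank-sum z^2 ~ chi-square(1), computed by hand
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  W <- sum(r[seq_len(n1)])
  z2 <- (W - n1 * (N + 1) / 2)^2 / (n1 * n2 * (N + 1) / 12)
  expect_equal(p_kw, pchisq(z2, 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("ordered-alternative trend statistic detects monotone shifts", {
  withr::with_seed(34, {
    p_up <- grade_trend_test(list(a = rnorm(20), b = rnorm(20, 1),
                                  c = rnorm(20, 2)),
                             ordered_alternative = TRUE)
    p_null <- mean(vapply(1:50, function(i)
      grade_trend_test(list(a = rnorm(20), b = rnorm(20), c = rnorm(20)),
                       ordered_alternative = TRUE), numeric(1)))
  })
  expect_lt(p_up, 1e-4)
  expect_gt(p_null, 0.3)
})

test_that("select_markers recovers planted markers and controls FWER", {
  # default replica: exactly the 14 planted markers
  co <- generate_cohort(default_config(), seed = 41)
  expect_setequal(select_markers(co), ev_affected_markers())

  # single planted marker with a x19 grade-3A effect
  cfg <- default_config(10)
  cfg$effect_table[] <- 1
  cfg$pre_effect_table[] <- 1
  cfg$effect_table["CD24", ] <- c(3, 7, 19)
  co1 <- generate_cohort(cfg, seed = 42)
  expect_equal(as.character(select_markers(co1)), "CD24")

  # global null: family-wise error controlled at alpha (over simulations)
  cfg0 <- default_config(8)
  cfg0$effect_table[] <- 1
  cfg0$pre_effect_table[] <- 1
  n_any <- sum(vapply(1:25, function(s) {
    length(select_markers(generate_cohort(cfg0, seed = 100 + s))) > 0
  }, logical(1)))
  expect_lte(n_any, 3)   # binomial(25, 0.05): P(X > 3) < 0.04
})

test_that("single_marker_roc matches brute-force concordance and Youden", {
  d <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.9)
  y <- c(0, 0, 1, 1, 0, 1)
  roc <- single_marker_roc(d, y, n_boot = 200, seed = 1)
  expect_equal(roc$auc, brute_force_auc(d, y))

  # perfectly separated classes
  sep <- single_marker_roc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1),
                           n_boot = 200, seed = 1)
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_true(sep$cutoff > 3 && sep$cutoff <= 10)

  # null: labels independent of values
  withr::with_seed(43, {
    auc_null <- single_marker_roc(runif(400), rbinom(400, 1, 0.3),
                                  n_boot = 100, seed = 2)$auc
  })
  expect_lt(abs(auc_null - 0.5), 0.08)

  # CI brackets the point estimate
  expect_true(roc$auc_ci[1] <= roc$auc && roc$auc <= roc$auc_ci[2])
  expect_error(single_marker_roc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("univariate OR recovers a generating logistic slope", {
  withr::with_seed(44, {
    d <- runif(5000, -50, 150)
    y <- rbinom(5000, 1, plogis(-2 + log(1.05) * d))
  })
  res <- univariate_or(d, y)
  expect_equal(res$or_per_pct, 1.05, tolerance = 0.01)
  expect_true(res$or_ci[1] < 1.05 && 1.05 < res$or_ci[2])
  expect_false(res$separated)

  # null: OR ~ 1
  withr::with_seed(45, {
    res0 <- univariate_or(runif(2000), rbinom(2000, 1, 0.3))
  })
  expect_equal(res0$or_per_pct, 1, tolerance = 0.2)

  # complete separation is flagged
  expect_warning(
    sep <- univariate_or(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)),
    "separation")
  expect_true(sep$separated)
  expect_true(all(is.na(sep$or_ci)))
})

test_that("multivariate OR adjusts for therapy", {
  withr::with_seed(46, {
    n <- 5000
    tac <- rbinom(n, 1, 0.5)
    d <- runif(n, -50, 150)
    y <- rbinom(n, 1, plogis(-2.5 + log(1.04) * d + log(2) * tac))
    therapy <- ifelse(tac == 1, "TAC", "CSA")
  })
  res <- multivariate_or(d, y, therapy)
  expect_equal(res$adjusted_or, 1.04, tolerance = 0.01)
  expect_true(res$or_ci[1] < 1.04 && 1.04 < res$or_ci[2])

  # therapy independent of label and delta: adjusted ~ univariate
  withr::with_seed(47, {
    d2 <- runif(1500, -50, 150)
    y2 <- rbinom(1500, 1, plogis(-2 + log(1.03) * d2))
    t2 <- sample(c("CSA", "TAC"), 1500, TRUE)
  })
  expect_equal(multivariate_or(d2, y2, t2)$adjusted_or,
               univariate_or(d2, y2)$or_per_pct, tolerance = 0.005)
  expect_error(multivariate_or(d2, y2, rep("CSA", 1500)), "both regimens")
})

test_that("treatment response test is exact for small n and null-centered", {
  # all pairs decreasing: exact one-sided signed-rank minimum p = 1/2^n
  pairs <- cbind(before = c(500, 600, 700, 800, 900),
                 after = c(100, 150, 200, 250, 300))
  expect_equal(treatment_response_test(pairs), 1 / 2^5)
  # symmetric no-change pairs: p around 0.5
  withr::with_seed(48, {
    p0 <- replicate(40, {
      b <- rnorm(12)
      treatment_response_test(cbind(b, b + rnorm(12)))
    })
  })
  expect_gt(mean(p0), 0.35)
  expect_lt(mean(p0), 0.65)
  expect_error(treatment_response_test(cbind(1:2, 2:3)), "insufficient")
})

test_that("treatment pairing and replica response show a decrease", {
  co <- generate_cohort(default_config(), seed = 49)
  norm <- normalize_cohort(co, "retrospective")
  pairs <- evreject:::treatment_pairs(co, norm, "CD45",
                                      protocol = "IMMUNO")
  expect_gte(nrow(pairs), 3)
  expect_lt(treatment_response_test(pairs), 0.05)
})

test_that("marker_stat_table assembles one coherent row per marker", {
  co <- generate_cohort(small_config(), seed = 71)
  tab <- suppressWarnings(marker_stat_table(co, n_boot = 50, seed = 1))
  expect_equal(tab$marker, ev_panel("IMMUNO"))
  expect_true(all(tab$selected == (tab$trend_p_bonferroni < 0.05)))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$auc_lo <= tab$auc & tab$auc <= tab$auc_hi))
  expect_true(all(tab$sensitivity >= 0 & tab$sensitivity <= 1))
  expect_true(all(tab$or_per_pct > 0, na.rm = TRUE))
  # planted markers discriminate far better than null markers
  expect_gt(min(tab$auc[tab$marker %in% ev_affected_markers()]),
            max(tab$auc[!tab$marker %in% ev_affected_markers()]))
})

test_that("AUC is invariant under strictly monotone transforms", {
  withr::with_seed(50, {
    d <- rnorm(60)
    y <- rbinom(60, 1, plogis(d))
  })
  a1 <- single_marker_roc(d, y, n_boot = 50, seed = 1)$auc
  a2 <- single_marker_roc(exp(d), y, n_boot = 50, seed = 1)$auc
  a3 <- single_marker_roc(10 + 3 * atan(d), y, n_boot = 50, seed = 1)$auc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})
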