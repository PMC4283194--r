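test_that("percent difference matches its closed form and is antisymmetric", {
  expect_equal(percent_diff(10, 10), 0)
  expect_equal(percent_diff(8, 12), 40)
  set.seed(77)
  a <- rexp(50); b <- rexp(50)
  expect_equal(percent_diff(a, b), -percent_diff(b, a))
  # bounded for positive pairs
  expect_true(all(abs(percent_diff(a, b)) < 200))
  expect_warning(pd <- percent_diff(1, -1), "zero")
  expect_true(is.nan(pd))
})

test_that("the one-way ICC matches a brute-force ANOVA oracle", {
  m0 <- cbind(c(10, 12, 8, 14, 9), c(11, 12, 9, 13, 10))
  expect_lt(abs(icc_oneway(m0)$icc - oracle_icc_aov(m0)), 1e-12)
  set.seed(88)
  worst <- 0
  for (i in 1:200) {
    n <- sample(3:20, 1)
    m <- matrix(rnorm(2 * n, mean = 10, sd = sample(1:5, 1)), ncol = 2)
    worst <- max(worst, abs(icc_oneway(m)$icc - oracle_icc_aov(m)))
  }
  expect_lt(worst, 1e-12)
})

test_that("ICC edge behaviour and invariances hold", {
  # exact repetition with between-subject spread
  perfect <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc_oneway(perfect)$icc, 1)
  # affine invariance y -> a y + b
  set.seed(99)
  m <- matrix(rnorm(20, 10), ncol = 2)
  expect_equal(icc_oneway(3.7 * m + 11)$icc, icc_oneway(m)$icc,
               tolerance = 1e-10)
  # incomplete pairs are dropped pairwise and counted
  m2 <- rbind(m, c(NaN, 5))
  r <- icc_oneway(m2)
  expect_equal(r$n_excluded, 1)
  expect_equal(r$icc, icc_oneway(m)$icc)
  expect_error(icc_oneway(m[1:2, ]), "at least 3")
  expect_error(icc_oneway(matrix(5, 4, 2)), "zero total variance")
})

test_that("the printed-denominator variant downweights reliability as written", {
  set.seed(111)
  m <- matrix(rnorm(30, 10, 3), ncol = 2)
  std <- icc_oneway(m, denominator = "standard")
  pr <- icc_oneway(m, denominator = "printed")
  # same mean squares, heavier denominator weight df_WS = n*(k-1) > k-1
  expect_equal(pr$msbs, std$msbs)
  expect_equal(pr$icc, (pr$msbs - pr$msws) / (pr$msbs + pr$df_ws * pr$msws))
  expect_lt(abs(pr$icc), abs(std$icc) + 1e-12)
})

test_that("between-subject CV uses sample SD over subject means", {
  # hand computation: per-subject means {8, 10, 12} -> 100 * 2/10
  m <- cbind(c(8, 10, 12), c(8, 10, 12))
  expect_equal(between_subject_cv(m), 20)
  expect_equal(between_subject_cv(matrix(7, 5, 2)), 0)
  expect_warning(v <- between_subject_cv(cbind(c(-5, 5, 0), c(-5, 5, 0))),
                 "non-positive")
  expect_true(is.nan(v))
})

test_that("Bland-Altman points, bias and limits follow the definitions", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_true(all(same$points$difference == 0))
  expect_equal(same$bias, 0)
  ba <- bland_altman(c(10, 12), c(8, 12))
  expect_equal(ba$points$mean, c(9, 12))
  expect_equal(ba$points$difference, c(2, 0))
  expect_equal(ba$bias, 1)
  expect_equal(ba$loa_upper - ba$bias, 1.96 * sd(c(2, 0)))
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("heterogeneity ratio and interval correlation behave", {
  est <- tibble::tibble(region_id = rep(c("pallidum", "pons"), each = 5),
                        vt = c(rep(9, 5), rep(3, 5)))
  expect_equal(heterogeneity_ratio(est), 3)
  est_eq <- est
  est_eq$vt <- 4
  expect_equal(heterogeneity_ratio(est_eq), 1)
  est0 <- est
  est0$vt[est0$region_id == "pons"] <- 0
  expect_error(heterogeneity_ratio(est0), "zero")
  ic <- interval_correlation(c(1, 2, 3, 4, 5), c(3, 9, 20, 60, 200))
  expect_equal(ic$rho, 1)
  expect_equal(ic$p_bonferroni, min(ic$p_value * 8, 1))
  expect_error(interval_correlation(1:3, 1:3), "at least 5")
})

test_that("a zero-variance cohort gives a perfect reliability table", {
  truth <- simulate_cohort(n_subjects = 5, seed = 4, ws_cv = 0,
                           tacs = FALSE)$truth
  tbl <- build_reliability_table(truth, value_col = "vt_true",
                                 method_label = "truth")
  expect_equal(nrow(tbl), 8)
  expect_true(all(abs(tbl$median_pct_diff) < 1e-10))
  expect_true(all(tbl$icc > 1 - 1e-10))
  expect_true(all(tbl$n_excluded == 0))
  summ <- reliability_summary(tbl)
  expect_equal(summ$mean_icc, 1, tolerance = 1e-10)
  expect_equal(summ$ratio_high_low, 3.6, tolerance = 0.35)
})

test_that("failed fits are excluded pairwise with counts", {
  truth <- simulate_cohort(n_subjects = 6, seed = 8, tacs = FALSE)$truth
  truth$vt_true[truth$subject_id == "S01" & truth$session == "retest" &
                  truth$region_id == "pons"] <- NaN
  tbl <- build_reliability_table(truth, value_col = "vt_true",
                                 method_label = "truth")
  expect_equal(tbl$n_excluded[tbl$region_id == "pons"], 1)
  expect_equal(tbl$n_pairs[tbl$region_id == "pons"], 5)
  expect_equal(tbl$n_excluded[tbl$region_id == "pallidum"], 0)
})
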