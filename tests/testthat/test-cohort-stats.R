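# hand-rolled one-sample KS statistic against a fitted normal: the
# ECDF-gap oracle for the packaged test
ks_stat_oracle <- function(x) {
  n <- length(x)
  z <- sort(pnorm(x, mean(x), sd(x)))
  max(pmax((1:n) / n - z, z - (0:(n - 1)) / n))
}

test_that("KS normality flags seeded normal and exponential samples", {
  x <- withr::with_seed(5, rnorm(200))
  res <- ks_normality(x)
  expect_true(res$normal)
  expect_equal(res$statistic, ks_stat_oracle(x), tolerance = 1e-12)

  y <- withr::with_seed(5, rexp(200))
  res_y <- ks_normality(y)
  expect_false(res_y$normal)
  expect_equal(res_y$statistic, ks_stat_oracle(y), tolerance = 1e-12)

  expect_error(ks_normality(rep(3, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2)), "n >= 5")
})

test_that("Welch's t matches the hand-evaluated formulas", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  # s^2 = 1 in both groups: t = -3 / sqrt(2/3), df = 4 exactly
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), -3.674)
  expect_equal(res$df, 4.0, tolerance = 1e-12)

  same <- welch_t(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(2, 4, 6, 8)
  expect_lt(welch_t(a, a + 3)$statistic, 0)
  expect_gt(welch_t(a, a - 3)$statistic, 0)
  expect_error(welch_t(1, c(2, 3)), "n >= 2")
})

test_that("one-sample Wilcoxon enumerates the exact two-tailed p", {
  # symmetric signed ranks about the hypothesized median
  expect_equal(wilcoxon_one_sample(c(1, 2, 3), 2)$p_value, 1.0)

  # 12 uniformly signed differences: the most extreme ordering
  res <- wilcoxon_one_sample(11:22, 5)
  expect_true(res$exact)
  expect_equal(res$statistic, 78)
  expect_equal(res$p_value, 2 / 2^12, tolerance = 1e-15)

  expect_error(wilcoxon_one_sample(rep(7, 5), 7), "equal the hypothesized")
})

test_that("exact Wilcoxon p agrees with wilcox.test on tie-free data", {
  for (s in 1:6) {
    x <- withr::with_seed(s, round(rnorm(15, 0.4, 1), 7))
    ours <- wilcoxon_one_sample(x, 0)
    ref <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12,
                 label = sprintf("seed %d", s))
  }
})

test_that("exact and normal-approximation Wilcoxon p agree at n = 20", {
  for (s in 1:20) {
    x <- withr::with_seed(100 + s, rnorm(20, 0.3, 1))
    d <- x[x != 0]
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    # continuity-corrected normal approximation, computed in-test
    z <- max(abs(W - sum(r) / 2) - 0.5, 0) / sqrt(sum(r^2) / 4)
    p_approx <- 2 * pnorm(-z)
    p_exact <- wilcoxon_one_sample(x, 0)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("correlation routes Pearson and Spearman correctly", {
  res <- correlate(c(1, 2, 3), c(2, 4, 6), parametric = TRUE)
  expect_equal(res$type, "pearson")
  expect_equal(res$r, 1.0)

  x <- 1:10
  res_sp <- correlate(x, exp(x), parametric = FALSE)
  expect_equal(res_sp$type, "spearman")
  expect_equal(res_sp$r, 1.0)

  expect_error(correlate(1:5, rep(2, 5)), "constant")
  expect_error(correlate(1:5, 1:4), "equal length")
})

test_that("Spearman equals Pearson on ranks for tie-free vectors", {
  for (s in 1:10) {
    x <- withr::with_seed(200 + s, rnorm(25))
    y <- withr::with_seed(300 + s, rnorm(25))
    ours <- correlate(x, y, parametric = FALSE)$r
    oracle <- cor(rank(x), rank(y))   # brute-force ranking route
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("the report reproduces group medians, differences and counts", {
  tab <- make_median_fixture()
  rep <- build_report(tab)
  s <- tidy(rep)

  expect_equal(s$median_pcd[s$method == "manual"], 9.2)
  expect_equal(s$median_hc[s$method == "manual"], 11.1)
  expect_equal(s$median_diff[s$method == "manual"], 1.9)
  expect_equal(s$median_diff[s$method == "mean_psd"], 1.9)
  expect_equal(s$median_diff[s$method == "histogram"], 2.1)

  g <- glance(rep)
  expect_equal(g$n_recordings_pcd, 115L)
  expect_equal(g$n_recordings_hc, 60L)
  expect_equal(g$total_observation_points, 175L)
})

test_that("report medians are invariant to row order", {
  tab <- make_median_fixture(n_pcd = 21, n_hc = 12)
  shuffled <- tab[withr::with_seed(9, sample(nrow(tab))), ]
  cols <- c("method", "median_pcd", "median_hc", "median_diff")
  expect_equal(dplyr::arrange(tidy(build_report(tab))[cols], method),
               dplyr::arrange(tidy(build_report(shuffled))[cols], method))
})

test_that("a method missing one group is a declared error", {
  tab <- make_median_fixture(n_pcd = 21, n_hc = 12)
  broken <- tab[!(tab$method == "histogram" & tab$group == "HC"), ]
  expect_error(build_report(broken), "lacks one of the groups")
})

test_that("skewed methods route nonparametric while normal ones stay parametric", {
  n_p <- 60; n_h <- 40
  base <- function(m, g, v) {
    tibble::tibble(subject = sprintf("%s_s%03d", g, seq_along(v)),
                   group = g,
                   recording = sprintf("%s_r%03d", g, seq_along(v)),
                   method = m, cbf_hz = v)
  }
  tab <- withr::with_seed(77, dplyr::bind_rows(
    base("manual", "PCD", rnorm(n_p, 9.2, 0.5)),
    base("manual", "HC", rnorm(n_h, 11.1, 0.5)),
    base("mean_psd", "PCD", rnorm(n_p, 8.8, 0.5)),
    base("mean_psd", "HC", rnorm(n_h, 10.7, 0.5)),
    # heavily right-skewed PCD values for one method only
    base("histogram", "PCD", 8 + rexp(n_p, 2)^2),
    base("histogram", "HC", rnorm(n_h, 10.8, 0.5))
  ))
  s <- tidy(build_report(tab))
  expect_equal(s$test[s$method == "manual"], "welch_t")
  expect_equal(s$test[s$method == "mean_psd"], "welch_t")
  expect_equal(s$test[s$method == "histogram"], "wilcoxon_one_sample")
  expect_equal(s$cor_type[s$method == "mean_psd"], "pearson")
  expect_equal(s$cor_type[s$method == "histogram"], "spearman")
})

test_that("cohort tables are validated", {
  expect_error(cohort_table(data.frame(a = 1)), "lacks column")
  bad_group <- data.frame(subject = "s", group = "X", recording = "r",
                          method = "manual", cbf_hz = 9)
  expect_error(cohort_table(bad_group), "PCD")
  dup <- data.frame(subject = c("s", "s"), group = "PCD",
                    recording = c("r", "r"), method = "manual",
                    cbf_hz = c(9, 10))
  expect_error(cohort_table(dup), "unique")
})
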