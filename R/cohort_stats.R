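#' Kolmogorov-Smirnov normality assessment
#'
#' One-sample KS test of the values against a normal distribution
#' with the sample's own mean and SD (no Lilliefors correction), the
#' routing criterion for the two-cohort comparison: `normal` is
#' `p > 0.05`.
#'
#' @param values numeric vector, `n >= 5`, non-constant.
#' @return a tibble: `test, statistic, p_value, n, normal`.
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 5L) abort_cf("KS normality needs n >= 5.", "too_few")
  s <- sd(values)
  if (s == 0) abort_cf("zero variance: KS normality undefined.",
                       "zero_variance")
  kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), s))
  tibble(test = "ks_normality", statistic = unname(kt$statistic),
         p_value = kt$p.value, n = n, normal = kt$p.value > 0.05)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of
#' freedom, two-tailed.
#'
#' @param a,b numeric vectors, each `n >= 2` with finite variance.
#' @return a tibble: `test, statistic, df, p_value, n_a, n_b`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_cf("Welch's t needs n >= 2 in both groups.", "too_few")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(test = "welch_t", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value,
         n_a = length(a), n_b = length(b))
}

# exact null distribution of the one-sample signed-rank statistic for
# (possibly tied, mid-ranked) absolute differences: dynamic program
# over doubled ranks, which are integers even with mid-ranks
signed_rank_exact_p <- function(W, ranks) {
  w2 <- as.integer(round(2 * ranks))
  total <- sum(w2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (w in w2) {
    g <- f
    g[(w + 1L):(total + 1L)] <- g[(w + 1L):(total + 1L)] +
      f[seq_len(total + 1L - w)]
    f <- g
  }
  probs <- f / 2^length(ranks)
  W2 <- round(2 * W)
  lo <- sum(probs[seq_len(W2 + 1L)])           # P(W <= w)
  hi <- sum(probs[(W2 + 1L):(total + 1L)])     # P(W >= w)
  min(1, 2 * min(lo, hi))
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether the values are symmetric about a hypothesized
#' median. Differences exactly equal to the hypothesized value are
#' dropped; ties among absolute differences receive mid-ranks. The
#' two-tailed p-value is exact (enumeration over sign assignments via
#' a rank-sum recursion) for `n <= 25` remaining values, and uses the
#' normal approximation with continuity correction above that, with
#' the exact tie-aware variance `sum(ranks^2) / 4`.
#'
#' @param values numeric vector.
#' @param mu hypothesized median.
#' @return a tibble: `test, statistic, p_value, n, exact, mu`.
#' @export
wilcoxon_one_sample <- function(values, mu) {
  d <- as.numeric(values) - mu
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) {
    abort_cf("all values equal the hypothesized median.", "degenerate")
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    p <- signed_rank_exact_p(W, r)
    exact <- TRUE
  } else {
    mu_w <- sum(r) / 2
    sig <- sqrt(sum(r^2) / 4)
    z <- max(abs(W - mu_w) - 0.5, 0) / sig
    p <- 2 * pnorm(-z)
    exact <- FALSE
  }
  tibble(test = "wilcoxon_one_sample", statistic = W, p_value = p,
         n = n, exact = exact, mu = mu)
}

#' Correlation between two CBF series
#'
#' Pearson's r for parametric data, Spearman's rank correlation
#' (Pearson on mid-ranks) otherwise; two-tailed p-value by the t
#' transform in both cases.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`,
#'   non-constant.
#' @param parametric `TRUE` for Pearson, `FALSE` for Spearman.
#' @return a tibble: `type, r, p_value, n`.
#' @export
correlate <- function(x, y, parametric = TRUE) {
  if (length(x) != length(y)) {
    abort_cf("`x` and `y` must have equal length.", "length_mismatch")
  }
  if (length(x) < 3L) abort_cf("correlation needs n >= 3.", "too_few")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_cf("constant input: correlation undefined.", "zero_variance")
  }
  if (parametric) {
    ct <- cor.test(x, y, method = "pearson")
    tibble(type = "pearson", r = unname(ct$estimate),
           p_value = ct$p.value, n = length(x))
  } else {
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))
    tibble(type = "spearman", r = unname(ct$estimate),
           p_value = ct$p.value, n = length(x))
  }
}

#' Assemble and validate a cohort table
#'
#' One row per (subject, recording, method): the long-format CBF
#' table the report builder consumes. Groups must be labelled
#' `"PCD"` and `"HC"`.
#'
#' @param df data frame with columns `subject, group, recording,
#'   method, cbf_hz`.
#' @return the validated tibble.
#' @export
cohort_table <- function(df) {
  need <- c("subject", "group", "recording", "method", "cbf_hz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_cf(paste0("cohort table lacks column(s): ",
                    paste(missing_cols, collapse = ", ")), "bad_table")
  }
  df <- as_tibble(df)[need]
  if (!all(df$group %in% c("PCD", "HC"))) {
    abort_cf('cohort groups must be labelled "PCD" and "HC".',
             "bad_table")
  }
  if (any(df$cbf_hz <= 0)) {
    abort_cf("cbf_hz must be > 0.", "bad_table")
  }
  key <- paste(df$subject, df$recording, df$method, sep = "\r")
  if (anyDuplicated(key)) {
    abort_cf("(subject, recording, method) rows must be unique.",
             "bad_table")
  }
  df
}

iqr_type7 <- function(x) {
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  c(lo = q[1], hi = q[2], width = q[2] - q[1])
}

#' Build the two-cohort comparison report
#'
#' For every method: per-group medians and IQRs (quartiles by the
#' inclusive linear-interpolation rule, R type 7), the actual median
#' difference (HC minus PCD), a normality-routed group test (Welch's
#' t when both groups pass [ks_normality()], otherwise a one-sample
#' Wilcoxon of the PCD values against the HC median), and a
#' normality-routed correlation of the method's per-recording values
#' against the manual method, per group. Groups with fewer than 5
#' values cannot be KS-assessed and route nonparametric.
#'
#' @param table a [cohort_table()] (or coercible data frame).
#' @param alpha significance level recorded in the report metadata.
#' @return An object of class `cbf_report`; see [tidy.cbf_report()]
#'   and [glance.cbf_report()].
#' @export
build_report <- function(table, alpha = 0.05) {
  table <- cohort_table(table)
  if (alpha <= 0 || alpha >= 1) abort_cf("`alpha` must be in (0, 1).",
                                         "bad_arg")
  methods <- unique(table$method)
  for (m in methods) {
    sub <- table[table$method == m, ]
    if (!all(c("PCD", "HC") %in% sub$group)) {
      abort_cf(sprintf("method %s lacks one of the groups.", m),
               "missing_group")
    }
  }
  manual_tab <- table[table$method == "manual", ]

  rows <- lapply(methods, function(m) {
    sub <- table[table$method == m, ]
    v_pcd <- sub$cbf_hz[sub$group == "PCD"]
    v_hc <- sub$cbf_hz[sub$group == "HC"]
    iqr_p <- iqr_type7(v_pcd)
    iqr_h <- iqr_type7(v_hc)
    norm_flag <- function(v) {
      if (length(v) < 5L || sd(v) == 0) return(NA)
      ks_normality(v)$normal
    }
    np <- norm_flag(v_pcd)
    nh <- norm_flag(v_hc)
    parametric <- isTRUE(np) && isTRUE(nh)
    test_res <- if (parametric) {
      welch_t(v_hc, v_pcd)
    } else {
      wilcoxon_one_sample(v_pcd, median(v_hc))
    }
    cors <- list(PCD = list(r = NA_real_, p = NA_real_),
                 HC = list(r = NA_real_, p = NA_real_))
    if (m != "manual" && nrow(manual_tab) > 0) {
      paired <- dplyr::inner_join(
        sub, manual_tab,
        by = c("subject", "group", "recording"),
        suffix = c("", "_manual"))
      for (g in c("PCD", "HC")) {
        pg <- paired[paired$group == g, ]
        if (nrow(pg) >= 3L && sd(pg$cbf_hz) > 0 &&
            sd(pg$cbf_hz_manual) > 0) {
          ct <- correlate(pg$cbf_hz, pg$cbf_hz_manual,
                          parametric = parametric)
          cors[[g]] <- list(r = ct$r, p = ct$p_value)
        }
      }
    }
    tibble(
      method = m,
      n_pcd = length(v_pcd), n_hc = length(v_hc),
      median_pcd = median(v_pcd), iqr_pcd = iqr_p[["width"]],
      median_hc = median(v_hc), iqr_hc = iqr_h[["width"]],
      median_diff = median(v_hc) - median(v_pcd),
      normal_pcd = np, normal_hc = nh,
      test = test_res$test[1], statistic = test_res$statistic[1],
      p_value = test_res$p_value[1],
      cor_type = if (m == "manual") NA_character_ else
        if (parametric) "pearson" else "spearman",
      r_pcd = cors$PCD$r, r_hc = cors$HC$r,
      r_p_pcd = cors$PCD$p, r_p_hc = cors$HC$p
    )
  })
  summary <- dplyr::bind_rows(rows)

  rec <- dplyr::distinct(table, .data$group, .data$subject,
                         .data$recording)
  n_pcd <- sum(rec$group == "PCD")
  n_hc <- sum(rec$group == "HC")
  structure(
    list(summary = summary,
         n_recordings_pcd = n_pcd,
         n_recordings_hc = n_hc,
         total_observation_points = n_pcd + n_hc,
         alpha = alpha,
         quartile_rule = "inclusive linear interpolation (type 7)"),
    class = "cbf_report"
  )
}

#' @export
print.cbf_report <- function(x, ...) {
  cat(sprintf(
    "<cbf_report> %d PCD + %d HC recordings (%d observation points), alpha = %g\n",
    x$n_recordings_pcd, x$n_recordings_hc, x$total_observation_points,
    x$alpha))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-10s median PCD %.4g (IQR %.3g) | HC %.4g (IQR %.3g) | diff %.3g Hz | %s p = %.3g\n",
      s$method[i], s$median_pcd[i], s$iqr_pcd[i], s$median_hc[i],
      s$iqr_hc[i], s$median_diff[i], s$test[i], s$p_value[i]))
    if (!is.na(s$cor_type[i])) {
      cat(sprintf("  %-10s r vs manual (%s): PCD %.4g, HC %.4g\n", "",
                  s$cor_type[i], s$r_pcd[i], s$r_hc[i]))
    }
  }
  cat(sprintf("  quartiles: %s\n", x$quartile_rule))
  invisible(x)
}

#' Tidy / glance methods for comparison reports
#'
#' `tidy()` returns the per-method summary table (one row per method:
#' medians, IQRs, median difference, routed test and p-value,
#' correlations against the manual method). `glance()` returns the
#' one-row cohort-level summary (recording counts, total observation
#' points, alpha, quartile rule).
#'
#' @param x a `cbf_report`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy cbf_report
#' @export
tidy.cbf_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy.cbf_report
#' @method glance cbf_report
#' @export
glance.cbf_report <- function(x, ...) {
  tibble(n_recordings_pcd = x$n_recordings_pcd,
         n_recordings_hc = x$n_recordings_hc,
         total_observation_points = x$total_observation_points,
         alpha = x$alpha,
         quartile_rule = x$quartile_rule)
}
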