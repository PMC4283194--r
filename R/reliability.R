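#' Signed test-retest percentage difference
#'
#' `100 * 2 * (retest - test) / (test + retest)`: the difference as a
#' percentage of the pair mean, signed, antisymmetric under swapping
#' the sessions, and bounded in (-200, 200) for positive pairs.
#'
#' @param test,retest Numeric vectors of paired estimates.
#' @return Numeric vector of signed percentages; `NaN` (with a warning)
#'   where the pair sum is zero.
#' @examples
#' percent_diff(8, 12)  # +40
#' @export
percent_diff <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  s <- test + retest
  out <- 2 * (retest - test) / s * 100
  bad <- is.finite(test) & is.finite(retest) & s == 0
  if (any(bad)) {
    warning("zero test+retest sum; returning NaN", call. = FALSE)
    out[bad] <- NaN
  }
  out
}

#' One-way random-effects, single-measures intraclass correlation
#'
#' Reliability of repeated measurements per subject from the one-way
#' ANOVA decomposition: with `MSBS` and `MSWS` the between- and
#' within-subject mean squares over `n` subjects and `k = 2` sessions,
#' the single-measures ICC(1,1) is
#' `(MSBS - MSWS) / (MSBS + (k - 1) * MSWS)`.
#' A variant denominator `MSBS + df_WS * MSWS` (with
#' `df_WS = n * (k - 1)`) is also available for comparison with reports
#' that print the formula that way; the standard form is the default
#' and is what mainstream statistical packages compute.
#'
#' Incomplete pairs (any non-finite value) are dropped pairwise and
#' counted. The ICC is at most 1, equals 1 exactly when the
#' within-subject variance vanishes while subjects differ, and is
#' invariant under affine rescaling of all measurements.
#'
#' @param values Numeric matrix or data frame with one row per subject
#'   and one column per session (typically n x 2).
#' @param denominator `"standard"` (`(k-1)` weight) or `"printed"`
#'   (`df_WS` weight).
#' @return An object of class `petrel_icc`: list with `icc`, `msbs`,
#'   `msws`, `df_bs`, `df_ws`, `n`, `k`, `n_excluded`, `denominator`.
#' @examples
#' icc_oneway(cbind(c(10, 12, 8, 14, 9), c(11, 12, 9, 13, 10)))
#' @export
icc_oneway <- function(values, denominator = c("standard", "printed")) {
  denominator <- match.arg(denominator)
  m <- as.matrix(values)
  stopifnot(ncol(m) >= 2)
  complete <- rowSums(!is.finite(m)) == 0
  n_excluded <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) stop("need at least 3 complete subject pairs", call. = FALSE)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0) {
    stop("zero total variance; ICC undefined", call. = FALSE)
  }
  subj_means <- rowMeans(m)
  ss_bs <- k * sum((subj_means - grand)^2)
  ss_ws <- sum((m - subj_means)^2)
  df_bs <- n - 1
  df_ws <- n * (k - 1)
  msbs <- ss_bs / df_bs
  msws <- ss_ws / df_ws
  denom <- if (denominator == "standard") {
    msbs + (k - 1) * msws
  } else {
    msbs + df_ws * msws
  }
  structure(
    list(icc = (msbs - msws) / denom, msbs = msbs, msws = msws,
         df_bs = df_bs, df_ws = df_ws, n = n, k = k,
         n_excluded = n_excluded, denominator = denominator,
         variant = "one-way random, single measures"),
    class = "petrel_icc")
}

#' @export
print.petrel_icc <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.3f  (%s; n = %d, k = %d%s)\n",
              x$icc, x$variant, x$n, x$k,
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Between-subject coefficient of variation (percent)
#'
#' `100 * SD / mean` across subjects. By default each subject enters as
#' the average of their test and retest values; `mode =
#' "per_session"` instead computes the CV within each session column
#' and averages the two. Sample (n-1) standard deviations are used.
#'
#' @param values Subjects x sessions matrix (as in [icc_oneway()]).
#' @param mode `"subject_mean"` or `"per_session"`.
#' @return Percent CV (scalar); `NaN` with a warning when the mean is
#'   not positive.
#' @export
between_subject_cv <- function(values, mode = c("subject_mean", "per_session")) {
  mode <- match.arg(mode)
  m <- as.matrix(values)
  complete <- rowSums(!is.finite(m)) == 0
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 complete subjects", call. = FALSE)
  cv1 <- function(x) {
    mu <- mean(x)
    if (mu <= 0) {
      warning("non-positive mean; between-subject CV undefined", call. = FALSE)
      return(NaN)
    }
    100 * stats::sd(x) / mu
  }
  if (mode == "subject_mean") cv1(rowMeans(m)) else mean(apply(m, 2, cv1))
}

#' Bland-Altman (Tukey mean-difference) comparison of two methods
#'
#' For paired estimates, plots/returns `x = (v1 + v2) / 2` against
#' `y = v1 - v2`, the mean difference (bias) and the 95% limits of
#' agreement `bias +/- 1.96 * SD(y)`. When comparing V_T
#' quantification methods, the convention is that `v2` is the reference
#' method (the one-tissue compartmental model).
#'
#' @param v1,v2 Paired numeric vectors (method 1, reference method 2).
#' @return An object of class `petrel_ba`: `points` tibble
#'   (`mean`, `difference`), `bias`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop("method vectors must have equal length", call. = FALSE)
  }
  ok <- is.finite(v1) & is.finite(v2)
  d <- v1[ok] - v2[ok]
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(points = tibble::tibble(mean = (v1[ok] + v2[ok]) / 2,
                                 difference = d),
         bias = bias,
         loa_lower = bias - 1.96 * s,
         loa_upper = bias + 1.96 * s,
         n = sum(ok)),
    class = "petrel_ba")
}

#' @export
print.petrel_ba <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, 95%% limits of agreement [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' Binding-heterogeneity ratio between a high- and a low-binding region
#'
#' Ratio of the cohort median estimate in the highest-binding region
#' (conventionally the pallidum) to the lowest-binding region (the
#' pons): a method preserving true between-region contrast keeps this
#' ratio high, while a method that compresses the dynamic range pulls
#' it toward 1.
#'
#' @param estimates Data frame with columns `region_id` and a value
#'   column.
#' @param high_label,low_label Region labels.
#' @param value_col Name of the value column (default `"vt"`).
#' @return Scalar ratio of medians.
#' @export
heterogeneity_ratio <- function(estimates, high_label = "pallidum",
                                low_label = "pons", value_col = "vt") {
  stopifnot(all(c(high_label, low_label) %in% estimates$region_id))
  med <- function(lab) {
    stats::median(estimates[[value_col]][estimates$region_id == lab],
                  na.rm = TRUE)
  }
  lo <- med(low_label)
  if (!is.finite(lo) || lo == 0) {
    stop("low-binding region median is zero or undefined", call. = FALSE)
  }
  med(high_label) / lo
}

#' Correlation of test-retest difference with the inter-scan interval
#'
#' Spearman rank correlation between per-subject absolute-or-signed
#' percentage differences and the days between sessions, with
#' Bonferroni correction for the number of regions examined.
#'
#' @param percent_diffs Numeric vector (one per subject).
#' @param intervals_d Inter-scan intervals in days, same length.
#' @param n_comparisons Bonferroni factor (default 8 regions).
#' @return A tibble with `rho`, `p_value`, `p_bonferroni`.
#' @export
interval_correlation <- function(percent_diffs, intervals_d,
                                 n_comparisons = 8) {
  ok <- is.finite(percent_diffs) & is.finite(intervals_d)
  if (sum(ok) < 5) stop("need at least 5 complete pairs", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(percent_diffs[ok], intervals_d[ok], method = "spearman"))
  tibble::tibble(
    rho = unname(ct$estimate),
    p_value = ct$p.value,
    p_bonferroni = min(ct$p.value * n_comparisons, 1)
  )
}

#' Per-region test-retest reliability table
#'
#' Assembles, from a tidy table of per-subject, per-session, per-region
#' estimates, the standard reliability report: cohort median,
#' interquartile range, minimum and maximum of the estimate; the median
#' signed test-retest percentage difference and its signed range; the
#' between-subject CV; and the one-way single-measures ICC. Non-finite
#' estimates (failed fits) are excluded pairwise and counted per
#' region. An ICC of at least 0.75 is conventionally read as good
#' reliability.
#'
#' @param estimates Data frame with columns `subject_id`, `session`
#'   (`"test"`/`"retest"`), `region_id` and the value column.
#' @param value_col Name of the estimate column (default `"vt"`).
#' @param method_label Stored in the `method` column of the output.
#' @param icc_denominator Passed to [icc_oneway()].
#' @return A tibble of class `petrel_reliability`, one row per region:
#'   `median`, `q25`, `q75`, `min`, `max`, `median_pct_diff`,
#'   `pct_diff_min`, `pct_diff_max`, `bs_cv_pct`, `icc`, `n_pairs`,
#'   `n_excluded`. Summarise across regions with
#'   [reliability_summary()].
#' @export
build_reliability_table <- function(estimates, value_col = "vt",
                                    method_label = "method",
                                    icc_denominator = "standard") {
  stopifnot(all(c("subject_id", "session", "region_id", value_col) %in%
                  names(estimates)))
  wide <- tidyr::pivot_wider(
    estimates[, c("subject_id", "session", "region_id", value_col)],
    names_from = "session", values_from = dplyr::all_of(value_col))
  if (!all(c("test", "retest") %in% names(wide))) {
    stop("estimates must contain both a 'test' and a 'retest' session",
         call. = FALSE)
  }
  n_subj <- length(unique(wide$subject_id))
  if (n_subj < 3) stop("need at least 3 subjects", call. = FALSE)

  out <- dplyr::group_by(wide, .data$region_id) |>
    dplyr::group_modify(function(d, key) {
      v <- c(d$test, d$retest)
      pd <- suppressWarnings(percent_diff(d$test, d$retest))
      ok <- is.finite(d$test) & is.finite(d$retest)
      icc <- tryCatch(
        icc_oneway(cbind(d$test, d$retest),
                   denominator = icc_denominator)$icc,
        error = function(e) NA_real_)
      bscv <- tryCatch(
        suppressWarnings(between_subject_cv(cbind(d$test, d$retest))),
        error = function(e) NA_real_)
      tibble::tibble(
        median = stats::median(v, na.rm = TRUE),
        q25 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
        q75 = unname(stats::quantile(v, 0.75, na.rm = TRUE)),
        min = suppressWarnings(min(v, na.rm = TRUE)),
        max = suppressWarnings(max(v, na.rm = TRUE)),
        median_pct_diff = stats::median(pd, na.rm = TRUE),
        pct_diff_min = suppressWarnings(min(pd, na.rm = TRUE)),
        pct_diff_max = suppressWarnings(max(pd, na.rm = TRUE)),
        bs_cv_pct = bscv,
        icc = icc,
        n_pairs = sum(ok),
        n_excluded = sum(!ok)
      )
    }) |>
    dplyr::ungroup()
  out <- dplyr::mutate(out, method = method_label, .before = 1)
  class(out) <- c("petrel_reliability", class(out))
  out
}

#' Cross-region summary of a reliability table
#'
#' Mean and SD across regions of the median percentage difference, the
#' between-subject CV and the ICC, plus the heterogeneity ratio of the
#' high- over the low-binding region medians.
#'
#' @param tbl A [build_reliability_table()] result.
#' @param high_label,low_label Regions for the heterogeneity ratio;
#'   `NA` is reported if either is absent.
#' @return A one-row tibble.
#' @export
reliability_summary <- function(tbl, high_label = "pallidum",
                                low_label = "pons") {
  ratio <- if (all(c(high_label, low_label) %in% tbl$region_id)) {
    lo <- tbl$median[tbl$region_id == low_label]
    if (is.finite(lo) && lo != 0) {
      tbl$median[tbl$region_id == high_label] / lo
    } else {
      NA_real_
    }
  } else {
    NA_real_
  }
  tibble::tibble(
    method = tbl$method[1],
    n_regions = nrow(tbl),
    mean_median_pct_diff = mean(tbl$median_pct_diff, na.rm = TRUE),
    sd_median_pct_diff = stats::sd(tbl$median_pct_diff, na.rm = TRUE),
    mean_bs_cv_pct = mean(tbl$bs_cv_pct, na.rm = TRUE),
    sd_bs_cv_pct = stats::sd(tbl$bs_cv_pct, na.rm = TRUE),
    mean_icc = mean(tbl$icc, na.rm = TRUE),
    sd_icc = stats::sd(tbl$icc, na.rm = TRUE),
    ratio_high_low = ratio
  )
}
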