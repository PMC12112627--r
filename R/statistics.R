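#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test between ipsilateral and contralateral values.
#' Zero differences are dropped first (with `p = 1` and a degenerate flag
#' when nothing remains). In `auto` mode the exact null distribution is used
#' up to 25 informative pairs — by the integer-rank convolution when there
#' are no ties, by full sign enumeration (up to `2^20` assignments) when
#' there are — and the normal approximation with tie and continuity
#' corrections otherwise.
#'
#' @param data data frame with the paired values, or `NULL` when `x` and
#'   `y` are vectors.
#' @param x,y column names (tidy-select style strings) or numeric vectors of
#'   ipsilateral / contralateral values.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return a one-row tibble of class `calcimorph_test`: `statistic`
#'   (V, sum of positive signed ranks), `p_value`, `method`, `n_effective`,
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(data = NULL, x, y,
                                 mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!is.null(data)) {
    x <- data[[x]]
    y <- data[[y]]
  }
  if (!length(x) || length(x) != length(y)) stop("need paired samples")
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  if (!length(d)) stop("no complete pairs")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(test_result(statistic = 0, p_value = 1,
                       method = "Wilcoxon signed rank (degenerate)",
                       n_effective = 0L, degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(r))
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = n <= 25 && (!ties || n <= 20))
  if (use_exact && ties && n > 20)
    stop("exact mode with ties is limited to 20 informative pairs")
  if (use_exact) {
    p <- if (!ties) exact_signrank_p(v, n) else enum_signrank_p(v, r)
    method <- "Wilcoxon signed rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed rank (normal approximation)"
  }
  test_result(statistic = v, p_value = p, method = method,
              n_effective = n, degenerate = FALSE)
}

# Exact two-sided p for integer ranks 1..n via the sign-assignment
# convolution (counts of subsets of {1..n} by sum).
exact_signrank_p <- function(v, n) {
  maxw <- n * (n + 1) / 2
  counts <- numeric(maxw + 1)
  counts[1] <- 1
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), counts[seq_len(maxw + 1 - k)])
    counts <- counts + shifted
  }
  pmf <- counts / 2^n
  lower <- sum(pmf[seq_len(floor(v) + 1)])
  upper <- sum(pmf[(ceiling(v) + 1):(maxw + 1)])
  min(1, 2 * min(lower, upper))
}

# Exact two-sided p for arbitrary (tie-averaged) ranks by full enumeration.
enum_signrank_p <- function(v, r) {
  n <- length(r)
  sums <- numeric(1)
  for (k in seq_len(n)) sums <- c(sums, sums + r[k])
  tot <- sum(r)
  lower <- mean(sums <= v + 1e-9)
  upper <- mean(sums >= v - 1e-9)
  min(1, 2 * min(lower, upper))
}

#' Chi-squared test on a contingency table
#'
#' Pearson chi-squared test (wrapping [stats::chisq.test()]); Yates
#' continuity correction is applied by default for 2x2 tables, matching the
#' standard report of categorical side-by-side comparisons.
#'
#' @param table a counts matrix (at least 2x2, non-negative integers).
#' @param yates apply the continuity correction (2x2 only).
#' @return a one-row tibble of class `calcimorph_test`.
#' @export
chi_square <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("need at least a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total: chi-squared test undefined")
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
              method = unname(ht$method),
              n_effective = sum(table), degenerate = FALSE,
              df = unname(ht$parameter))
}

test_result <- function(statistic, p_value, method, n_effective,
                        degenerate = FALSE, df = NA_real_) {
  out <- tibble::tibble(statistic = statistic, p_value = p_value,
                        method = method, n_effective = as.integer(n_effective),
                        df = df, degenerate = degenerate)
  class(out) <- c("calcimorph_test", class(out))
  out
}

#' Intraclass correlation, two-way model, absolute agreement
#'
#' Single-measurement absolute-agreement ICC from the two-way ANOVA mean
#' squares, `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the
#' 95 percent confidence interval from the F-distribution method for this
#' coefficient. The consistency form and the average-measure form are
#' reported alongside for transparency; systematic rater bias lowers the
#' absolute-agreement coefficient but not the consistency one.
#'
#' @param data data frame in long format with columns named by `subject`,
#'   `rater`, `value`, or a subjects x raters numeric matrix.
#' @param subject,rater,value column names when `data` is a data frame.
#' @param conf_level confidence level for the interval.
#' @return a one-row tibble of class `icc_result`: `icc`, `ci_low`,
#'   `ci_high`, `icc_consistency`, `icc_avg`, `msr`, `msc`, `mse`,
#'   `n_subjects`, `n_raters`, `model`, `degenerate`.
#' @export
icc_absolute_agreement <- function(data, subject = "subject", rater = "rater",
                                   value = "value", conf_level = 0.95) {
  if (is.matrix(data)) {
    m <- data
  } else {
    w <- tidyr::pivot_wider(
      dplyr::select(tibble::as_tibble(data),
                    subject = dplyr::all_of(subject),
                    rater = dplyr::all_of(rater),
                    value = dplyr::all_of(value)),
      names_from = "rater", values_from = "value")
    m <- as.matrix(w[, -1, drop = FALSE])
  }
  if (anyNA(m)) stop("rater matrix must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  degenerate <- msr < 1e-300 || ss_rows < 1e-12 * max(ss_tot, 1)
  icc_a <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  icc_avg <- (msr - mse) / (msr + (msc - mse) / n)
  alpha <- 1 - conf_level
  if (mse <= 0 && msc <= msr * 1e-12) {
    # perfect agreement: no error and no rater variance
    lo <- hi <- icc_a
  } else {
    a <- (k * icc_a) / (n * (1 - icc_a))
    b <- 1 + (k * icc_a * (n - 1)) / (n * (1 - icc_a))
    if (!is.finite(a) || !is.finite(b)) {
      lo <- hi <- icc_a
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    }
  }
  out <- tibble::tibble(
    icc = icc_a, ci_low = lo, ci_high = hi,
    icc_consistency = icc_c, icc_avg = icc_avg,
    msr = msr, msc = msc, mse = mse,
    n_subjects = n, n_raters = k,
    model = "two-way, single measurement, absolute agreement",
    degenerate = degenerate)
  class(out) <- c("icc_result", class(out))
  out
}

#' Median and interquartile range summary
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7), the convention used for all reported IQRs.
#'
#' @param values numeric vector (NAs dropped).
#' @return tibble: `median`, `q1`, `q3`, `iqr`, `n`.
#' @export
summarize_median_iqr <- function(values) {
  values <- values[!is.na(values)]
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
                 n = length(values))
}

#' Side-by-side comparison report of per-artery metrics
#'
#' Produces a per-variable report in the layout of a morphometry comparison
#' table: total / ipsilateral / contralateral medians with IQRs and a paired
#' Wilcoxon signed-rank p per continuous variable, or frequencies and a
#' chi-squared p per categorical variable.
#'
#' @param metrics data frame with one row per artery: a patient id column, a
#'   side column coded `"ipsilateral"` / `"contralateral"`, and metric
#'   columns (numeric or categorical).
#' @param patient_id,side names of the id and side columns.
#' @param alpha significance level carried into the report.
#' @param p_adjust `"none"` (default, one test per variable at `alpha`) or
#'   `"holm"`.
#' @return a tibble of class `comparison_report`, one row per variable:
#'   `variable`, `type`, `total`, `ipsilateral`, `contralateral` (formatted
#'   summaries), `p_value`, `significant`.
#' @export
compare_table <- function(metrics, patient_id = "patient_id", side = "side",
                          alpha = 0.05, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  metrics <- tibble::as_tibble(metrics)
  stopifnot(patient_id %in% names(metrics), side %in% names(metrics))
  sides <- metrics[[side]]
  if (!all(sides %in% c("ipsilateral", "contralateral")))
    stop("side column must be coded ipsilateral/contralateral")
  vars <- setdiff(names(metrics), c(patient_id, side))
  fmt <- function(s) sprintf("%.1f [%.1f, %.1f]", s$median, s$q1, s$q3)
  rows <- lapply(vars, function(vn) {
    v <- metrics[[vn]]
    if (is.numeric(v)) {
      wide <- tidyr::pivot_wider(
        metrics[, c(patient_id, side, vn)],
        names_from = dplyr::all_of(side), values_from = dplyr::all_of(vn))
      ok <- stats::complete.cases(wide$ipsilateral, wide$contralateral)
      tt <- wilcoxon_signed_rank(x = wide$ipsilateral[ok],
                                 y = wide$contralateral[ok])
      tibble::tibble(
        variable = vn, type = "continuous",
        total = fmt(summarize_median_iqr(v)),
        ipsilateral = fmt(summarize_median_iqr(v[sides == "ipsilateral"])),
        contralateral = fmt(summarize_median_iqr(v[sides == "contralateral"])),
        p_value = tt$p_value)
    } else {
      tab <- table(factor(v), sides)
      p <- tryCatch(chi_square(unclass(tab))$p_value,
                    error = function(e) NA_real_)
      fmtcat <- function(col) {
        cnt <- tab[, col]
        paste(sprintf("%s %d (%.1f%%)", rownames(tab), cnt,
                      100 * cnt / sum(cnt)), collapse = "; ")
      }
      tot <- table(factor(v))
      tibble::tibble(
        variable = vn, type = "categorical",
        total = paste(sprintf("%s %d (%.1f%%)", names(tot), as.integer(tot),
                              100 * as.integer(tot) / sum(tot)),
                      collapse = "; "),
        ipsilateral = fmtcat("ipsilateral"),
        contralateral = fmtcat("contralateral"),
        p_value = p)
    }
  })
  out <- dplyr::bind_rows(rows)
  if (p_adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  class(out) <- c("comparison_report", class(out))
  out
}

#' Inter-rater agreement table
#'
#' One absolute-agreement ICC row per metric from a long rater table.
#'
#' @param ratings data frame with columns `subject_id`, `rater_id`, and one
#'   column per metric.
#' @param subject,rater id column names.
#' @return tibble: `variable`, `icc`, `ci_low`, `ci_high`, plus the
#'   auxiliary coefficients from [icc_absolute_agreement()].
#' @export
rater_agreement <- function(ratings, subject = "subject_id",
                            rater = "rater_id") {
  ratings <- tibble::as_tibble(ratings)
  vars <- setdiff(names(ratings), c(subject, rater))
  purrr::map_dfr(vars, function(vn) {
    res <- icc_absolute_agreement(ratings, subject = subject, rater = rater,
                                  value = vn)
    dplyr::mutate(res, variable = vn, .before = 1)
  })
}
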