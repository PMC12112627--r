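# independent brute-force oracle: two-sided signed-rank p by explicit
# enumeration of all 2^n sign assignments
brute_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- signs %*% r
  min(1, 2 * min(mean(sums <= v + 1e-9), mean(sums >= v - 1e-9)))
}

test_that("exact signed-rank p matches the textbook example", {
  res <- wilcoxon_signed_rank(x = c(2, 3, 4, 5, 6), y = rep(1, 5),
                              mode = "exact")
  expect_equal(res$p_value, 2 / 32, tolerance = 1e-12)
  expect_equal(res$statistic, 15)
})

test_that("all-zero differences give p = 1 with a degenerate flag", {
  res <- wilcoxon_signed_rank(x = 1:4, y = 1:4)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  expect_equal(res$n_effective, 0)
  expect_error(wilcoxon_signed_rank(x = numeric(0), y = numeric(0)))
})

test_that("exact p matches brute-force enumeration over random inputs", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 2) next
    res <- wilcoxon_signed_rank(x = d, y = rep(0, length(d)),
                                mode = "exact")
    expect_equal(res$p_value, brute_signrank_p(d), tolerance = 1e-10)
  }
})

test_that("exact p agrees with stats::wilcox.test when it can be exact", {
  set.seed(7)
  for (i in 1:50) {
    d <- rnorm(15)
    ours <- wilcoxon_signed_rank(x = d, y = rep(0, 15), mode = "exact")
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("exact and approximate paths agree on moderate samples", {
  set.seed(11)
  for (i in 1:20) {
    d <- rnorm(20, mean = 0.3)
    pe <- wilcoxon_signed_rank(x = d, y = rep(0, 20), mode = "exact")$p_value
    pa <- wilcoxon_signed_rank(x = d, y = rep(0, 20), mode = "approx")$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("data-frame-first interface pipes through column names", {
  df <- tibble::tibble(ipsi = c(1, 2, 3, 5), contra = c(2, 2, 1, 4))
  res <- wilcoxon_signed_rank(df, "ipsi", "contra")
  expect_s3_class(res, "calcimorph_test")
  expect_equal(res$n_effective, 3)  # one zero difference dropped
})

test_that("chi-squared on the cohort sex table reproduces p = 0.01", {
  res <- chi_square(matrix(c(24, 11, 26, 39), 2, 2))
  expect_equal(round(res$p_value, 2), 0.01)
})

test_that("chi-squared basics: identical rows, hand formula, errors", {
  res <- chi_square(matrix(c(10, 10, 5, 5), 2, 2), yates = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # hand formula for 2x2 without correction
  a <- 12; b <- 5; cc <- 7; d <- 20
  n <- a + b + cc + d
  hand <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  res2 <- chi_square(matrix(c(a, cc, b, d), 2, 2), yates = FALSE)
  expect_equal(res2$statistic, hand, tolerance = 1e-12)
  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2, 2)), "marginal")
  expect_error(chi_square(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
})

test_that("chi-squared is invariant under row and column permutation", {
  m <- matrix(c(8, 15, 22, 5, 13, 9), 2, 3)
  p0 <- chi_square(m)$p_value
  expect_equal(chi_square(m[2:1, ])$p_value, p0, tolerance = 1e-12)
  expect_equal(chi_square(m[, c(3, 1, 2)])$p_value, p0, tolerance = 1e-12)
})

test_that("ICC matches an independent ANOVA mean-squares oracle", {
  set.seed(3)
  m <- matrix(rnorm(30, rep(rnorm(10, 50, 10), 3), 2), 10, 3)
  res <- icc_absolute_agreement(m)
  # oracle: mean squares from aov on the long layout
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:10, 3)),
                     rater = factor(rep(1:3, each = 10)))
  ms <- anova(stats::aov(y ~ subj + rater, data = long))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 10; k <- 3
  oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(res$icc, oracle, tolerance = 1e-10)
  expect_equal(res$msr, msr, tolerance = 1e-10)
  expect_equal(res$mse, mse, tolerance = 1e-10)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
})

test_that("identical raters give ICC 1; rater bias lowers absolute agreement", {
  m <- matrix(rep(seq(1, 10), 3), 10, 3)
  expect_equal(icc_absolute_agreement(m)$icc, 1)
  mb <- cbind(1:10, (1:10) + 4, (1:10) - 2) * 1.0
  res <- icc_absolute_agreement(mb)
  expect_lt(res$icc, res$icc_consistency)
  # joint affine rescaling leaves the ICC unchanged
  res2 <- icc_absolute_agreement(mb * 3 + 7)
  expect_equal(res2$icc, res$icc, tolerance = 1e-12)
})

test_that("ICC flags zero between-subject variance as degenerate", {
  m <- matrix(5, 6, 3) + matrix(rep(c(0, 1, -1), each = 6), 6, 3)
  res <- icc_absolute_agreement(m)
  expect_true(res$degenerate)
  expect_error(icc_absolute_agreement(matrix(1:3, 3, 1)), "2 subjects")
})

test_that("simulated high-agreement raters land in [0.9, 1]", {
  set.seed(19)
  iccs <- replicate(200, {
    subj <- rnorm(10, 0, 10)
    m <- matrix(rnorm(30, rep(subj, 3), 1), 10, 3)
    icc_absolute_agreement(m)$icc
  })
  expect_true(all(iccs > 0.9 & iccs <= 1))
})

test_that("median/IQR uses type-7 quartiles", {
  s <- summarize_median_iqr(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$q1, 1.75)
  expect_equal(s$q3, 3.25)
})

test_that("long-format rater tables pivot into per-metric ICC rows", {
  set.seed(5)
  subj <- rep(1:10, each = 3)
  ratings <- tibble::tibble(
    subject_id = subj, rater_id = rep(c("A", "B", "C"), 10),
    ti = rnorm(30, rep(rnorm(10, 0.7, 0.2), each = 3), 0.01),
    count = rnorm(30, rep(rpois(10, 4), each = 3), 0.1))
  tab <- rater_agreement(ratings)
  expect_equal(tab$variable, c("ti", "count"))
  expect_true(all(tab$icc > 0.9))
  # three identical raters: all ICC exactly 1
  same <- tibble::tibble(subject_id = subj,
                         rater_id = rep(c("A", "B", "C"), 10),
                         m = rep(rnorm(10), each = 3))
  expect_equal(rater_agreement(same)$icc, 1)
})

test_that("comparison report has the side-by-side shape and sane rows", {
  set.seed(23)
  n <- 40
  base <- rnorm(n, 4, 1)
  metrics <- tibble::tibble(
    patient_id = rep(1:n, 2),
    side = rep(c("ipsilateral", "contralateral"), each = n),
    calc_count = c(rpois(n, 4), rpois(n, 4)) + 0,
    severity = sample(c("<30", "30-50", ">50"), 2 * n, replace = TRUE))
  rep <- compare_table(metrics)
  expect_equal(rep$variable, c("calc_count", "severity"))
  expect_equal(rep$type, c("continuous", "categorical"))
  expect_true(all(!is.na(rep$p_value)))
  # identically generated sides: no systematic rejections expected here
  expect_true(all(rep$p_value > 0.001))
  expect_error(compare_table(dplyr::mutate(metrics, side = "up")), "coded")
})
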