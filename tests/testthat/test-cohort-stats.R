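test_that("normality screening routes normal and skewed data correctly", {
  set.seed(61)
  xn <- stats::rnorm(200); yn <- stats::rnorm(200, 0.2)
  expect_equal(choose_test(xn, yn)$test, "t_test")
  xl <- stats::rlnorm(200, sdlog = 1); yl <- stats::rlnorm(200, sdlog = 1)
  expect_equal(choose_test(xl, yl)$test, "mann_whitney")
  expect_warning(res <- choose_test(rep(5, 10), stats::rnorm(10)),
                 "degenerate")
  expect_equal(res$test, "mann_whitney")
  expect_error(choose_test(1:2, 1:5), "at least 3")
})

test_that("Mann-Whitney agrees with exact enumeration for small groups", {
  set.seed(71)
  for (sizes in list(c(3, 5), c(4, 4), c(6, 5), c(8, 7), c(8, 8))) {
    x <- stats::rnorm(sizes[1]); y <- stats::rnorm(sizes[2], 0.8)
    p_pkg <- suppressWarnings(
      stats::wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(p_pkg, mw_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("Fisher's exact p matches the hypergeometric tail computation", {
  tab <- matrix(c(20, 16, 11, 23), 2, byrow = TRUE)
  # enumerate all tables with the observed margins; two-sided p sums the
  # probabilities of tables no more likely than the observed one
  m <- 20 + 16; n <- 11 + 23; k <- 20 + 11
  probs <- stats::dhyper(0:k, m, n, k)
  p_hand <- sum(probs[probs <= stats::dhyper(20, m, n, k) * (1 + 1e-7)])
  expect_equal(stats::fisher.test(tab)$p.value, p_hand, tolerance = 1e-10)
})

test_that("group comparison summarizes, tests and reports per variable", {
  sim <- simulate_cohort(sim_config(seed = 12, n_mild = 18, n_modsev = 18))
  coh <- compute_indices(sim$cohort)
  gt <- compare_groups(coh, c("age", "bmi", "cl_total", "sex", "tanner"))
  expect_equal(nrow(gt), 5)
  expect_true(all(gt$p >= 0 & gt$p <= 1))
  expect_true(all(gt$test[gt$type == "categorical"] %in%
                    c("fisher", "chi_square")))
  expect_true("p_bh" %in% names(gt))
  expect_equal(attr(gt, "n_tests"), 5)
  expect_error(compare_groups(coh, "nope"), "not found")
})

test_that("identical groups give null p-values", {
  vals <- c(3.2, 4.8, 1.1, 7.5, 2.2, 5.9, 6.3, 0.7)
  ins <- lapply(rep(list(rep(100, 9)), 16), identity)
  coh <- curves_cohort(ins, ahi = c(rep(3, 8), rep(8, 8)))
  coh$metric <- c(vals, vals)   # copied values across groups
  gt <- compare_groups(coh, "metric")
  expect_gt(gt$p, 0.99)
  cv <- pointwise_curve_compare(coh, "insulin")
  expect_true(all(cv$p[!is.na(cv$p)] > 0.99))
})

test_that("curve comparison localizes a targeted shift and keeps shape", {
  set.seed(41)
  base <- c(60, 200, 320, 380, 330, 250, 180, 130, 90)
  hits <- replicate(50, {
    mk <- function(n, shift60) lapply(seq_len(n), function(i) {
      f <- exp(stats::rnorm(1, 0, 0.15))
      v <- base * f * exp(stats::rnorm(9, 0, 0.05))
      if (shift60) v[ogtt_grid() == 60] <- v[ogtt_grid() == 60] * 1.5
      v
    })
    coh <- curves_cohort(c(mk(12, FALSE), mk(12, TRUE)),
                         ahi = c(rep(3, 12), rep(8, 12)))
    cv <- pointwise_curve_compare(coh, "insulin")
    cv$time[which.min(cv$p)]
  })
  expect_equal(stats::median(hits), 60)
  # shape: one row per grid point, medians and IQRs filled
  coh1 <- curves_cohort(lapply(1:8, function(i) base + i),
                        ahi = c(rep(3, 4), rep(8, 4)))
  cv1 <- pointwise_curve_compare(coh1, "insulin")
  expect_equal(cv1$time, ogtt_grid())
  expect_true(all(is.finite(cv1$median_mild)))
})

test_that("timepoints with too few subjects are skipped with a note", {
  ins <- lapply(1:5, function(i) rep(100 + i, 9))
  coh <- curves_cohort(ins, ahi = c(3, 3, 3, 8, 8))
  cv <- pointwise_curve_compare(coh, "insulin")
  expect_true(all(is.na(cv$p)))
  expect_match(cv$note[1], "fewer than 3")
})

test_that("Spearman correlations match the hand rank computation", {
  # 5 pairs with one tie in the index
  ahi <- c(1.5, 3, 6, 9, 14)
  idx <- c(10, 12, 12, 20, 25)
  coh <- curves_cohort(rep(list(rep(100, 9)), 5), ahi = ahi)
  coh$metric <- idx
  ct <- spearman_vs_ahi(coh, "metric")
  rho_hand <- stats::cor(rank(ahi), rank(idx))   # average ranks for ties
  expect_equal(ct$spearman_r, rho_hand, tolerance = 1e-12)
  expect_equal(ct$n, 5L)
  # monotone and anti-monotone limits
  coh$up <- ahi * 2 + 1
  coh$down <- -ahi
  both <- spearman_vs_ahi(coh, c("up", "down"))
  expect_equal(both$spearman_r, c(1, -1))
  coh$flat <- rep(1, 5)
  expect_match(spearman_vs_ahi(coh, "flat")$note, "constant")
})

test_that("Spearman p-values are calibrated under the null", {
  set.seed(83)
  reps <- 600
  # index independent of AHI at the study's cohort size and AHI mixture
  ps <- replicate(reps, {
    a <- c(stats::runif(36, 1.1, 5), stats::runif(34, 5.1, 25))
    x <- stats::rnorm(70)
    suppressWarnings(stats::cor.test(a, x, method = "spearman",
                                     exact = FALSE)$p.value)
  })
  fpr <- mean(ps < 0.05)
  expect_gt(fpr, 0.03)
  expect_lt(fpr, 0.07)
})

test_that("the bundled report is deterministic given cohort and config", {
  sim <- simulate_cohort(sim_config(seed = 33, n_mild = 10, n_modsev = 10))
  coh <- compute_indices(sim$cohort)
  r1 <- cohort_stats_report(coh)
  r2 <- cohort_stats_report(coh)
  expect_identical(r1$group_table, r2$group_table)
  expect_identical(r1$corr_table, r2$corr_table)
  expect_true(all(r1$corr_table$spearman_r >= -1 &
                    r1$corr_table$spearman_r <= 1))
})
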