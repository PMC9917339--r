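test_that("cohort draws respect the lognormal dispersion model", {
  med <- cohort_preset("healthy")
  # zero dispersion: every cell equals the medians
  cells0 <- draw_cohort(cohort_config(med, dispersion_sigma = 0,
                                      n_cells = 5), seed = 1)
  for (cl in cells0) {
    expect_equal(cl$E_app, med$E_app)
    expect_equal(cl$E0, med$E0)
    expect_equal(cl$alpha, med$alpha)
    expect_equal(cl$mu, med$mu)
  }
  # determinism
  c1 <- draw_cohort(cohort_config(med, 0.5, 20), seed = 33)
  c2 <- draw_cohort(cohort_config(med, 0.5, 20), seed = 33)
  expect_identical(c1, c2)
  # sample median of E_app near the configured median for n = 90
  cells <- draw_cohort(cohort_config(med, dispersion_sigma = 0.5,
                                     n_cells = 90), seed = 5)
  e <- vapply(cells, function(x) x$E_app, numeric(1))
  expect_lt(abs(median(e) / 3345 - 1), 0.15)
  # lognormal median identity at large n: median(ln E0) ~ ln(median E0)
  big <- draw_cohort(cohort_config(med, 0.5, 10000), seed = 6)
  e0 <- vapply(big, function(x) x$E0, numeric(1))
  expect_lt(abs(median(log(e0)) - log(med$E0)), 3 * 0.5 / sqrt(10000) * 2)
})

test_that("cohort summaries report medians, quartiles and log histograms", {
  rec <- data.frame(label = "healthy", E0 = 3000, alpha = 0.1)
  s1 <- summarize_cohort(rec)
  expect_equal(s1$stats$median[s1$stats$parameter == "E0"], 3000)
  expect_equal(s1$stats$p25, s1$stats$median)

  set.seed(2)
  cells <- draw_cohort(cohort_config(cohort_preset("healthy"), 0.4, 90),
                       seed = 9)
  rec <- data.frame(label = "healthy",
                    E0 = vapply(cells, function(x) x$E0, numeric(1)))
  s <- summarize_cohort(rec)
  expect_lt(abs(s$stats$median / 3308 - 1), 0.10)
  expect_true(s$stats$p25 <= s$stats$median &&
                s$stats$median <= s$stats$p75)
  h <- s$histograms[["healthy.E0"]]
  expect_equal(sum(h$counts), 90)
  # duplicating every record leaves the median unchanged exactly; the
  # interpolated quartiles move by at most one inter-order-statistic gap
  s2 <- summarize_cohort(rbind(rec, rec))
  expect_equal(s2$stats$median, s$stats$median)
  expect_equal(s2$stats$p25, s$stats$p25, tolerance = 0.01)
  expect_equal(s2$stats$p75, s$stats$p75, tolerance = 0.01)
})

test_that("exact rank-sum p-values match the closed-form null distribution", {
  # derived example: a = 1,2,3 vs b = 10,11,12 -> two-sided p = 2/20
  expect_equal(rank_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  # identical samples -> maximal p
  expect_equal(rank_test(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  # rank invariance under common shifts
  set.seed(3)
  a <- rnorm(5); b <- rnorm(6)
  expect_equal(rank_test(a, b)$p_value, rank_test(a + 7, b + 7)$p_value)
  # exhaustive cross-check against the Wilcoxon null CDF (independent
  # shift-algorithm implementation in stats) for tie-free samples
  for (na in 2:6) {
    for (nb in 2:6) {
      x <- rnorm(na); y <- rnorm(nb)
      mine <- rank_test(x, y)
      expect_true(mine$exact)
      oracle <- stats::wilcox.test(x, y, exact = TRUE)$p.value
      expect_equal(mine$p_value, oracle, tolerance = 1e-12,
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  }
})

test_that("paired signed-rank enumeration matches the stats oracle", {
  set.seed(4)
  for (n in c(4, 6, 8)) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- rank_test(x, y, mode = "paired")
    oracle <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(mine$p_value, oracle, tolerance = 1e-12)
  }
  expect_error(rank_test(1:3, 1:4, mode = "paired"), "equal lengths")
  expect_equal(rank_test(1:5, 1:5, mode = "paired")$p_value, 1)
})

test_that("large-sample approximation agrees with wilcox.test", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(25, 0.3)
  mine <- rank_test(x, y)
  expect_false(mine$exact)
  oracle <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(mine$p_value, oracle, tolerance = 1e-10)
})

test_that("Cohen's d follows its definition and conventions", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means one pooled SD apart -> |d| = 1
  a <- c(-1, 0, 1)
  b <- a + sd(a)
  expect_equal(abs(cohens_d(b, a)), 1)
  # sign convention: first minus second
  expect_gt(cohens_d(b, a), 0)
  # affine invariance
  set.seed(6)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  expect_equal(cohens_d(2 * x + 3, 2 * y + 3), cohens_d(x, y),
               tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled SD")
})

test_that("significance marks apply strict thresholds", {
  expect_equal(significance_marks(0.005, 0.7), "*##")
  expect_equal(significance_marks(0.02, 0.1), "")
  expect_equal(significance_marks(0.005, 0.3), "*#")
  # boundaries are excluded as printed
  expect_equal(significance_marks(0.01, 0.5), "")
  expect_equal(significance_marks(0.5, 0.2), "")
  expect_equal(significance_marks(0.5, 1.0), "")
  expect_equal(significance_marks(0.009999, 0.499), "*#")
  expect_equal(significance_marks(0.5, -0.7), "##")
})

test_that("pairwise cohort comparisons annotate all pairs", {
  set.seed(7)
  rec <- data.frame(
    label = rep(c("healthy", "scar", "dupuytren"), each = 30),
    E = c(rlnorm(30, log(3345), 0.4), rlnorm(30, log(3940), 0.4),
          rlnorm(30, log(5364), 0.4)))
  tests <- pairwise_tests(rec, "E")
  expect_equal(nrow(tests), 3L)
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
  expect_identical(tests$annotation,
                   significance_marks(tests$p_value, tests$cohens_d))
})
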