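test_that("exact signed-rank test reproduces enumerable anchor cases", {
  # all 8 differences positive: smallest achievable two-sided exact p
  r <- wilcoxon_signed_rank_exact(2:9, 1:8)
  expect_equal(r$statistic, 36)
  expect_equal(r$p_value, 2 / 256)
  expect_equal(r$method, "exact_enumeration")

  # single nonzero difference: both tails are 1/2
  r1 <- wilcoxon_signed_rank_exact(2, 1)
  expect_equal(r1$p_value, 1)
  expect_equal(r1$n_effective, 1)

  # identical vectors: degenerate, p = 1
  rd <- wilcoxon_signed_rank_exact(1:5, 1:5)
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 1)
  expect_equal(rd$n_effective, 0)

  expect_error(wilcoxon_signed_rank_exact(1:3, 1:4), "equal length")
})

test_that("exact p equals brute-force enumeration, with and without ties", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    r <- wilcoxon_signed_rank_exact(x, y)
    expect_equal(r$p_value, oracle_wsr_p(x - y), tolerance = 1e-12)
  }
  # tied absolute differences exercise the midrank path
  for (i in 1:25) {
    n <- sample(3:9, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)
    r <- wilcoxon_signed_rank_exact(d, rep(0, n))
    expect_equal(r$p_value, oracle_wsr_p(d), tolerance = 1e-12)
  }
})

test_that("tie-free exact p agrees with the distribution-function reference", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:11, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- wilcoxon_signed_rank_exact(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = TRUE))
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(r$statistic, unname(ref$statistic))
  }
})

test_that("large-sample path uses the tie- and continuity-corrected normal approximation", {
  set.seed(13)
  x <- rnorm(20, 0.3); y <- rnorm(20)
  r <- wilcoxon_signed_rank_exact(x, y)
  expect_equal(r$method, "normal_approximation")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)

  # forced-approximation p stays close to the exact p near n = 12
  x <- rnorm(12, 0.5); y <- rnorm(12)
  exact <- wilcoxon_signed_rank_exact(x, y)$p_value
  approx <- wilcoxon_signed_rank_exact(x, y, exact_limit = 0)$p_value
  expect_equal(approx, exact, tolerance = 0.05)
})

test_that("Pratt zero handling ranks zeros but never counts them", {
  d <- c(0, 0, 1, 2, -3, 4)
  r <- wilcoxon_signed_rank_exact(d, rep(0, 6), zero_method = "pratt")
  expect_equal(r$n_effective, 4)
  # |d| ranks with zeros: 0,0 -> 1.5; 1,2,3,4 -> 3,4,5,6
  expect_equal(r$statistic, 3 + 4 + 6)
})

test_that("BH adjustment matches direct step-up computation", {
  expect_equal(bh_adjust(c(0.0078125, 0.0078125, 0.0078125, 0.5)),
               c(0.0104166666666667, 0.0104166666666667, 0.0104166666666667, 0.5),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(5)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    # monotone in the ordered raw p-values
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("Friedman test reproduces hand-computed cases", {
  # identical ordering in 3 blocks of 3 treatments
  m <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  f <- friedman_test(m)
  expect_equal(f$statistic, 6)
  expect_equal(f$kendalls_w, 1)
  expect_equal(f$df, 2)

  # all values equal within each block: no signal
  m0 <- rbind(c(2, 2, 2), c(5, 5, 5))
  f0 <- friedman_test(m0)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$kendalls_w, 0)

  # two blocks, two treatments, perfect agreement
  f2 <- friedman_test(rbind(c(1, 2), c(3, 4)))
  expect_equal(f2$kendalls_w, 1)

  expect_error(friedman_test(rbind(c(1, 2))), "2 complete blocks")
})

test_that("Friedman chi-square matches base R and the first-principles oracle", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(4:10, 1); k <- sample(3:5, 1)
    m <- matrix(rnorm(n * k), n, k)
    if (i %% 2 == 0) m <- round(m)  # induce ties
    f <- friedman_test(m)
    expect_equal(f$statistic, oracle_friedman_chi2(m), tolerance = 1e-12)
    ref <- stats::friedman.test(m)
    expect_equal(f$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(f$p_value, ref$p.value, tolerance = 1e-10)
    expect_true(f$kendalls_w >= 0 && f$kendalls_w <= 1 + 1e-12)
  }
})

test_that("Kendall's W is 1 exactly for concordant untied blocks, below 1 otherwise", {
  set.seed(8)
  base_order <- rnorm(5)
  concordant <- t(replicate(6, base_order + runif(1, 1, 10) * 0 + rnorm(1)))
  # monotone transform per block preserves ranks
  concordant <- t(apply(concordant, 1, function(r) r * 2 + 1))
  expect_equal(friedman_test(concordant)$kendalls_w, 1)

  discordant <- rbind(base_order, rev(base_order), base_order + rnorm(5))
  expect_lt(friedman_test(discordant)$kendalls_w, 1)
})

test_that("incomplete blocks are dropped with a message", {
  m <- matrix(rnorm(20), 5, 4)
  m[2, 3] <- NA
  expect_message(f <- friedman_test(m), "1 incomplete")
  expect_equal(f$n_blocks, 4)
  expect_equal(f$n_dropped, 1)
})

test_that("condition comparisons compose the exact test and BH across the family", {
  cultures <- paste0("DT", 1:8)
  m <- cbind(control_72h = seq(80, 45, length.out = 8),
             se5 = seq(60, 30, length.out = 8),
             se15 = seq(20, 6, length.out = 8),
             se30 = seq(5, 1, length.out = 8),
             gem1 = seq(80, 45, length.out = 8))
  rownames(m) <- cultures
  res <- compare_conditions(m, "control_72h")
  expect_equal(nrow(res), 4)
  sel <- res$comparison != "control_72h vs gem1"
  expect_equal(res$p_value[sel], rep(2 / 256, 3))
  expect_equal(res$p_adjusted[sel], rep(4 * (2 / 256) / 3, 3), tolerance = 1e-12)
  gem <- res[!sel, ]
  expect_true(gem$degenerate)
  expect_equal(gem$p_value, 1)

  # pairwise-complete: one missing culture shrinks that test to n = 7
  m2 <- m
  m2[3, "se15"] <- NA
  res2 <- compare_conditions(m2, "control_72h")
  expect_equal(res2$n_total[res2$comparison == "control_72h vs se15"], 7)

  # control against itself is degenerate
  res3 <- compare_conditions(m, "control_72h",
                             family = c("control_72h", "se30"))
  self <- res3[res3$comparison == "control_72h vs control_72h", ]
  expect_true(self$degenerate)
  expect_equal(self$p_value, 1)

  expect_error(compare_conditions(m, "missing_ctrl"), "control column")
})

test_that("normality screen reports a Shapiro-Wilk result descriptively", {
  set.seed(3)
  res <- normality_screen(matrix(rexp(40), 8, 5))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_null(normality_screen(matrix(1, 4, 4)))
})
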