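test_that("t-test on identical groups gives statistic 0 and agrees with stats::t.test", {
  res <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  withr::local_seed(2)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  res2 <- compare_groups(a, b, test = "t")
  ref <- t.test(a, b)
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(res2$p_value, ref$p.value)
  pooled <- compare_groups(a, b, test = "t", var_equal = TRUE)
  expect_equal(pooled$p_value, t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("exact Mann-Whitney matches the printed small-sample case", {
  res <- compare_groups(c(1, 2), c(3, 4), test = "mann_whitney_u",
                        alternative = "less")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 6)   # 1 of choose(4,2) = 6 assignments
  expect_true(res$exact)
})

test_that("exact Mann-Whitney equals full permutation enumeration for small n", {
  withr::local_seed(8)
  for (i in 1:6) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- round(rnorm(n1), 2); b <- round(rnorm(n2, 0.8), 2)
    for (alt in c("two.sided", "less", "greater")) {
      got <- mann_whitney_u(a, b, alternative = alt)
      expect_equal(got$p_value, bf_mann_whitney(a, b, alt))
    }
  }
  # with ties (enumeration handles midranks)
  a <- c(1, 2, 2, 3); b <- c(2, 3, 4)
  expect_equal(mann_whitney_u(a, b)$p_value, bf_mann_whitney(a, b))
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free data", {
  withr::local_seed(13)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(7, 0.4)
    got <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("large-sample Mann-Whitney falls back to the tie-corrected normal approximation", {
  withr::local_seed(3)
  a <- rnorm(30); b <- rnorm(35, 0.3)
  got <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_false(got$exact)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("signed-rank vs 1 enumerates sign patterns exactly", {
  # all four values above 1, tied magnitudes: 1 of 2^4 sign patterns reaches
  # V = 10, two-sided doubles it
  res <- compare_groups(c(2, 2, 2, 2), test = "wilcoxon_signed_rank_vs_1")
  expect_equal(res$statistic, 10)
  expect_equal(res$p_value, 2 / 16)

  # tie-free case agrees with wilcox.test's exact distribution
  withr::local_seed(4)
  x <- 1 + rnorm(9, 0.3)
  got <- signed_rank_exact(x, mu = 1)
  ref <- wilcox.test(x, mu = 1, exact = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

test_that("group swap flips the statistic's orientation but keeps p", {
  withr::local_seed(5)
  a <- rnorm(8); b <- rnorm(8, 1)
  for (tst in c("t", "mann_whitney_u")) {
    r1 <- compare_groups(a, b, test = tst)
    r2 <- compare_groups(b, a, test = tst)
    expect_equal(r1$p_value, r2$p_value)
    if (tst == "t") {
      expect_equal(r1$statistic, -r2$statistic)
    } else {
      # U_a + U_b = n1 * n2
      expect_equal(r1$statistic + r2$statistic, 64)
    }
  }
})

test_that("type-I error under the null stays within binomial bounds", {
  withr::local_seed(99)
  n_sim <- 1000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    a <- rnorm(8); b <- rnorm(8)
    if (compare_groups(a, b, test = "t")$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  # 99% binomial bounds around 0.05 for 1000 simulations
  bounds <- qbinom(c(0.005, 0.995), n_sim, 0.05)
  expect_gte(rejections, bounds[1])
  expect_lte(rejections, bounds[2])
})

test_that("kruskal-wallis and two-way ANOVA wrap the standard fits", {
  withr::local_seed(6)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  res <- compare_groups(g, test = "kruskal_wallis")
  ref <- kruskal.test(g)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  d <- expand.grid(treatment = c("ctrl", "drug"), time = c("t0", "t1"),
                   rep = 1:6)
  d$value <- rnorm(nrow(d)) + (d$treatment == "drug") * 0.8
  tab <- anova_two_way(d, value ~ treatment * time)
  expect_true(all(c("treatment", "time", "treatment:time") %in% tab$effect))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
})

test_that("group summaries report mean, SEM, median and IQR", {
  res <- compare_groups(c(1, 2, 3, 4), c(2, 4, 6, 8), test = "t")
  s <- res$summaries$a
  expect_equal(s$mean, 2.5)
  expect_equal(s$sem, sd(1:4) / 2)
  expect_equal(s$median, 2.5)
  expect_equal(unname(s$iqr), unname(quantile(1:4, c(0.25, 0.75))))
})
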