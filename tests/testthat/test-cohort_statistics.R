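test_that("Pearson correlation reproduces hand-derived values", {
  expect_equal(pearson_with_p(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_with_p(c(1, 2, 3), c(6, 4, 2))$r, -1)
  # product-moment formula by hand: sum(dx*dy) = 4, sum(dx^2) = sum(dy^2) = 5
  res <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$n, 4)
})

test_that("Pearson p-values agree with the cor.test oracle", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    mine <- pearson_with_p(x, y)
    oracle <- cor.test(x, y)
    expect_equal(mine$r, unname(oracle$estimate), tolerance = 1e-12)
    expect_equal(mine$p, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("Pearson correlation is symmetric and affine-invariant", {
  set.seed(61)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_with_p(x, y)$r, pearson_with_p(y, x)$r)
  expect_equal(pearson_with_p(3 * x + 7, y)$r, pearson_with_p(x, y)$r,
               tolerance = 1e-12)
  expect_equal(pearson_with_p(-2 * x, y)$r, -pearson_with_p(x, y)$r,
               tolerance = 1e-12)
  expect_error(pearson_with_p(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_with_p(1:4, 1:5), "equal length")
})

test_that("size bins split at 3000/6000 with an open-ended upper bin", {
  expect_equal(assign_size_bin(3000), 1L)
  expect_equal(assign_size_bin(3001), 2L)
  expect_equal(assign_size_bin(6001), 3L)
  expect_equal(assign_size_bin(19659), 3L)  # beyond the cosmetic 17,000 label
  expect_equal(assign_size_bin(c(1, 5999, 1e6)), c(1L, 2L, 3L))
  expect_error(assign_size_bin(0), "at least 1")
  # total and order-preserving
  sizes <- sort(sample(1:25000, 200))
  bins <- assign_size_bin(sizes)
  expect_true(all(!is.na(bins)))
  expect_true(all(diff(bins) >= 0))
})

test_that("ANOVA handles degenerate and two-group cases exactly", {
  flat <- anova_tukey(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(flat$F, 0)
  expect_equal(flat$p_overall, 1)
  expect_true(all(!flat$pairwise$significant))
  expect_equal(nrow(flat$pairwise), 3)  # C(3, 2)

  # two groups: overall F equals the squared pooled two-sample t statistic
  set.seed(71)
  for (i in 1:5) {
    g1 <- rnorm(sample(5:20, 1), mean = 0)
    g2 <- rnorm(sample(5:20, 1), mean = 1)
    res <- anova_tukey(list(g1 = g1, g2 = g2))
    t_stat <- t.test(g1, g2, var.equal = TRUE)$statistic
    expect_equal(res$F, unname(t_stat)^2, tolerance = 1e-10)
  }
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "at least 2 values")
  expect_error(anova_tukey(list(a = c(1, 2))), "at least 2 groups")
})

test_that("ANOVA detects a shifted group with high power", {
  set.seed(81)
  hits <- 0L
  for (i in 1:200) {
    res <- anova_tukey(list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 3)))
    if (res$p_overall < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 190)  # >= 95% of 200 replicates
})

test_that("Tukey-adjusted p-values dominate the unadjusted pairwise t", {
  set.seed(91)
  groups <- list(a = rnorm(12), b = rnorm(15, 0.5), c = rnorm(8, 1))
  res <- anova_tukey(groups)
  expect_equal(nrow(res$pairwise), 3)
  for (j in seq_len(nrow(res$pairwise))) {
    pa <- groups[[res$pairwise$group_a[j]]]
    pb <- groups[[res$pairwise$group_b[j]]]
    raw_p <- t.test(pb, pa, var.equal = TRUE)$p.value
    expect_gte(res$pairwise$p_adjusted[j] + 1e-12, raw_p)
  }
  # pairwise labels orient the difference as group_b minus group_a
  ab <- res$pairwise[res$pairwise$group_a == "a" & res$pairwise$group_b == "b", ]
  expect_equal(ab$mean_diff, mean(groups$b) - mean(groups$a), tolerance = 1e-10)
})

test_that("Shapiro-Wilk separates normal from exponential samples", {
  set.seed(101)
  norm_ok <- 0L; exp_ok <- 0L
  for (i in 1:100) {
    if (shapiro_wilk(rnorm(500))$p > 0.05) norm_ok <- norm_ok + 1L
    if (shapiro_wilk(rexp(500))$p < 0.05) exp_ok <- exp_ok + 1L
  }
  expect_gte(norm_ok, 90)
  expect_equal(exp_ok, 100L)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(5, 10)), "constant")
})
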