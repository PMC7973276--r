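test_that("trend statistic direction, antisymmetry and degeneracy", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- factor(rep(c("short", "intermediate", "long"), each = 2),
              levels = c("short", "intermediate", "long"))
  tr <- cuzick_trend(v, g)
  expect_gt(tr$z, 0)
  rev_tr <- cuzick_trend(v, factor(g, levels = rev(levels(g))))
  expect_equal(rev_tr$z, -tr$z)
  expect_equal(rev_tr$p, tr$p)

  const <- cuzick_trend(rep(2, 6), g)
  expect_equal(const$z, 0)
  expect_equal(const$p, 1)
  expect_error(cuzick_trend(1:3, factor(rep("a", 3))), "two ordered groups")
})

test_that("two-group trend reduces to the rank-sum normal deviate", {
  set.seed(81)
  for (i in 1:10) {
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    v <- sample(seq_len(50), n1 + n2)          # tie-free
    g <- factor(rep(c("short", "long"), c(n1, n2)),
                levels = c("short", "long"))
    tr <- cuzick_trend(v, g)
    W <- sum(rank(v)[g == "long"]) - n2 * (n2 + 1) / 2
    z_rs <- (W - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    expect_equal(abs(tr$z), abs(z_rs), tolerance = 1e-9)
  }
})

test_that("spearman correlation equals the rank-then-pearson oracle", {
  expect_equal(spearman_corr(1:10, exp(1:10))$r, 1)
  expect_equal(spearman_corr(1:10, exp(1:10))$p, 0)
  expect_equal(spearman_corr(1:8, -(1:8))$r, -1)
  expect_true(is.na(spearman_corr(rep(1, 5), 1:5)$r))
  set.seed(91)
  for (i in 1:15) {
    x <- round(rnorm(26), 1); y <- round(rnorm(26), 1)
    got <- spearman_corr(x, y)
    want <- oracle_spearman(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(92)
  x <- rnorm(20); y <- rnorm(20)
  base <- spearman_corr(x, y)$r
  expect_equal(spearman_corr(exp(x), y)$r, base)
  expect_equal(spearman_corr(x, y^3 + 5 * y)$r, base)  # strictly increasing
})

test_that("correlation matrices are symmetric with unit diagonal", {
  x <- paper_shaped_fixture(2)
  genes <- c("CTLA4", "ICOS", "LAG3", "PD-1")
  cm <- correlation_matrix(x, genes)
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_equal(cm$r, t(cm$r))
  expect_true(all(abs(cm$r) <= 1))
  expect_error(correlation_matrix(x, c("CTLA4", "NOPE")), "NOPE")
})

test_that("median split balances groups and respects the tie policy", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(s$low, c(1, 2))
  expect_equal(s$high, c(3, 4))
  s <- median_split(c(5, 5, 5, 5))
  expect_length(s$low, 2)
  expect_length(s$high, 2)
  set.seed(101)
  for (i in 1:200) {
    v <- sample(1:5, sample(2:30, 1), replace = TRUE)
    s <- median_split(v)
    expect_lte(abs(length(s$low) - length(s$high)), 1)
    expect_equal(sort(c(s$low, s$high)), seq_along(v))
  }
})

test_that("student t-test matches closed form and handles degenerate variance", {
  p <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(p, 2 * pt(-sqrt(3 / 2), df = 4), tolerance = 1e-12)
  # arm swap leaves the two-sided p unchanged
  expect_equal(two_sample_t(c(2, 3, 4), c(1, 2, 3)), p)
  # paired identical vectors: zero-variance contract
  p0 <- two_sample_t(c(5, 6, 7), c(5, 6, 7), paired = TRUE)
  expect_equal(as.numeric(p0), 1)
  expect_true(attr(p0, "degenerate"))
  p1 <- two_sample_t(rep(2, 3), rep(3, 3))
  expect_equal(as.numeric(p1), 0)
})

test_that("fold change is a ratio of means with the paired test attached", {
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$fold, 1)
  expect_equal(fold_change(c(2, 4, 6), c(1, 2, 3))$fold, 2)
  expect_error(fold_change(1:3, c(-1, 0, 1)), "positive")
  # lognormal arms with true mean ratio 44: the recovered fold averaged
  # over seeds sits within 25% at n = 26
  set.seed(111)
  folds <- replicate(10, {
    den <- exp(rnorm(26, 0, 0.5) + 7)
    num <- exp(rnorm(26, 0, 0.5) + 7 + log(44))
    fc <- fold_change(num, den, paired = TRUE)
    expect_lt(fc$p, 0.001)
    fc$fold
  })
  expect_lt(abs(exp(mean(log(folds))) / 44 - 1), 0.25)
})

test_that("per-analyte trend table runs over the full ordered cohort", {
  x <- paper_shaped_fixture(4)
  tr <- trend_table(x, analytes = c("LAG3", "CTLA4", "ARG1"))
  expect_equal(names(tr), c("analyte", "z", "p", "median_short",
                            "median_intermediate", "median_long"))
  expect_true(all(tr$p >= 0 & tr$p <= 1))
  # the panel plants higher long-group levels for LAG3: positive trend
  expect_gt(tr$z[tr$analyte == "LAG3"], 0)
})
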