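test_that("rank-sum test reproduces exact enumeration p-values, ties included", {
  expect_equal(wilcoxonRankSum(1:3, 4:6)$p_value, 0.1)
  expect_equal(wilcoxonRankSum(c(1, 1, 1), c(3, 3, 3))$p_value, 0.1)
  expect_equal(wilcoxonRankSum(c(2, 4, 6), c(2, 4, 6))$p_value, 1)

  set.seed(42)
  for (i in 1:200) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    x <- sample(1:6, nx, replace = TRUE)
    y <- sample(1:6, ny, replace = TRUE)
    got <- wilcoxonRankSum(x, y)
    if (got$degenerate) {
      expect_equal(got$p_value, 1)
    } else {
      expect_equal(got$p_value, oracle_ranksum_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("rank-sum agrees with the classical exact distribution on tie-free data", {
  set.seed(7)
  for (i in 1:50) {
    nx <- sample(3:6, 1)
    ny <- sample(3:6, 1)
    v <- sample(1:100, nx + ny)  # distinct values, no ties
    x <- v[1:nx]
    y <- v[-(1:nx)]
    expect_equal(wilcoxonRankSum(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("rank-sum normal approximation matches the reference tie-corrected form", {
  set.seed(11)
  x <- rnorm(60)
  y <- rnorm(70, 0.3)
  got <- wilcoxonRankSum(x, y, exactLimit = 1)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$method, "normal")
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # with heavy ties
  xt <- sample(1:4, 50, replace = TRUE)
  yt <- sample(1:4, 50, replace = TRUE)
  expect_equal(wilcoxonRankSum(xt, yt, exactLimit = 1)$p_value,
               stats::wilcox.test(xt, yt, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("rank-sum degenerate and one-sided behaviour", {
  d <- wilcoxonRankSum(rep(2, 4), rep(2, 5))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  expect_equal(wilcoxonRankSum(4:6, 1:3, alternative = "greater")$p_value,
               1 / 20)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "nonempty")
})

test_that("signed-rank test reproduces exact enumeration p-values", {
  expect_equal(wilcoxonSignedRank(6:10, c(1, 2, 3, 4, 5))$p_value, 0.0625)
  expect_true(wilcoxonSignedRank(1:4, 1:4)$degenerate)
  expect_equal(wilcoxonSignedRank(1:4, 1:4)$p_value, 1)

  set.seed(9)
  for (i in 1:50) {
    d <- sample(c(-4:4), 8, replace = TRUE)
    if (all(d == 0)) next
    expect_equal(wilcoxonSignedRank(d)$p_value, oracle_signedrank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with the classical exact distribution, and its approximation holds", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    x <- rnorm(n)  # continuous: no ties, no zero differences
    y <- rnorm(n, 1)
    expect_equal(wilcoxonSignedRank(x, y)$p_value,
                 stats::wilcox.test(x, y, paired = TRUE,
                                    exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  x <- rnorm(40)
  y <- rnorm(40, 0.4)
  expect_equal(wilcoxonSignedRank(x, y)$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("spearman rho matches the rank formula and flags constant input", {
  expect_equal(spearmanRho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanRho(1:10, -(1:10))$rho, -1)
  expect_equal(spearmanRho(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  cst <- spearmanRho(rep(1, 5), 1:5)
  expect_true(is.na(cst$rho))
  expect_equal(cst$reason, "constant_input")
  # invariance under strictly monotone transforms of either side
  set.seed(3)
  x <- rnorm(30)
  y <- rnorm(30)
  base <- spearmanRho(x, y)
  expect_equal(spearmanRho(exp(x), y)$rho, base$rho)
  expect_equal(spearmanRho(x, y^3 + 5 * y)$rho, base$rho)
  # p-value against the t reference used by cor.test
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(base$rho, unname(ref$estimate))
  expect_equal(base$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("BH adjustment is the step-up procedure, order-preserving and monotone", {
  expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bhAdjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bhAdjust(0.037), 0.037)
  expect_error(bhAdjust(c(0.5, 1.2)), "outside")

  set.seed(21)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    perm <- sample(length(p))
    expect_equal(bhAdjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
})
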