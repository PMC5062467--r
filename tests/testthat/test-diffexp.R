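test_that("size factors follow the median-of-ratios definition", {
  y <- nb_fixture(G = 50, n = 3, seed = 1)
  # identical columns get equal factors
  y2 <- cbind(a = y[, 1], b = y[, 1])
  expect_equal(unname(size_factors(y2)), c(1, 1))
  # a uniformly doubled column doubles its factor
  y3 <- cbind(a = y[, 1], b = 2L * y[, 1], c = y[, 2])
  sf <- size_factors(y3)
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  # gene-by-gene reference loop oracle on a random matrix
  loggeo <- numeric(nrow(y))
  for (g in seq_len(nrow(y))) loggeo[g] <- mean(log(y[g, ]))
  ok <- is.finite(loggeo)
  brute <- apply(y, 2, function(col) exp(median(log(col[ok]) - loggeo[ok])))
  expect_equal(size_factors(y), brute)
  # no gene expressed everywhere: informative error
  ybad <- matrix(c(1L, 0L, 0L, 2L), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(ybad), "pseudo-reference")
})

test_that("nb_wald_test validates groups and excludes all-zero genes", {
  y <- nb_fixture(G = 40, n = 4, seed = 2)
  y["g0001", ] <- 0L
  expect_error(nb_wald_test(y, colnames(y)[1], colnames(y)[2:5]), ">= 2")
  expect_error(nb_wald_test(y, colnames(y)[1:3], colnames(y)[3:6]), "disjoint")
  de <- suppressMessages(nb_wald_test(y, colnames(y)[1:4], colnames(y)[5:8]))
  expect_true(is.na(de$stat[de$gene == "g0001"]))
  expect_true(is.na(de$padj[de$gene == "g0001"]))
  expect_true(all(is.finite(de$stat[de$gene != "g0001"])))
  # BH never below raw p, never above 1, monotone in rank
  ok <- !is.na(de$pvalue)
  expect_true(all(de$padj[ok] >= de$pvalue[ok]))
  expect_true(all(de$padj[ok] <= 1))
  o <- order(de$pvalue[ok])
  expect_true(all(diff(de$padj[ok][o]) >= -1e-12))
})

test_that("statistics are invariant to gene row order", {
  y <- nb_fixture(G = 60, n = 5, seed = 3)
  gA <- colnames(y)[1:5]; gB <- colnames(y)[6:10]
  de1 <- suppressMessages(nb_wald_test(y, gA, gB))
  perm <- sample(nrow(y))
  de2 <- suppressMessages(nb_wald_test(y[perm, ], gA, gB))
  de2 <- de2[match(de1$gene, de2$gene), ]
  expect_equal(de2$stat, de1$stat, tolerance = 1e-10)
})

test_that("scaling one sample scales its size factor and barely moves the Wald stats", {
  y <- nb_fixture(G = 100, n = 6, seed = 4)
  gA <- colnames(y)[1:6]; gB <- colnames(y)[7:12]
  de1 <- suppressMessages(nb_wald_test(y, gA, gB))
  y2 <- y; y2[, 1] <- 2L * y2[, 1]
  # doubling one column also moves the geometric-mean reference by
  # 2^(1/n), so the factor scales by exactly 2^((n-1)/n)
  n <- ncol(y)
  expect_equal(unname(size_factors(y2)[1] / size_factors(y)[1]),
               2^((n - 1) / n), tolerance = 1e-12)
  de2 <- suppressMessages(nb_wald_test(y2, gA, gB))
  # the NB likelihood genuinely sees the rescaled counts, so invariance is
  # approximate: the statistics must stay tightly coupled
  expect_gt(cor(de1$stat, de2$stat), 0.999)
  expect_lt(median(abs(de1$stat - de2$stat)), 0.05)
})

test_that("fixed near-zero dispersion reproduces the Poisson GLM Wald statistic", {
  y <- nb_fixture(G = 30, n = 6, seed = 5, disp = 1e-4)
  gA <- colnames(y)[1:6]; gB <- colnames(y)[7:12]
  de <- suppressMessages(nb_wald_test(y, gA, gB, dispersion = "fixed",
                                      fixed_alpha = 1e-8))
  sf <- size_factors(y)
  grp <- rep(0:1, each = 6)
  zp <- vapply(seq_len(nrow(y)), function(g) {
    fit <- stats::glm(y[g, ] ~ grp + offset(log(sf)), family = stats::poisson())
    summary(fit)$coefficients["grp", "z value"]
  }, 0)
  expect_equal(de$stat, zp, tolerance = 1e-4)
})

test_that("the t-test path matches the Welch formula and its symmetries", {
  set.seed(6)
  expr <- matrix(rnorm(20 * 8, 8, 1), 20, 8,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:8)))
  gA <- colnames(expr)[1:4]; gB <- colnames(expr)[5:8]
  # identical groups: t = 0, p = 1
  same <- cbind(expr[, gA], expr[, gA])
  colnames(same) <- c(gA, gB)
  de0 <- ttest_pipeline(same, gA, gB)
  expect_equal(de0$stat, rep(0, 20))
  expect_equal(de0$pvalue, rep(1, 20))
  # swapping groups flips every t, p unchanged
  de1 <- ttest_pipeline(expr, gA, gB)
  de2 <- ttest_pipeline(expr, gB, gA)
  expect_equal(de2$stat, -de1$stat)
  expect_equal(de2$pvalue, de1$pvalue)
  # hand data: textbook Welch evaluated independently
  xh <- rbind(gX = c(1, 2, 3, 4, 5, 6))
  colnames(xh) <- sprintf("h%d", 1:6)
  deh <- ttest_pipeline(xh, colnames(xh)[1:3], colnames(xh)[4:6])
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  tw <- (mean(b) - mean(a)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(deh$stat, tw)
  # zero-variance gene in both groups is NA and out of the BH family
  expr[1, ] <- 5
  dez <- ttest_pipeline(expr, gA, gB)
  expect_true(is.na(dez$stat[1]) && is.na(dez$padj[1]))
  # Shapiro-Wilk QC p is recorded for testable genes
  expect_true(all(!is.na(de1$sw_pvalue)))
})
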