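test_that("quantile normalization equalizes per-sample distributions", {
  # hand-enumerated mean-quantile rule: samples (1,2) and (3,4) both map to
  # the mean quantile vector (2,3)
  m <- matrix(c(1, 2, 3, 4), nrow = 2)
  expect_equal(quantile_normalize(m), matrix(c(2, 3, 2, 3), nrow = 2))

  # identical samples are unchanged
  m2 <- matrix(c(5, 1, 9, 5, 1, 9), nrow = 3)
  expect_equal(quantile_normalize(m2), m2)

  # permuted samples map to identical multisets
  set.seed(42)
  x <- rnorm(50)
  m3 <- cbind(x, sample(x), sample(x))
  q3 <- quantile_normalize(m3)
  expect_equal(sort(q3[, 1]), sort(q3[, 2]))
  expect_equal(sort(q3[, 2]), sort(q3[, 3]))

  # multiset equality across arbitrary samples (property over random input)
  m4 <- matrix(rexp(200), 40, 5)
  q4 <- quantile_normalize(m4)
  for (j in 2:5) expect_equal(sort(q4[, 1]), sort(q4[, j]))

  # cross-check against the established implementation, including ties
  skip_if_not_installed("limma")
  set.seed(7)
  m5 <- matrix(rnorm(120), 20, 6)
  expect_equal(quantile_normalize(m5), limma::normalizeQuantiles(m5))
  m6 <- matrix(sample(1:5, 120, TRUE), 20, 6)
  expect_equal(quantile_normalize(m6),
               limma::normalizeQuantiles(m6, ties = TRUE))
})

test_that("log transform uses the half-minimum pseudocount", {
  m <- matrix(c(0, 4, 2, 8), 2)
  lt <- log_transform(m)
  expect_equal(attr(lt, "pseudocount"), 1)  # half of min nonzero (2)
  expect_equal(lt[2, 2], log2(9))
  # no zeros: plain log2
  expect_equal(unclass(log_transform(matrix(c(2, 4), 1)))[1, ],
               c(1, 2), ignore_attr = TRUE)
})

test_that("pareto scaling centers and divides by sqrt(sd)", {
  x <- c(2, 4, 6, 8)
  m <- matrix(x, nrow = 1)
  expect_equal(pareto_scale(m), (m - mean(x)) / sqrt(sd(x)))
  # feature with sd 1 is mean-centered only
  m1 <- matrix(c(0.5, 1.5, 2.5), nrow = 1)  # sd = 1
  expect_equal(pareto_scale(m1), m1 - 1.5)
  # constant features become all zeros
  expect_equal(unname(pareto_scale(matrix(7, 1, 4))), matrix(0, 1, 4))
})

test_that("pooled t-tests match the reference implementation", {
  set.seed(3)
  X <- matrix(rnorm(10 * 20), nrow = 10)
  g <- rep(c("A", "B"), each = 5)
  res <- ttest_bh(X, g)
  for (j in c(1, 7, 20)) {
    ref <- t.test(X[g == "B", j], X[g == "A", j], var.equal = TRUE)
    expect_equal(res$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-12)
  }
  # Welch option
  resw <- ttest_bh(X, g, var_equal = FALSE)
  refw <- t.test(X[g == "B", 1], X[g == "A", 1])
  expect_equal(resw$p[1], refw$p.value, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  X0 <- rbind(X[1:5, ], X[1:5, ])
  res0 <- ttest_bh(X0, g)
  expect_true(all(res0$t == 0))
  expect_true(all(res0$p == 1))
  # zero pooled variance: degenerate flag, p = 1 convention
  Xc <- X0
  Xc[, 1] <- 5
  resc <- ttest_bh(Xc, g)
  expect_true(resc$degenerate[1])
  expect_equal(resc$p[1], 1)

  expect_error(ttest_bh(X[1:3, ], c("A", "A", "B")),
               class = "InsufficientData")
})

test_that("BH q-values match brute-force step-up enumeration", {
  # hand-derived example: p = (.01,.02,.03,.04), m = 4 -> q = .04 everywhere
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(bh_bruteforce(p), rep(0.04, 4))

  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_bruteforce(p), tolerance = 1e-12)
  }
  # q >= p and q monotone in the rank of p
  X <- matrix(rnorm(10 * 30), nrow = 10)
  res <- ttest_bh(X, rep(c("A", "B"), each = 5))
  expect_true(all(res$q >= res$p))
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
})

test_that("PCA is an SVD of the centered matrix with stable signs", {
  set.seed(5)
  X <- matrix(rnorm(8 * 6), nrow = 8)
  res <- pca(X, n_components = 3)
  # scores orthogonal
  cp <- crossprod(res$scores)
  expect_equal(cp, diag(diag(cp)), tolerance = 1e-8, ignore_attr = TRUE)
  # explained variance matches prcomp
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(res$explained_variance,
               (pr$sdev^2 / sum(pr$sdev^2))[1:3], tolerance = 1e-10)
  # reconstruction with all components equals the centered input
  full <- pca(X, n_components = 6)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(full$scores %*% t(full$loadings), Xc,
               tolerance = 1e-9, ignore_attr = TRUE)
  # rank-1 matrix: PC1 explains everything
  r1 <- outer(rnorm(8), rnorm(6))
  r1 <- r1 - rep(colMeans(r1), each = 8)  # keep it rank 1 after centering
  expect_warning(p1 <- pca(r1, n_components = 3), class = "RankDeficient")
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-9)
  # deterministic sign: largest-|loading| entry is positive
  for (a in 1:3) {
    j <- which.max(abs(res$loadings[, a]))
    expect_gt(res$loadings[j, a], 0)
  }
})
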