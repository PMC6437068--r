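test_that("a perfectly separating feature gives an exact one-component fit", {
  X <- cbind(sep = rep(c(0, 1), each = 4), noise = 0)
  y <- rep(c("A", "B"), each = 4)
  fit <- plsda(X, y, n_components = 1)
  expect_equal(fit$R2Y, 1, tolerance = 1e-12)
  expect_equal(unname(predict(fit, X)), as.numeric(y == "B"),
               tolerance = 1e-12)
  expect_equal(as.character(predict(fit, X, type = "class")), y)
})

test_that("NIPALS matches the direct least-squares oracle on a 6x4 instance", {
  set.seed(21)
  X <- matrix(rnorm(24), nrow = 6, ncol = 4)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- plsda(X, factor(y, labels = c("a", "b")), n_components = 1)

  # oracle: the 1-component bilinear model solved directly -
  # w from the X'y covariance, then ordinary least squares of y on t = Xc w
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
  t1 <- drop(Xc %*% w)
  q <- unname(coef(lm(yc ~ 0 + t1)))
  expect_equal(unname(fit$scores[, 1]), t1, tolerance = 1e-10)
  expect_equal(fit$y_loadings[1], q, tolerance = 1e-10)
  expect_equal(unname(fitted(fit)), t1 * q + mean(y), tolerance = 1e-10)
  expect_equal(unname(residuals(fit)), y - (t1 * q + mean(y)),
               tolerance = 1e-10)
})

test_that("weights are unit norm and scores mutually orthogonal", {
  set.seed(8)
  X <- matrix(rnorm(10 * 20), nrow = 10)
  y <- rep(c("A", "B"), each = 5)
  fit <- plsda(X, y, n_components = 3)
  expect_equal(unname(sqrt(colSums(fit$weights^2))), rep(1, 3),
               tolerance = 1e-10)
  cp <- crossprod(fit$scores)
  expect_equal(cp, diag(diag(cp)), tolerance = 1e-8, ignore_attr = TRUE)

  # invariance to feature reordering (1-component solution)
  perm <- sample(ncol(X))
  fit1 <- plsda(X, y, n_components = 1)
  fit2 <- plsda(X[, perm], y, n_components = 1)
  expect_equal(unname(fit2$weights[, 1]), unname(fit1$weights[perm, 1]),
               tolerance = 1e-10)
  expect_equal(fit1$R2Y, fit2$R2Y, tolerance = 1e-12)
})

test_that("VIP has unit mean square and singles out planted features", {
  # p = 1 feature: VIP forced to 1
  X1 <- matrix(rep(c(0, 1), each = 4) + rnorm(8, sd = 0.1), ncol = 1)
  f1 <- plsda(X1, rep(c("A", "B"), each = 4), n_components = 1)
  expect_equal(unname(vip(f1)), 1, tolerance = 1e-10)

  # algebraic identity: mean of squared VIPs is 1 on any fit
  set.seed(13)
  for (i in 1:10) {
    X <- matrix(rnorm(10 * 25), nrow = 10)
    fit <- plsda(X, rep(c("A", "B"), each = 5),
                 n_components = sample(1:3, 1))
    v <- vip(fit, n_components = fit$n_components)
    expect_equal(mean(v^2), 1, tolerance = 1e-10)
    expect_equal(mean(vip(fit)^2), 1, tolerance = 1e-10)  # first component
  }

  # planted informative features out-rank noise
  set.seed(14)
  hits <- 0
  for (i in 1:40) {
    X <- matrix(rnorm(10 * 50), nrow = 10)
    X[6:10, 1:5] <- X[6:10, 1:5] + 4
    fit <- plsda(X, rep(c("A", "B"), each = 5), n_components = 1)
    v <- vip(fit)
    hits <- hits + (min(v[1:5]) > max(v[6:50]))
  }
  expect_gte(hits / 40, 0.95)
})

test_that("cross-validated Q2 distinguishes signal from permuted labels", {
  dat <- synthetic_amounts(seed = 3)
  X <- preprocess_lipidome(dat$amounts)
  g <- dat$groups
  strong <- q2_cv(X, g, n_components = 2)
  expect_gt(strong$Q2, 0.9)
  expect_equal(sum(strong$press), sum((as.numeric(factor(g)) - 1 -
                                         strong$predictions)^2),
               tolerance = 1e-10)

  # noiseless exactly-predictable response: Q2 = 1
  Xs <- cbind(rep(c(0, 1), each = 5), matrix(0, 10, 2))
  expect_equal(q2_cv(Xs, rep(c("A", "B"), each = 5), 1)$Q2, 1,
               tolerance = 1e-10)

  # permuted labels: mean Q2 <= 0
  q2p <- vapply(1:30, function(s) {
    set.seed(s)
    q2_cv(X, sample(g), n_components = 2)$Q2
  }, numeric(1))
  expect_lte(mean(q2p), 0)

  # k-fold stratification keeps both classes in training folds
  kf <- q2_cv(X, g, n_components = 2, folds = 3, seed = 2)
  expect_length(kf$press, 3)
  expect_true(is.finite(kf$Q2))
})

test_that("auto component selection and model summary are coherent", {
  dat <- synthetic_amounts(seed = 5)
  X <- preprocess_lipidome(dat$amounts)
  fit <- plsda(X, dat$groups, n_components = "auto", max_components = 3)
  expect_true(fit$n_components %in% 1:3)
  fit$Q2 <- q2_cv(X, dat$groups, n_components = fit$n_components)$Q2
  s <- summary(fit, vip_threshold = 1)
  expect_equal(s$n_vip_ge_threshold, sum(vip(fit) >= 1))
  expect_error(plsda(X[1:3, ], dat$groups[c(1, 2, 6)]),
               class = "InsufficientData")
})
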