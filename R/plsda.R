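# Partial least squares discriminant analysis (PLS1 on a dummy-coded
# two-level response) fitted by NIPALS, with VIP scores and cross-validated
# predictive ability Q2. This is the package's central model object.

#' Fit a PLS-DA model (NIPALS, two classes)
#'
#' The two-level response is dummy-coded 0/1 and centered; `X` is column-
#' centered. Per component `a`: `w_a = X'y / ||X'y||`, `t_a = X w_a`,
#' `p_a = X't_a / t_a't_a`, `q_a = y't_a / t_a't_a`, then `X` and `y` are
#' deflated. Successive score vectors are mutually orthogonal.
#'
#' The number of components may be fixed or chosen by maximizing
#' cross-validated Q2 (`n_components = "auto"`), the usual criterion for an
#' "optimal" PLS-DA model; variable importance is conventionally reported
#' from the first component regardless.
#'
#' @param X samples x features numeric matrix (preprocess first; see
#'   [preprocess_lipidome()]).
#' @param y two-level factor/character/dummy vector of class labels.
#' @param n_components integer, or `"auto"` to maximize leave-one-out Q2 over
#'   `1:max_components`.
#' @param max_components search bound for `"auto"`.
#' @param seed RNG seed used only when cross-validation folds are random
#'   (k-fold); recorded in the model.
#' @return object of class `"plsda"` with elements `weights` (W), `scores`
#'   (T), `x_loadings` (P), `y_loadings` (q), `coefficients`, `fitted`,
#'   `R2Y`, `Q2` (when computed), `n_components`, `levels`, `x_center`,
#'   `y_center`.
#' @export
plsda <- function(X, y, n_components = 2, max_components = 3, seed = 1L) {
  X <- as.matrix(X)
  y_fac <- factor(y)
  if (nlevels(y_fac) != 2) {
    lip_stop("PLS-DA requires exactly two classes", "InsufficientData")
  }
  if (min(table(y_fac)) < 2) {
    lip_stop("each class needs at least two samples", "InsufficientData")
  }
  if (identical(n_components, "auto")) {
    kmax <- min(max_components, nrow(X) - 2, ncol(X))
    q2s <- vapply(seq_len(kmax), function(k) {
      q2_cv(X, y, n_components = k, seed = seed)$Q2
    }, numeric(1))
    n_components <- which.max(q2s)
  }
  fit <- .pls1_fit(X, as.numeric(y_fac) - 1, n_components)
  fit$levels <- levels(y_fac)
  fit$seed <- seed
  class(fit) <- "plsda"
  fit
}

# Core NIPALS PLS1 on numeric 0/1 response.
.pls1_fit <- function(X, y01, n_components) {
  n <- nrow(X); p <- ncol(X)
  x_center <- colMeans(X)
  y_center <- mean(y01)
  Xa <- sweep(X, 2, x_center)
  ya <- y01 - y_center
  tss <- sum(ya^2)

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  qv <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      lip_stop("degenerate PLS component: X carries no covariance with y",
               "InsufficientData")
    }
    w <- w / nw
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; qv[a] <- q_a
  }
  fitted_centered <- drop(Tm %*% qv)
  rss <- sum((y01 - y_center - fitted_centered)^2)
  # regression coefficients on the original (uncentered X) scale
  B <- W %*% solve(crossprod(P, W), qv)
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("comp", seq_len(n_components)))
  dimnames(Tm) <- list(rownames(X), paste0("comp", seq_len(n_components)))
  list(weights = W, x_loadings = P, scores = Tm, y_loadings = qv,
       coefficients = drop(B), fitted = fitted_centered + y_center,
       y = y01, R2Y = 1 - rss / tss, Q2 = NA_real_,
       n_components = n_components, x_center = x_center, y_center = y_center)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d components, %d features, n = %d\n",
              x$n_components, nrow(x$weights), nrow(x$scores)))
  cat(sprintf("  R2Y = %.4f%s\n", x$R2Y,
              if (is.na(x$Q2)) "" else sprintf(", Q2 = %.4f", x$Q2)))
  if (!is.null(x$levels)) {
    cat(sprintf("  classes: %s (0) vs %s (1)\n", x$levels[1], x$levels[2]))
  }
  invisible(x)
}

#' @export
summary.plsda <- function(object, vip_threshold = 1, ...) {
  v <- vip(object)
  ss <- object$y_loadings^2 * colSums(object$scores^2)
  out <- list(n_components = object$n_components, R2Y = object$R2Y,
              Q2 = object$Q2, component_ss = ss,
              n_vip_ge_threshold = sum(v >= vip_threshold),
              vip_threshold = vip_threshold)
  class(out) <- "summary.plsda"
  out
}

#' @export
print.summary.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d components, R2Y = %.4f%s\n", x$n_components, x$R2Y,
              if (is.na(x$Q2)) "" else sprintf(", Q2 = %.4f", x$Q2)))
  cat(sprintf("features with first-component VIP >= %g: %d\n",
              x$vip_threshold, x$n_vip_ge_threshold))
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' @export
fitted.plsda <- function(object, ...) object$fitted

#' @export
residuals.plsda <- function(object, ...) object$y - object$fitted

#' Predict from a PLS-DA model
#' @param object a `"plsda"` fit.
#' @param newdata samples x features matrix on the training scale.
#' @param type `"response"` (continuous 0/1-scale prediction) or `"class"`.
#' @param ... unused.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("response", "class"), ...) {
  type <- match.arg(type)
  Xc <- sweep(as.matrix(newdata), 2, object$x_center)
  yhat <- drop(Xc %*% object$coefficients) + object$y_center
  if (type == "response") return(yhat)
  factor(object$levels[(yhat >= 0.5) + 1], levels = object$levels)
}

#' @export
plot.plsda <- function(x, components = c(1, 2), ...) {
  k <- min(x$n_components, 2)
  s <- x$scores
  col <- as.integer(x$y) + 2
  if (x$n_components == 1) {
    graphics::stripchart(s[, 1] ~ factor(x$levels[x$y + 1]), vertical = TRUE,
                         pch = 19, col = c(2, 3), method = "jitter",
                         ylab = "component 1 score", ...)
  } else {
    graphics::plot(s[, components[1]], s[, components[2]], col = col, pch = 19,
                   xlab = sprintf("component %d", components[1]),
                   ylab = sprintf("component %d", components[2]), ...)
    graphics::legend("topright", legend = x$levels, col = c(2, 3), pch = 19)
  }
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` with
#' `SS_a = q_a^2 t_a' t_a` and unit-norm weights, over the first
#' `n_components` components of the fit. The mean of squared VIPs over
#' features is 1 by construction.
#'
#' @param model a `"plsda"` fit.
#' @param n_components how many leading components to aggregate (default 1,
#'   the conventional first-component VIP).
#' @return named numeric vector of VIP scores.
#' @export
vip <- function(model, n_components = 1) {
  stopifnot(inherits(model, "plsda"))
  a <- seq_len(min(n_components, model$n_components))
  ss <- model$y_loadings[a]^2 * colSums(model$scores[, a, drop = FALSE]^2)
  if (all(ss == 0)) {
    lip_stop("all component sums of squares are zero; VIP undefined",
             "InsufficientData")
  }
  W <- model$weights[, a, drop = FALSE]
  p <- nrow(W)
  v <- sqrt(p * drop(W^2 %*% ss) / sum(ss))
  stats::setNames(v, rownames(model$weights))
}

#' Cross-validated Q2 of a PLS-DA model
#'
#' `Q2 = 1 - PRESS / TSS` with test-fold predictions from models fitted on the
#' training folds only. Default is stratified leave-one-out, the conventional
#' scheme at n around 10; k-fold splits are stratified by class and shuffled
#' under `seed`.
#'
#' @param X samples x features matrix.
#' @param y two-level labels.
#' @param n_components number of PLS components (integer).
#' @param folds `"loo"` or an integer number of folds (>= 2).
#' @param seed RNG seed for fold assignment (k-fold only).
#' @return list: `Q2`, `press` (per-fold PRESS), `predictions`, `folds`,
#'   `seed`.
#' @export
q2_cv <- function(X, y, n_components = 2, folds = "loo", seed = 1L) {
  X <- as.matrix(X)
  y_fac <- factor(y)
  stopifnot(nlevels(y_fac) == 2)
  y01 <- as.numeric(y_fac) - 1
  n <- nrow(X)

  if (identical(folds, "loo")) {
    assign <- seq_len(n)
  } else {
    folds <- as.integer(folds)
    stopifnot(folds >= 2)
    assign <- integer(n)
    with_seed(seed, {
      for (lv in levels(y_fac)) {
        idx <- which(y_fac == lv)
        idx <- idx[sample.int(length(idx))]
        assign[idx] <- rep_len(seq_len(folds), length(idx))
      }
    })
  }
  fold_ids <- sort(unique(assign))
  preds <- rep(NA_real_, n)
  press <- numeric(length(fold_ids))
  for (f in seq_along(fold_ids)) {
    test <- which(assign == fold_ids[f])
    train <- setdiff(seq_len(n), test)
    if (length(unique(y01[train])) < 2) {
      lip_stop("a cross-validation training fold lost one class; use fewer folds",
               "InsufficientData")
    }
    k <- min(n_components, length(train) - 1)
    fit <- .pls1_fit(X[train, , drop = FALSE], y01[train], k)
    Xc <- sweep(X[test, , drop = FALSE], 2, fit$x_center)
    preds[test] <- drop(Xc %*% fit$coefficients) + fit$y_center
    press[f] <- sum((y01[test] - preds[test])^2)
  }
  tss <- sum((y01 - mean(y01))^2)
  list(Q2 = 1 - sum(press) / tss, press = press, predictions = preds,
       folds = assign, seed = seed)
}
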