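# Feature-wise two-group testing: pooled-variance (Student) two-tailed t-test
# with Benjamini-Hochberg FDR adjustment, the gates used for the univariate
# lipidome comparison (P < 0.05 and FDR < 0.10).

#' Two-group t-tests with BH false discovery rate
#'
#' Pooled-variance Student's two-tailed t-test per feature (Welch available
#' via `var_equal = FALSE`), BH step-up q-values, and significance flags at
#' the configured gates. Features with zero pooled variance get the
#' conventional p = 1 and are flagged in `degenerate`.
#'
#' @param X samples x features numeric matrix.
#' @param groups factor-like with exactly two levels; each group needs
#'   >= 2 samples.
#' @param p_gate,q_gate significance gates (defaults 0.05 and 0.10).
#' @param var_equal pooled variance (TRUE, Student) or Welch (FALSE).
#' @return data.frame of class `"lipid_ttest"`: `feature`, `mean_<g1>`,
#'   `mean_<g2>`, `log_fc` (group2 minus group1 difference in the input scale),
#'   `t`, `df`, `p`, `q`, `significant`, `degenerate`.
#' @export
ttest_bh <- function(X, groups, p_gate = 0.05, q_gate = 0.10,
                     var_equal = TRUE) {
  X <- as.matrix(X)
  groups <- factor(groups)
  if (nlevels(groups) != 2) {
    lip_stop("exactly two groups are required", "InsufficientData")
  }
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2 || n2 < 2) {
    lip_stop("each group needs at least two samples", "InsufficientData")
  }
  X1 <- X[groups == levels(groups)[1], , drop = FALSE]
  X2 <- X[groups == levels(groups)[2], , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2, stats::var); v2 <- apply(X2, 2, stats::var)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  degenerate <- se == 0 | !is.finite(se)
  t_stat <- ifelse(degenerate, 0, (m2 - m1) / se)
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(t_stat), df))
  q <- stats::p.adjust(p, method = "BH")

  out <- data.frame(
    feature = colnames(X) %||% paste0("feature_", seq_along(p)),
    mean_1 = m1, mean_2 = m2, diff = m2 - m1,
    t = t_stat, df = df, p = p, q = q,
    significant = p < p_gate & q < q_gate,
    degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE
  )
  names(out)[2:3] <- paste0("mean_", make.names(levels(groups)))
  structure(out, groups = levels(groups),
            class = c("lipid_ttest", "data.frame"))
}

#' @export
print.lipid_ttest <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("<lipid_ttest> %s vs %s: %d features, %d significant (p<gate & q<gate)\n",
              g[2], g[1], nrow(x), sum(x$significant)))
  NextMethod()
}
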