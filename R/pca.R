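# Principal component analysis by singular value decomposition of the
# column-centered design matrix, with a deterministic sign convention.

#' Principal component analysis by SVD
#'
#' @param X samples x features matrix (typically the output of
#'   [preprocess_lipidome()]).
#' @param n_components number of components to return; truncated with a
#'   warning when it exceeds the matrix rank.
#' @param center center columns before decomposition (default TRUE).
#' @return list of class `"lipid_pca"`: `scores` (samples x k), `loadings`
#'   (features x k), `explained_variance` (fraction per component), `sdev`,
#'   `center`.
#' @export
pca <- function(X, n_components = 2, center = TRUE) {
  X <- as.matrix(X)
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  positive <- sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(positive)
  if (n_components > rank) {
    lip_warn(sprintf("n_components truncated from %d to rank %d",
                     n_components, rank), "RankDeficient")
    n_components <- rank
  }
  k <- seq_len(n_components)
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components)
  loadings <- sv$v[, k, drop = FALSE]
  # sign convention: the largest-|loading| element of each component positive
  for (a in k) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  var_all <- sv$d^2 / max(1, (nrow(X) - 1))
  dimnames(scores) <- list(rownames(X), paste0("PC", k))
  dimnames(loadings) <- list(colnames(X), paste0("PC", k))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = var_all[k] / sum(var_all),
                 sdev = sqrt(var_all[k]), center = mu),
            class = "lipid_pca")
}

#' @export
print.lipid_pca <- function(x, ...) {
  cat("<lipid_pca>\n  explained variance:",
      paste0(sprintf("PC%d=%.1f%%", seq_along(x$explained_variance),
                     100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.lipid_pca <- function(x, groups = NULL, components = c(1, 2), ...) {
  s <- x$scores[, components, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(factor(groups)) + 1
  graphics::plot(s[, 1], s[, 2],
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * x$explained_variance[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * x$explained_variance[components[2]]),
                 col = col, pch = 19, ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_len(nlevels(factor(groups))) + 1, pch = 19)
  }
  invisible(x)
}
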