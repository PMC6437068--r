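# Preprocessing for multivariate analysis of lipid tables: quantile
# normalization across samples, log transform with a data-driven pseudocount,
# and pareto scaling per feature. The stack mirrors the standard metabolomics
# workflow: quantile-normalize, log-transform, pareto-scale.

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the across-sample mean quantile
#' vector. Ties within a sample receive the average of the mean-quantile
#' values they span, so permuted samples map to identical multisets.
#'
#' @param mat numeric matrix, features x samples (>= 2 samples).
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) >= 2, all(is.finite(mat)))
  sorted <- apply(mat, 2, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = 1)
  ref <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    rk <- rank(mat[, j], ties.method = "average")
    # average ref values for tied ranks (rank may be fractional)
    lo <- floor(rk); hi <- ceiling(rk)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  dimnames(out) <- dimnames(mat)
  out
}

#' Log transform with half-minimum pseudocount
#'
#' `log2(x + pseudocount)`; the default pseudocount is half the smallest
#' nonzero value of the matrix, so zero intensities map to a finite floor
#' without imputation.
#'
#' @param mat non-negative numeric matrix.
#' @param pseudocount override for the additive constant; must be > 0 when
#'   the matrix contains zeros.
#' @param base logarithm base (default 2).
#' @return transformed matrix with attribute `"pseudocount"`.
#' @export
log_transform <- function(mat, pseudocount = NULL, base = 2) {
  stopifnot(all(mat >= 0))
  if (is.null(pseudocount)) {
    nz <- mat[mat > 0]
    if (length(nz) == 0) lip_stop("all-zero matrix", "DegenerateSample")
    pseudocount <- if (any(mat == 0)) min(nz) / 2 else 0
  }
  out <- log(mat + pseudocount, base = base)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Pareto scaling per feature
#'
#' Centers each feature and divides by the square root of its standard
#' deviation, the usual compromise between no scaling and unit-variance
#' scaling for intensity data. Constant features are centered only.
#'
#' @param mat numeric matrix, features x samples (features are scaled along
#'   samples); set `margin = 2` to scale columns instead.
#' @param margin 1 to scale rows (default), 2 for columns.
#' @return scaled matrix.
#' @export
pareto_scale <- function(mat, margin = 1) {
  mat <- as.matrix(mat)
  if (margin == 2) return(t(pareto_scale(t(mat))))
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  centered <- mat - mu
  scale_by <- ifelse(sdv > 0, sqrt(sdv), 1)
  centered / scale_by
}

#' Standard preprocessing stack for multivariate lipidome analysis
#'
#' Applies quantile normalization (across samples), log transform and pareto
#' scaling (per feature) to a features x samples matrix and returns the
#' samples x features design matrix used by [pca()] and [plsda()], with the
#' applied transforms recorded in the `"provenance"` attribute.
#'
#' @param mat features x samples non-negative matrix.
#' @param quantile,log,pareto logical switches for the three steps.
#' @param pseudocount passed to [log_transform()].
#' @return samples x features matrix with attribute `"provenance"`.
#' @export
preprocess_lipidome <- function(mat, quantile = TRUE, log = TRUE,
                                pareto = TRUE, pseudocount = NULL) {
  prov <- character(0)
  if (quantile) { mat <- quantile_normalize(mat); prov <- c(prov, "quantile") }
  if (log) { mat <- log_transform(mat, pseudocount); prov <- c(prov, "log2") }
  if (pareto) { mat <- pareto_scale(mat, margin = 1); prov <- c(prov, "pareto") }
  out <- t(mat)
  attr(out, "provenance") <- prov
  out
}
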