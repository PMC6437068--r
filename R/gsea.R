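# Weighted Kolmogorov-Smirnov-like running-sum enrichment score (the GSEA ES
# statistic). Only the statistic is computed here; set-permutation p-values
# are out of scope.

#' GSEA enrichment score
#'
#' Walks the ranked list from top to bottom accumulating `P_hit - P_miss`,
#' where hits are weighted by `|ranking weight|^weight_exponent` (exponent 0
#' recovers the classic Kolmogorov-Smirnov statistic) and misses by
#' `1 / (N - N_hit)`. The enrichment score is the signed maximum deviation of
#' the running sum.
#'
#' @param ranked_genes named numeric vector of ranking weights (e.g. log2
#'   fold-changes or signal-to-noise), sorted internally in decreasing order.
#' @param gene_set character vector; must be a non-empty proper subset of the
#'   ranked universe.
#' @param weight_exponent non-negative exponent on |weight| (default 1, the
#'   weighted statistic).
#' @return list of class `"gsea_es"`: `es`, `running_sum`, `hit_positions`,
#'   `n`, `n_hit`.
#' @export
gsea_es <- function(ranked_genes, gene_set, weight_exponent = 1) {
  if (is.null(names(ranked_genes)) || anyDuplicated(names(ranked_genes))) {
    lip_stop("ranked_genes must carry unique gene names", "ParseError")
  }
  stopifnot(weight_exponent >= 0)
  r <- sort(ranked_genes, decreasing = TRUE)
  genes <- names(r)
  hit <- genes %in% gene_set
  n <- length(genes); nh <- sum(hit)
  if (nh == 0) {
    lip_stop("gene set has no overlap with the ranked universe", "EmptySet")
  }
  if (nh == n) {
    lip_stop("gene set equals the ranked universe; ES undefined", "EmptySet")
  }
  w <- abs(r)^weight_exponent
  nr <- sum(w[hit])
  if (nr == 0) {
    lip_stop("all in-set ranking weights are zero; weighted ES undefined",
             "EmptySet")
  }
  p_hit <- cumsum(ifelse(hit, w / nr, 0))
  p_miss <- cumsum(ifelse(hit, 0, 1 / (n - nh)))
  running <- p_hit - p_miss
  # signed maximum deviation; an exact tie between the positive and negative
  # extremes scores 0 (keeps the statistic antisymmetric under ranking
  # reversal on the lattice values the classic statistic takes)
  max_dev <- max(running); min_dev <- min(running)
  tol <- 1e-10 * max(1, abs(max_dev), abs(min_dev))
  es <- if (abs(max_dev + min_dev) <= tol) 0
        else if (max_dev > -min_dev) max_dev
        else min_dev
  structure(list(es = unname(es), running_sum = running,
                 hit_positions = which(hit), n = n, n_hit = nh),
            class = "gsea_es")
}

#' @export
print.gsea_es <- function(x, ...) {
  cat(sprintf("<gsea_es> ES = %.3f (set n = %d of %d genes)\n",
              x$es, x$n_hit, x$n))
  invisible(x)
}
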