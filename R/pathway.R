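# Enzyme-mapped fatty-acid activity indices (product/substrate ratios on the
# unsaturated fatty-acid biosynthesis map), group comparison, transcript
# fold-change overlay and a sign-concordance permutation test.

#' Packaged fatty-acid biosynthesis pathway map
#'
#' Desaturation and elongation steps linking substrate to product fatty acids
#' with the annotating gene symbols: the two SCD desaturation indices
#' (16:0 -> 16:1, 18:0 -> 18:1), the saturated elongation chain
#' (16:0 -> 18:0 -> 20:0 -> 22:0, elongation-cycle genes), and the composite
#' DHA step 22:5n3 -> 22:6n3 (ELOVL2-dependent elongation / desaturation /
#' beta-oxidation, reported as the single product-to-substrate ratio). The map
#' ships as TSV and is user-extensible.
#'
#' @param path optional alternative map TSV (columns substrate, product,
#'   genes `;`-separated, kind).
#' @return data.frame of class `"pathway_map"`.
#' @export
default_pathway_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathway_map.tsv", package = "lipidemt",
                        mustWork = TRUE)
  }
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("substrate", "product", "genes", "kind") %in% names(map)))
  if (any(map$substrate == map$product)) {
    lip_stop("pathway step with identical substrate and product", "ParseError")
  }
  map$step <- paste0(map$product, "/", map$substrate)
  structure(map, class = c("pathway_map", "data.frame"))
}

#' Write a pathway map as TSV
#' @param map a `"pathway_map"`.
#' @param path output path.
#' @export
write_pathway_map <- function(map, path) {
  utils::write.table(map[, c("substrate", "product", "genes", "kind")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample product/substrate fatty-acid indices
#'
#' `ratio = product %% / substrate %%` per sample and step. Ratios are
#' invariant to closure rescaling of the profile. Steps whose substrate or
#' product is absent from the profile are skipped with a warning; a zero
#' substrate composition yields a missing ratio (never +/-Inf).
#'
#' @param profile a `"fa_profile"` (fatty acids x samples).
#' @param map a `"pathway_map"`.
#' @return matrix steps x samples of ratios.
#' @export
compute_indices <- function(profile, map = default_pathway_map()) {
  fa <- rownames(profile)
  have <- map$substrate %in% fa & map$product %in% fa
  if (any(!have)) {
    lip_warn(sprintf("steps skipped (fatty acid not in profile): %s",
                     paste(map$step[!have], collapse = ", ")), "MissingStep")
  }
  m <- map[have, , drop = FALSE]
  sub <- unclass(profile)[m$substrate, , drop = FALSE]
  prod <- unclass(profile)[m$product, , drop = FALSE]
  out <- prod / sub
  out[sub == 0] <- NA_real_
  if (any(sub == 0)) {
    lip_warn("zero substrate composition: ratio reported as missing",
             "ZeroSubstrate")
  }
  rownames(out) <- m$step
  out
}

#' Two-group comparison of fatty-acid indices
#'
#' Student's pooled-variance t-test per step (delegating to [ttest_bh()]),
#' group means with SEM, and a direction call: `up` / `down` in the second
#' group when the gate is passed, `unchanged` otherwise.
#'
#' @param ratios steps x samples matrix from [compute_indices()].
#' @param groups two-level labels, one per sample (the second factor level is
#'   the "treatment" whose direction is reported).
#' @param p_gate direction gate on the per-step t-test p-value.
#' @param q_gate FDR gate applied alongside `p_gate` when `use_q` is TRUE.
#' @param use_q also require q < `q_gate` for a direction call.
#' @return data.frame of class `"index_result"`: step, group means/SEM,
#'   t, p, q, direction.
#' @export
compare_indices <- function(ratios, groups, p_gate = 0.05, q_gate = 0.10,
                            use_q = FALSE) {
  groups <- factor(groups)
  tt <- ttest_bh(t(ratios), groups, p_gate = p_gate, q_gate = q_gate)
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  sem1 <- apply(ratios[, groups == g1, drop = FALSE], 1, sem)
  sem2 <- apply(ratios[, groups == g2, drop = FALSE], 1, sem)
  gate <- if (use_q) tt$p < p_gate & tt$q < q_gate else tt$p < p_gate
  direction <- ifelse(!gate, "unchanged", ifelse(tt$diff > 0, "up", "down"))
  out <- data.frame(step = tt$feature,
                    mean_1 = tt[[2]], sem_1 = sem1,
                    mean_2 = tt[[3]], sem_2 = sem2,
                    t = tt$t, p = tt$p, q = tt$q,
                    direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0(c("mean_", "sem_"), make.names(g1)),
                       paste0(c("mean_", "sem_"), make.names(g2)))
  structure(out, groups = levels(groups),
            class = c("index_result", "data.frame"))
}

#' Overlay transcript log2 fold-changes on a pathway map
#'
#' Gene symbols are matched case-insensitively; each step is annotated with
#' the mean log2 fold-change of its genes and the per-gene values. Genes in
#' the overlay that match no step are reported in the `"unmatched"` attribute.
#'
#' @param map a `"pathway_map"`.
#' @param expr named numeric vector of log2 fold-changes (names are gene
#'   symbols), finite values.
#' @return the map with added columns `gene_log2fc` (`;`-joined per-gene
#'   values, NA for genes without data) and `mean_log2fc`.
#' @export
overlay_expression <- function(map, expr) {
  stopifnot(is.numeric(expr), !is.null(names(expr)), all(is.finite(expr)))
  lut <- stats::setNames(expr, toupper(names(expr)))
  used <- character(0)
  per_step <- lapply(strsplit(map$genes, ";"), function(gs) {
    gs <- toupper(trimws(gs))
    v <- lut[gs]
    names(v) <- gs
    v
  })
  used <- unique(unlist(lapply(per_step, function(v) names(v)[!is.na(v)])))
  map$gene_log2fc <- vapply(per_step, function(v) {
    paste(sprintf("%s=%s", names(v), ifelse(is.na(v), "NA",
                                            sprintf("%.3f", v))),
          collapse = ";")
  }, character(1))
  map$mean_log2fc <- vapply(per_step, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  attr(map, "unmatched") <- setdiff(toupper(names(expr)), used)
  map
}

#' Sign concordance between index directions and transcript fold-changes
#'
#' The fraction of evaluable steps where the sign of the index change (mean
#' difference between groups) equals the sign of the step's mean gene log2
#' fold-change, with a permutation p-value obtained by shuffling the
#' gene-to-step assignment. Formalizes the qualitative claim that
#' product/substrate ratios move with their regulatory gene expression.
#'
#' @param index_results an `"index_result"` data.frame (from
#'   [compare_indices()]); the mean difference column is recomputed from the
#'   group means.
#' @param annotated_map output of [overlay_expression()]; steps are matched
#'   by the `step` column.
#' @param n_permutations number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list: `concordance`, `p_value`, `n_steps`, `table`.
#' @export
concordance <- function(index_results, annotated_map, n_permutations = 1000,
                        seed = 1L) {
  i <- match(index_results$step, annotated_map$step)
  idx_diff <- index_results[[4]] - index_results[[2]]  # mean_2 - mean_1
  gene_fc <- annotated_map$mean_log2fc[i]
  ok <- !is.na(gene_fc) & is.finite(idx_diff) & idx_diff != 0
  if (!any(ok)) {
    lip_stop("no step carries both an index direction and a gene fold-change",
             "InsufficientData")
  }
  s_idx <- sign(idx_diff[ok]); s_gene <- sign(gene_fc[ok])
  conc <- mean(s_idx == s_gene)
  n <- sum(ok)
  if (n < 2) {
    p <- 1  # no exchangeable permutations
  } else {
    hits <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        mean(s_idx == s_gene[sample.int(n)]) >= conc
      }, logical(1))
    })
    p <- (1 + sum(hits)) / (n_permutations + 1)
  }
  list(concordance = conc, p_value = p, n_steps = n,
       table = data.frame(step = index_results$step[ok],
                          index_sign = s_idx, gene_sign = s_gene,
                          stringsAsFactors = FALSE))
}
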