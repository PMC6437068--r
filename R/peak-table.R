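# Lightweight container for an aligned features x samples intensity table
# with feature and sample metadata, in the spirit of a minimal ExpressionSet.

#' Construct a peak table
#'
#' @param intensities numeric matrix, features in rows, samples in columns;
#'   all values finite and >= 0.
#' @param features data.frame with one row per feature; must contain columns
#'   `name` and `class`; optional `mz`, `rt`, `is_standard` (logical flag for
#'   spiked internal standards) and `standard_class` (the class a standard
#'   normalizes).
#' @param samples data.frame with one row per sample; must contain `sample_id`
#'   and `group`; optional `protein_ug`.
#' @return object of class `"peak_table"`.
#' @export
peak_table <- function(intensities, features, samples) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities) || any(!is.finite(intensities)) ||
      any(intensities < 0)) {
    lip_stop("intensities must be finite, non-negative numerics", "ParseError")
  }
  stopifnot(nrow(features) == nrow(intensities),
            nrow(samples) == ncol(intensities),
            all(c("name", "class") %in% names(features)),
            all(c("sample_id", "group") %in% names(samples)))
  if (anyDuplicated(features$name)) {
    lip_stop("duplicate feature names in peak table", "ParseError")
  }
  if (is.null(features$is_standard)) features$is_standard <- FALSE
  rownames(intensities) <- features$name
  colnames(intensities) <- samples$sample_id
  structure(list(intensities = intensities,
                 features = features, samples = samples),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d features x %d samples (%d internal standards)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$features$is_standard)))
  cat("  classes:", paste(sort(unique(x$features$class)), collapse = ", "), "\n")
  cat("  groups: ", paste(names(table(x$samples$group)),
                          table(x$samples$group),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

#' Subset a peak table by feature and/or sample index
#' @param x a `"peak_table"`.
#' @param i,j feature / sample indices (logical, integer or names).
#' @param ... unused.
#' @export
`[.peak_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  peak_table(x$intensities[i, j, drop = FALSE],
             x$features[i, , drop = FALSE],
             x$samples[j, , drop = FALSE])
}

#' Write / read a peak table as a pair of TSV files
#'
#' The intensity matrix (with feature metadata columns prepended) goes to
#' `path`; sample metadata goes to `paste0(path, ".samples.tsv")`.
#' @param x a `"peak_table"`.
#' @param path output TSV path.
#' @export
write_peak_table <- function(x, path) {
  out <- cbind(x$features, as.data.frame(x$intensities, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @return for `read_peak_table`, a `"peak_table"`.
#' @export
read_peak_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  samples <- utils::read.delim(paste0(path, ".samples.tsv"))
  meta_cols <- intersect(c("name", "class", "mz", "rt", "is_standard",
                           "standard_class"), names(tab))
  features <- tab[, meta_cols, drop = FALSE]
  ints <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  peak_table(ints, features, samples)
}

#' Long-format export of an amount/composition table
#'
#' @param mat numeric matrix (features x samples) such as the output of
#'   [is_normalize()] or [class_composition()].
#' @param features optional feature metadata to join on row names.
#' @return data.frame in long ("tidy") layout: feature, sample, value.
#' @export
as_long_table <- function(mat, features = NULL) {
  out <- data.frame(
    feature = rep(rownames(mat), times = ncol(mat)),
    sample = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat),
    stringsAsFactors = FALSE
  )
  if (!is.null(features) && "class" %in% names(features)) {
    out$class <- features$class[match(out$feature, features$name)]
  }
  out
}
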