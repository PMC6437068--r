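# Internal-standard and protein normalization, class/species compositions,
# lipidome -> fatty-acid decomposition, and GC-MS FAME relative composition.

#' Default internal-standard map
#'
#' One spiked odd-chain standard per quantified class with the spiked amount in
#' ng. Ether classes share their diacyl class standard and SM shares the
#' nearest-sphingolipid Cer standard because no dedicated standards are spiked
#' for those classes; both mappings are user-overridable.
#'
#' @return data.frame: `class`, `standard`, `amount_ng`.
#' @export
default_standard_map <- function() {
  data.frame(
    class = c("LPC", "PC", "PC O-", "PE", "PE O-", "TG", "SM", "Cer"),
    standard = c("LPC(17:0)", "PC(17:0/17:0)", "PC(17:0/17:0)",
                 "PE(17:0/17:0)", "PE(17:0/17:0)", "TG(17:0/17:0/17:0)",
                 "Cer(d18:1/17:0)", "Cer(d18:1/17:0)"),
    amount_ng = c(400, 400, 400, 400, 400, 2000, 400, 400),
    stringsAsFactors = FALSE
  )
}

#' Internal-standard normalization of a peak table
#'
#' Converts intensities to ng-equivalent amounts:
#' `amount = intensity / intensity(class standard) * spiked amount`.
#' Standards are removed from the output. Per-sample global intensity scaling
#' cancels by construction.
#'
#' @param table a `"peak_table"`; internal-standard features must be flagged
#'   via `features$is_standard` and named as in `is_map$standard`.
#' @param is_map internal-standard map, see [default_standard_map()].
#' @return numeric matrix of amounts (features x samples) with attribute
#'   `"features"` carrying the remaining feature metadata.
#' @export
is_normalize <- function(table, is_map = default_standard_map()) {
  stopifnot(inherits(table, "peak_table"))
  feats <- table$features
  ints <- table$intensities
  analytes <- which(!feats$is_standard)
  std_rows <- stats::setNames(match(is_map$standard, feats$name), is_map$class)

  cls <- feats$class[analytes]
  need <- unique(cls)
  for (cl in need) {
    i <- std_rows[[cl]]
    if (is.null(i) || is.na(i)) {
      lip_stop(sprintf("no internal standard found for class '%s'", cl),
               "MissingStandard")
    }
    bad <- which(ints[i, ] <= 0)
    if (length(bad)) {
      lip_stop(sprintf(
        "internal standard for class '%s' has non-positive intensity in sample %s",
        cl, colnames(ints)[bad[1]]), "MissingStandard")
    }
  }

  std_int <- ints[std_rows[cls], , drop = FALSE]
  spike <- is_map$amount_ng[match(cls, is_map$class)]
  amounts <- ints[analytes, , drop = FALSE] / std_int * spike
  rownames(amounts) <- feats$name[analytes]
  attr(amounts, "features") <- feats[analytes, , drop = FALSE]
  amounts
}

#' Protein normalization
#'
#' @param amounts matrix (features x samples) of ng amounts.
#' @param protein_ug per-sample protein quantity (ug), positive, recycled by
#'   column.
#' @return amounts per ug protein.
#' @export
protein_normalize <- function(amounts, protein_ug) {
  if (any(!is.finite(protein_ug)) || any(protein_ug <= 0)) {
    lip_stop("protein amounts must be positive and finite", "InvalidProtein")
  }
  stopifnot(length(protein_ug) == ncol(amounts))
  sweep(amounts, 2, protein_ug, "/")
}

.closure <- function(mat, what = "sample") {
  tot <- colSums(mat)
  if (any(tot <= 0)) {
    lip_stop(sprintf("all-zero %s encountered in composition closure", what),
             "DegenerateSample")
  }
  sweep(mat, 2, tot, "/") * 100
}

#' Per-sample lipid class composition (% of total lipid)
#'
#' @param amounts normalized amount matrix with a `"features"` attribute, or
#'   any matrix plus an explicit `classes` vector.
#' @param classes per-feature class labels (defaults to the attribute).
#' @return matrix classes x samples; columns sum to 100.
#' @export
class_composition <- function(amounts, classes = NULL) {
  if (is.null(classes)) classes <- attr(amounts, "features")$class
  stopifnot(!is.null(classes), length(classes) == nrow(amounts))
  agg <- rowsum(amounts, group = classes)
  .closure(agg)
}

#' Per-sample species composition
#'
#' @param amounts normalized amount matrix.
#' @param scope `"total"` (percent of all lipid) or `"within-class"` (percent
#'   of the species' own class).
#' @param classes per-feature class labels, needed for `"within-class"`.
#' @return matrix species x samples.
#' @export
species_composition <- function(amounts, scope = c("total", "within-class"),
                                classes = NULL) {
  scope <- match.arg(scope)
  if (scope == "total") return(.closure(amounts))
  if (is.null(classes)) classes <- attr(amounts, "features")$class
  stopifnot(!is.null(classes), length(classes) == nrow(amounts))
  out <- amounts
  for (cl in unique(classes)) {
    i <- classes == cl
    out[i, ] <- .closure(amounts[i, , drop = FALSE], what = "class")
  }
  out
}

#' Construct a fatty-acid profile object
#' @param mat matrix, fatty acids x samples, columns summing to 100.
#' @param provenance `"FAME-GC"` or `"lipidome-decomposition"`.
#' @return matrix of class `"fa_profile"`.
#' @export
fa_profile <- function(mat, provenance) {
  stopifnot(max(abs(colSums(mat) - 100)) < 1e-6)
  structure(mat, provenance = provenance, class = c("fa_profile", "matrix"))
}

#' @export
print.fa_profile <- function(x, ...) {
  cat(sprintf("<fa_profile> %d fatty acids x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "provenance")))
  print(round(unclass(x), 2))
  invisible(x)
}

#' GC-MS FAME relative composition via relative response factors
#'
#' `amount_i = area_i / (rrf_i * area_IS) * is_amount`, then closure to 100%.
#'
#' @param gc_areas matrix of integrated FAME peak areas, fatty acids x samples;
#'   row names are fatty-acid names and must include `is_name`.
#' @param rrf named numeric vector of relative response factors per reported
#'   fatty acid; missing entries default to 1 with a warning when
#'   `default_rrf_warn` is `TRUE`.
#' @param is_name internal-standard row name (default `"23:0"`, the spiked
#'   C23:0 FAME).
#' @param is_amount spiked amount in ug (default 5).
#' @param default_rrf_warn warn when an RRF is defaulted to 1.
#' @return a `"fa_profile"` (percent composition).
#' @export
fame_composition <- function(gc_areas, rrf = NULL, is_name = "23:0",
                             is_amount = 5, default_rrf_warn = TRUE) {
  if (!is_name %in% rownames(gc_areas)) {
    lip_stop(sprintf("internal standard '%s' not present in GC areas", is_name),
             "MissingStandard")
  }
  analytes <- setdiff(rownames(gc_areas), is_name)
  r <- stats::setNames(rep(1, length(analytes)), analytes)
  if (!is.null(rrf)) {
    known <- intersect(names(rrf), analytes)
    r[known] <- rrf[known]
  }
  missing_r <- if (is.null(rrf)) analytes else setdiff(analytes, names(rrf))
  if (length(missing_r) && default_rrf_warn) {
    lip_warn(sprintf("RRF defaulted to 1.0 for: %s",
                     paste(missing_r, collapse = ", ")), "MissingRRF")
  }
  if (any(r <= 0)) {
    lip_stop("relative response factors must be positive", "MissingStandard")
  }
  is_area <- gc_areas[is_name, ]
  if (any(is_area <= 0)) {
    lip_stop("internal standard area must be positive in every sample",
             "MissingStandard")
  }
  amounts <- sweep(gc_areas[analytes, , drop = FALSE], 2, is_area, "/") /
    r * is_amount
  fa_profile(.closure(amounts), provenance = "FAME-GC")
}

#' Fatty-acid profile from a molecular-acyl lipid amount table
#'
#' Decomposes each molecular-acyl species into its esterified fatty acids;
#' every species contributes its amount once per acyl occurrence, then the
#' profile is closed to 100%. Species without acyl resolution are excluded
#' with a warning.
#'
#' @param amounts amount matrix (features x samples) whose row names are
#'   shorthand species names.
#' @return a `"fa_profile"`.
#' @export
lipidome_to_fa_profile <- function(amounts) {
  species <- rownames(amounts)
  acyl_lists <- lapply(species, function(nm) lipid_acyls(nm))
  resolved <- lengths(acyl_lists) > 0
  if (any(!resolved)) {
    lip_warn(sprintf("%d species without acyl resolution excluded from FA profile",
                     sum(!resolved)), "UnresolvedSpecies")
  }
  if (!any(resolved)) {
    out <- matrix(numeric(0), nrow = 0, ncol = ncol(amounts),
                  dimnames = list(NULL, colnames(amounts)))
    return(structure(out, provenance = "lipidome-decomposition",
                     class = c("fa_profile", "matrix")))
  }
  idx <- rep(which(resolved), lengths(acyl_lists[resolved]))
  fas <- unlist(acyl_lists[resolved])
  contrib <- rowsum(amounts[idx, , drop = FALSE], group = fas, reorder = TRUE)
  fa_profile(.closure(contrib), provenance = "lipidome-decomposition")
}
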