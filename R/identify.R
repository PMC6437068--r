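# Rule-based MS/MS identification: precursor tolerance match against a species
# library, class-diagnostic fragment confirmation, acyl-evidence check, and
# deterministic tie-breaking. The in-silico counterpart of a vendor-search-
# then-manual-confirmation workflow.

#' Build a species library with theoretical adduct m/z
#'
#' @param species_names character vector of shorthand lipid names.
#' @param adduct_by_class optional named character vector mapping class to the
#'   quantified adduct; defaults to the `quant_adduct` column of the packaged
#'   class templates.
#' @return data.frame: `name`, `class`, `resolution`, `mass`, `adduct`,
#'   `polarity`, `mz`.
#' @export
build_species_library <- function(species_names, adduct_by_class = NULL) {
  tpl <- lipid_class_templates()
  if (is.null(adduct_by_class)) {
    adduct_by_class <- stats::setNames(tpl$quant_adduct, tpl$class)
  }
  adducts <- default_adducts()
  rows <- lapply(species_names, function(nm) {
    sp <- parse_lipid_name(nm)
    add <- adduct_by_class[[sp$lipid_class]]
    mass <- monoisotopic_mass(sp)
    data.frame(name = format_lipid_name(sp), class = sp$lipid_class,
               resolution = sp$resolution, mass = mass, adduct = add,
               polarity = adducts$polarity[match(add, adducts$adduct)],
               mz = mz_for_adduct(mass, add), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Packaged class-diagnostic fragmentation rules
#'
#' Diagnostic ions and neutral losses per lipid class and polarity, shipped as
#' editable TSV data. `kind` is one of `fragment` (fixed m/z),
#' `neutral_loss` (subtracted from the precursor), `acyl_fragment`
#' (deprotonated fatty-acid carboxylate per ester/amide chain) or
#' `acyl_neutral_loss` (precursor minus NH3 minus the fatty acid, the
#' ammoniated-triglyceride acyl loss). `role` marks required, optional and
#' forbidden evidence; `min_required` is the per-class confirmation threshold.
#'
#' @param path optional path to an alternative rule TSV.
#' @return data.frame of rules.
#' @export
fragmentation_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fragmentation_rules.tsv",
                        package = "lipidemt", mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.NH3_MASS <- 17.02654910101  # N + 3H

#' Expected diagnostic fragments for a candidate species
#'
#' Expands the class rules into concrete m/z values for one candidate:
#' fixed fragments as-is, neutral losses relative to the precursor, and
#' acyl-derived evidence (carboxylates, fatty-acid losses) per ester/amide
#' chain of molecular-acyl species.
#'
#' @param species a `"lipid_species"` or shorthand name.
#' @param precursor_mz precursor m/z the neutral losses are relative to.
#' @param rules rule table, see [fragmentation_rules()].
#' @return data.frame: `mz`, `label`, `role` (required/optional/forbidden).
#' @export
expected_fragments <- function(species, precursor_mz, rules) {
  if (is.character(species)) species <- parse_lipid_name(species)
  cls_rules <- rules[rules$class == species$lipid_class, , drop = FALSE]
  if (nrow(cls_rules) == 0) {
    lip_stop(sprintf("no fragmentation rule for class '%s'",
                     species$lipid_class), "MissingRule")
  }
  out <- list()
  for (i in seq_len(nrow(cls_rules))) {
    r <- cls_rules[i, ]
    role <- if (identical(r$kind, "forbidden_fragment")) "forbidden" else r$role
    if (r$kind %in% c("fragment", "forbidden_fragment")) {
      out[[length(out) + 1]] <- data.frame(mz = r$mz, label = r$label,
                                           role = role)
    } else if (r$kind == "neutral_loss") {
      out[[length(out) + 1]] <- data.frame(mz = precursor_mz - r$mz,
                                           label = r$label, role = role)
    } else if (r$kind %in% c("acyl_fragment", "acyl_neutral_loss",
                             "acyl_fa_neutral_loss")) {
      if (species$resolution != "molecular-acyl") next
      chains <- Filter(function(a) a$linkage %in% c("ester", "amide"),
                       species$acyls)
      for (a in chains) {
        fa_mass <- a$carbons * .ATOMIC_MASS[["C"]] +
          (2 * a$carbons - 2 * a$double_bonds) * .ATOMIC_MASS[["H"]] +
          2 * .ATOMIC_MASS[["O"]]
        mz <- switch(r$kind,
          acyl_fragment = fa_mass - .PROTON_MASS,
          acyl_neutral_loss = precursor_mz - .NH3_MASS - fa_mass,
          acyl_fa_neutral_loss = precursor_mz - fa_mass)
        out[[length(out) + 1]] <- data.frame(
          mz = mz, label = sprintf("%s %d:%d", r$label, a$carbons,
                                   a$double_bonds), role = role)
      }
    }
  }
  do.call(rbind, out)
}

#' Precursor-matching candidate species
#'
#' @param precursor_mz observed precursor m/z.
#' @param polarity `"+"` or `"-"`.
#' @param library species library from [build_species_library()].
#' @param tol_ppm precursor tolerance in ppm (> 0).
#' @return data.frame of candidates (`name`, `class`, `adduct`, `error_ppm`)
#'   sorted by |error_ppm|; zero rows when nothing matches.
#' @export
candidate_species <- function(precursor_mz, polarity, library, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  if (is.null(library) || nrow(library) == 0) {
    lip_stop("species library is empty", "EmptyLibrary")
  }
  lib <- library[library$polarity == polarity, , drop = FALSE]
  err <- (precursor_mz - lib$mz) / lib$mz * 1e6
  keep <- abs(err) <= tol_ppm
  out <- lib[keep, c("name", "class", "resolution", "adduct", "mz"),
             drop = FALSE]
  out$error_ppm <- err[keep]
  out[order(abs(out$error_ppm)), , drop = FALSE]
}

#' Confirm a candidate against an MS/MS spectrum
#'
#' A candidate is `confirmed` when at least `min_required` of its class's
#' required diagnostic fragments are present within `frag_tol` Da and no
#' forbidden fragment is present; otherwise `rejected`. The score is the
#' fraction of required evidence matched, reported for audit.
#'
#' @param spectrum a `"spectrum_record"`.
#' @param candidate one row of [candidate_species()] output (or a list with
#'   `name` and `error_ppm`).
#' @param rules rule table, see [fragmentation_rules()].
#' @param frag_tol fragment matching tolerance in Da.
#' @return data.frame of class `"identification_hit"` row: `species`, `adduct`,
#'   `error_ppm`, `n_matched`, `n_required`, `score`, `status`,
#'   `matched_fragments` (semicolon-joined labels).
#' @export
confirm_hit <- function(spectrum, candidate, rules = fragmentation_rules(),
                        frag_tol = 0.02) {
  species <- parse_lipid_name(candidate$name)
  frags <- expected_fragments(species, spectrum$precursor_mz, rules)
  req <- frags[frags$role == "required", , drop = FALSE]
  forb <- frags[frags$role == "forbidden", , drop = FALSE]
  min_req <- rules$min_required[match(species$lipid_class, rules$class)]
  min_req <- min(min_req, nrow(req))  # cap at evaluable evidence

  obs <- spectrum$peaks[, "mz"]
  present <- function(mz) length(obs) > 0 && any(abs(obs - mz) <= frag_tol)
  matched <- if (nrow(req)) vapply(req$mz, present, logical(1)) else logical(0)
  forbidden_hit <- if (nrow(forb)) any(vapply(forb$mz, present, logical(1)))
                   else FALSE

  n_matched <- sum(matched)
  score <- if (nrow(req) == 0) 0 else n_matched / nrow(req)
  status <- if (nrow(spectrum$peaks) == 0 || forbidden_hit ||
                n_matched < min_req) "rejected" else "confirmed"
  structure(data.frame(
    species = format_lipid_name(species),
    adduct = candidate$adduct %||% NA_character_,
    error_ppm = candidate$error_ppm %||% NA_real_,
    n_matched = n_matched, n_required = nrow(req), score = score,
    status = status,
    matched_fragments = paste(req$label[matched], collapse = ";"),
    stringsAsFactors = FALSE
  ), class = c("identification_hit", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identify a set of MS/MS spectra against a species library
#'
#' Runs [candidate_species()] and [confirm_hit()] on every spectrum and
#' resolves ties deterministically: highest score, then smallest
#' |precursor error|, then lexicographic species name. At most one species is
#' confirmed per spectrum; confirmed candidates losing the tie-break are
#' downgraded to `tentative`. The full candidate audit trail is attached as
#' attribute `"audit"`.
#'
#' @param spectra list of `"spectrum_record"` objects.
#' @param library species library, see [build_species_library()].
#' @param rules fragmentation rule table.
#' @param tol_ppm precursor tolerance (ppm).
#' @param frag_tol fragment tolerance (Da).
#' @return data.frame with one row per spectrum-candidate pair and a `status`
#'   column in `{confirmed, tentative, rejected}`; spectra without candidates
#'   contribute a row with `species = NA` and `status = "no_candidate"`.
#' @export
identify_dataset <- function(spectra, library, rules = fragmentation_rules(),
                             tol_ppm = 10, frag_tol = 0.02) {
  out <- vector("list", length(spectra))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    id <- if (nzchar(s$title)) s$title else paste0("spectrum_", k)
    cands <- candidate_species(s$precursor_mz, s$polarity, library, tol_ppm)
    if (nrow(cands) == 0) {
      out[[k]] <- data.frame(spectrum = id, species = NA_character_,
                             adduct = NA_character_, error_ppm = NA_real_,
                             n_matched = 0L, n_required = 0L, score = 0,
                             status = "no_candidate", matched_fragments = "",
                             stringsAsFactors = FALSE)
      next
    }
    hits <- do.call(rbind, lapply(seq_len(nrow(cands)), function(i) {
      confirm_hit(s, cands[i, ], rules, frag_tol)
    }))
    conf <- which(hits$status == "confirmed")
    if (length(conf) > 1) {
      ord <- conf[order(-hits$score[conf], abs(hits$error_ppm[conf]),
                        hits$species[conf])]
      hits$status[setdiff(conf, ord[1])] <- "tentative"
    }
    out[[k]] <- cbind(spectrum = id, hits, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, audit = res,
            class = c("identification_table", "data.frame"))
}

#' Confirmed species from an identification table
#' @param hits output of [identify_dataset()].
#' @return character vector of unique confirmed species names.
#' @export
confirmed_species <- function(hits) {
  sort(unique(hits$species[hits$status == "confirmed"]))
}
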