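# Shorthand lipid nomenclature: parsing, canonical formatting, elemental
# composition, monoisotopic mass and adduct m/z.
#
# Grammar (a pragmatic subset of shorthand notation):
#   CLASS(C:D)                 species-sum, e.g. PC(34:1)
#   CLASS(C:D/C:D[/C:D])       molecular acyls, e.g. TG(17:0/17:0/17:0)
#   SM(d34:1), Cer(d18:1/17:0) sphingoid "d" prefix (2 hydroxyls; "t" = 3)
#   PC(O-34:1), PC(O-16:0/18:1), "PC O-34:1", "PC O-(34:1)"  ether linkage
#   omega suffix on a chain: 22:6n3

# CODATA monoisotopic atomic masses (Da)
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  Na = 22.9897692809
)
.ELECTRON_MASS <- 0.00054857990946
.PROTON_MASS <- .ATOMIC_MASS[["H"]] - .ELECTRON_MASS
.CH2_MASS <- .ATOMIC_MASS[["C"]] + 2 * .ATOMIC_MASS[["H"]]
.H2_MASS <- 2 * .ATOMIC_MASS[["H"]]

.pkg_cache <- new.env(parent = emptyenv())

#' Parse a chemical formula string into element counts
#'
#' @param formula string such as `"C8H20NO6P"`. Only C, H, N, O, P, Na are
#'   supported. `"C0"` denotes the empty formula.
#' @return named integer vector over `c(C, H, N, O, P)`.
#' @keywords internal
parse_formula <- function(formula) {
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L, P = 0L)
  if (identical(formula, "C0") || !nzchar(formula)) return(counts)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    lip_stop(sprintf("malformed formula '%s'", formula), "ParseError")
  }
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(counts)) counts[el] <- 0L
    counts[el] <- counts[el] + n
  }
  counts
}

formula_mass <- function(counts) {
  sum(counts * .ATOMIC_MASS[names(counts)])
}

#' Packaged lipid class templates
#'
#' Backbone ("core") formulas and slot structure per supported lipid class.
#' Loaded from a TSV shipped with the package so new classes can be added as
#' data rather than code.
#'
#' @param path optional path to an alternative template TSV.
#' @return data.frame with one row per class.
#' @export
lipid_class_templates <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_cache$templates)) return(.pkg_cache$templates)
    path <- system.file("extdata", "lipid_class_templates.tsv",
                        package = "lipidemt", mustWork = TRUE)
    tpl <- utils::read.delim(path, stringsAsFactors = FALSE)
    .pkg_cache$templates <- tpl
    return(tpl)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Supported lipid class names
#' @return character vector.
#' @export
lipid_classes <- function() lipid_class_templates()$class

.class_template <- function(lipid_class) {
  tpl <- lipid_class_templates()
  i <- match(lipid_class, tpl$class)
  if (is.na(i)) {
    lip_stop(sprintf("no backbone template registered for class '%s'",
                     lipid_class), "UnsupportedClass")
  }
  tpl[i, ]
}

#' Construct an acyl/alkyl chain descriptor
#'
#' @param carbons chain length (>= 2).
#' @param double_bonds number of C=C bonds (0 <= db <= carbons/2).
#' @param n_position optional omega position of the last double bond
#'   (e.g. 3 for "22:6n3"); `NA` when unspecified.
#' @param linkage `"ester"`, `"ether"`, `"amide"` or `"sphingoid"`.
#' @return a list of class `"acyl"`.
#' @export
acyl <- function(carbons, double_bonds, n_position = NA_integer_,
                 linkage = "ester") {
  carbons <- as.integer(carbons); double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 2L) {
    lip_stop("acyl carbons must be an integer >= 2", "ParseError")
  }
  if (is.na(double_bonds) || double_bonds < 0L ||
      double_bonds > carbons %/% 2L) {
    lip_stop(sprintf("invalid double bond count %d for %d carbons",
                     double_bonds, carbons), "ParseError")
  }
  if (!is.na(n_position)) {
    n_position <- as.integer(n_position)
    if (n_position < 1L || n_position > carbons) {
      lip_stop("omega (n) position must be in [1, carbons]", "ParseError")
    }
  }
  linkage <- match.arg(linkage, c("ester", "ether", "amide", "sphingoid"))
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 n_position = n_position, linkage = linkage),
            class = "acyl")
}

#' Parse a fatty-acid name such as "16:1" or "22:6n3"
#' @param name fatty-acid shorthand, optionally prefixed with "C" ("C16:1").
#' @param linkage passed to [acyl()].
#' @return an `"acyl"` object.
#' @export
parse_fatty_acid <- function(name, linkage = "ester") {
  m <- regmatches(name, regexec("^\\s*C?(\\d+):(\\d+)(n(\\d+))?\\s*$", name))[[1]]
  if (length(m) == 0) {
    lip_stop(sprintf("cannot parse fatty acid '%s'", name), "ParseError")
  }
  npos <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  acyl(as.integer(m[2]), as.integer(m[3]), npos, linkage)
}

format_fatty_acid <- function(a) {
  paste0(a$carbons, ":", a$double_bonds,
         if (!is.na(a$n_position)) paste0("n", a$n_position) else "")
}

.CLASS_LOOKUP <- c(LPC = "LPC", PC = "PC", PCO = "PC O-", PE = "PE",
                   PEO = "PE O-", TG = "TG", SM = "SM", CER = "Cer")

.ether_variant <- c(PC = "PC O-", PE = "PE O-")

#' Parse a shorthand lipid name
#'
#' Accepts the notation used throughout two-group lipidomics reports:
#' `"PC(34:1)"`, `"TG(17:0/17:0/17:0)"`, `"SM(d34:1)"`, `"Cer(d18:1/17:0)"`,
#' ether species as `"PC(O-34:1)"`, `"PC O-34:1"` or `"PC O-(16:0/18:1)"`.
#' Sphingolipid names without the hydroxyl prefix (`"Cer(18:1/17:0)"`) are
#' accepted and canonicalized to the di-hydroxy `d` form.
#'
#' @param name a single shorthand lipid name.
#' @return a `"lipid_species"` object with fields `lipid_class`, `backbone`,
#'   `acyls`, `sphingoid_hydroxyls`, `sum_carbons`, `sum_double_bonds` and
#'   `resolution` (`"species-sum"` or `"molecular-acyl"`).
#' @examples
#' parse_lipid_name("SM(d34:1)")
#' parse_lipid_name("TG(17:0/17:0/17:0)")
#' @export
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    lip_stop("lipid name must be a non-empty string", "ParseError")
  }
  raw <- trimws(name)
  if (grepl("\\(", raw)) {
    class_part <- trimws(sub("\\(.*$", "", raw))
    inner <- sub("^[^(]*\\(", "", raw)
    if (!grepl("\\)\\s*$", inner)) {
      lip_stop(sprintf("unbalanced parentheses in '%s'", raw), "ParseError")
    }
    inner <- trimws(sub("\\)\\s*$", "", inner))
  } else {
    m <- regmatches(raw, regexec("^([A-Za-z][A-Za-z -]*?)[ -]?([dtO]?-?\\d.*)$",
                                 raw))[[1]]
    if (length(m) == 0) {
      lip_stop(sprintf("cannot split class and chains in '%s'", raw),
               "ParseError")
    }
    class_part <- trimws(m[2]); inner <- trimws(m[3])
  }
  if (!nzchar(class_part)) {
    lip_stop(sprintf("missing lipid class in '%s'", raw), "ParseError")
  }
  key <- toupper(gsub("[^A-Za-z]", "", class_part))
  lipid_class <- unname(.CLASS_LOOKUP[key])
  if (is.na(lipid_class)) {
    lip_stop(sprintf("unknown lipid class token '%s'", class_part),
             "UnknownLipidClass")
  }

  chains <- strsplit(inner, "[/_]")[[1]]
  if (length(chains) == 0 || any(!nzchar(trimws(chains)))) {
    lip_stop(sprintf("malformed chain list in '%s'", raw), "ParseError")
  }
  chains <- trimws(chains)

  # chain prefixes: ether "O-", sphingoid "d"/"t"
  ether_chain <- grepl("^O-", chains)
  sph_prefix <- regmatches(chains, regexpr("^[dt]", chains))
  sph_chain <- grepl("^[dt]\\d", chains)
  chains_clean <- sub("^O-", "", chains)
  chains_clean <- sub("^[dt](?=\\d)", "", chains_clean, perl = TRUE)

  if (any(ether_chain[-1])) {
    lip_stop("ether 'O-' prefix is only accepted on the first chain",
             "ParseError")
  }
  if (ether_chain[1] && lipid_class %in% names(.ether_variant)) {
    lipid_class <- .ether_variant[[lipid_class]]
  }

  tpl <- .class_template(lipid_class)
  sphingoid <- isTRUE(tpl$sphingoid)
  hydroxyls <- NA_integer_
  if (sphingoid) {
    hydroxyls <- 2L
    if (sph_chain[1]) {
      hydroxyls <- if (identical(substr(chains[1], 1, 1), "t")) 3L else 2L
    }
  } else if (any(sph_chain)) {
    lip_stop(sprintf("sphingoid prefix not valid for class %s", lipid_class),
             "ParseError")
  }

  parsed <- vector("list", length(chains_clean))
  for (i in seq_along(chains_clean)) {
    link <- if (i == 1 && ether_chain[1]) "ether"
            else if (sphingoid && i == 1 && length(chains_clean) > 1) "sphingoid"
            else if (sphingoid) "amide"
            else "ester"
    parsed[[i]] <- tryCatch(parse_fatty_acid(chains_clean[i], linkage = link),
      error = function(e) {
        lip_stop(sprintf("malformed chain '%s' in '%s'", chains[i], raw),
                 "ParseError")
      })
  }

  n_slots <- tpl$n_acyls
  if (length(parsed) == 1L && n_slots > 1L) {
    resolution <- "species-sum"
    acyls <- list()
    sum_c <- parsed[[1]]$carbons
    sum_d <- parsed[[1]]$double_bonds
  } else if (length(parsed) == n_slots) {
    resolution <- "molecular-acyl"
    if (tpl$ether_slots > 0 && !ether_chain[1]) {
      # ether class written without an explicit O- chain prefix: first slot
      # carries the ether linkage by construction
      parsed[[1]]$linkage <- "ether"
    }
    acyls <- parsed
    sum_c <- sum(vapply(parsed, `[[`, integer(1), "carbons"))
    sum_d <- sum(vapply(parsed, `[[`, integer(1), "double_bonds"))
  } else {
    lip_stop(sprintf("class %s expects 1 (sum) or %d (molecular) chains, got %d",
                     lipid_class, n_slots, length(parsed)), "ParseError")
  }

  structure(list(
    lipid_class = lipid_class,
    backbone = tpl$backbone,
    acyls = acyls,
    sphingoid_hydroxyls = hydroxyls,
    sum_carbons = sum_c,
    sum_double_bonds = sum_d,
    resolution = resolution
  ), class = "lipid_species")
}

#' Canonical shorthand name of a lipid species
#'
#' Inverse of [parse_lipid_name()]: `parse_lipid_name(format_lipid_name(x))`
#' reproduces `x`.
#'
#' @param species a `"lipid_species"` object.
#' @return canonical shorthand string.
#' @export
format_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  tpl <- .class_template(species$lipid_class)
  base_class <- sub(" O-$", "", species$lipid_class)
  sph <- isTRUE(tpl$sphingoid)
  prefix <- ""
  if (sph) prefix <- if (identical(species$sphingoid_hydroxyls, 3L)) "t" else "d"
  if (tpl$ether_slots > 0) prefix <- "O-"
  if (species$resolution == "species-sum") {
    body <- paste0(prefix, species$sum_carbons, ":", species$sum_double_bonds)
  } else {
    toks <- vapply(species$acyls, format_fatty_acid, character(1))
    toks[1] <- paste0(prefix, toks[1])
    body <- paste(toks, collapse = "/")
  }
  paste0(base_class, "(", body, ")")
}

#' @export
format.lipid_species <- function(x, ...) format_lipid_name(x)

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  [%s, %s, %d:%d]\n",
              format_lipid_name(x), x$lipid_class, x$resolution,
              x$sum_carbons, x$sum_double_bonds))
  invisible(x)
}

#' Saturation class of fatty acyl chains
#'
#' Maps double-bond counts to the saturation buckets used in the composition
#' figures: 0 -> SFA, 1 -> MUFA, 2 -> DUFA, >= 3 -> PUFA. The PUFA cut-off of
#' three or more C=C bonds follows the study's definition; di-unsaturated
#' chains get their own DUFA bucket so they are excluded from the three-way
#' SFA/MUFA/PUFA summary by default.
#'
#' @param x an `"acyl"` object, a fatty-acid name (e.g. "22:6n3") or an
#'   integer vector of double-bond counts; vectors are handled element-wise.
#' @param thresholds named numeric vector giving the minimum double-bond
#'   count for MUFA, DUFA and PUFA.
#' @return factor with levels SFA, MUFA, DUFA, PUFA.
#' @export
saturation_class <- function(x, thresholds = c(MUFA = 1, DUFA = 2, PUFA = 3)) {
  db <- if (inherits(x, "acyl")) x$double_bonds
        else if (is.character(x)) {
          vapply(x, function(s) parse_fatty_acid(s)$double_bonds, integer(1))
        } else as.integer(x)
  stopifnot(all(db >= 0))
  out <- ifelse(db >= thresholds[["PUFA"]], "PUFA",
         ifelse(db >= thresholds[["DUFA"]], "DUFA",
         ifelse(db >= thresholds[["MUFA"]], "MUFA", "SFA")))
  factor(out, levels = c("SFA", "MUFA", "DUFA", "PUFA"))
}

# Elemental increments:
#   ester  acyl (c,d): +C_c H_{2c-2-2d} O        (fatty acid minus H2O)
#   ether  alkyl (c,d): +C_c H_{2c-2d}           (fatty alcohol minus H2O)
#   sphingolipid totals (C,D over base + N-acyl, h hydroxyls):
#     +C_C H_{2C+1-2D} N O_{h+1}
.acyl_counts <- function(carbons, double_bonds, linkage) {
  switch(linkage,
    ester = c(C = carbons, H = 2L * carbons - 2L - 2L * double_bonds,
              N = 0L, O = 1L, P = 0L),
    ether = c(C = carbons, H = 2L * carbons - 2L * double_bonds,
              N = 0L, O = 0L, P = 0L),
    lip_stop(sprintf("no elemental increment for linkage '%s'", linkage),
             "UnsupportedClass"))
}

#' Elemental composition and monoisotopic mass of a lipid species
#'
#' Assembles the molecular formula from the packaged class backbone template
#' plus per-chain increments, for both species-sum and molecular-acyl
#' resolution. Each added CH2 increases the monoisotopic mass by the C + 2H
#' increment, each double bond removes H2.
#'
#' @param species a `"lipid_species"` or shorthand name string.
#' @return list of class `"elemental_composition"`: `counts` (named integer
#'   vector over C, H, N, O, P) and `monoisotopic_mass` (Da).
#' @examples
#' elemental_composition("PC(16:0/16:0)")  # DPPC, C40H80NO8P
#' @export
elemental_composition <- function(species) {
  if (is.character(species)) species <- parse_lipid_name(species)
  stopifnot(inherits(species, "lipid_species"))
  tpl <- .class_template(species$lipid_class)
  counts <- parse_formula(tpl$core_formula)

  if (isTRUE(tpl$sphingoid)) {
    h <- if (is.na(species$sphingoid_hydroxyls)) 2L else species$sphingoid_hydroxyls
    C <- species$sum_carbons; D <- species$sum_double_bonds
    counts["C"] <- counts["C"] + C
    counts["H"] <- counts["H"] + 2L * C + 1L - 2L * D
    counts["N"] <- counts["N"] + 1L
    counts["O"] <- counts["O"] + h + 1L
  } else if (species$resolution == "molecular-acyl") {
    for (a in species$acyls) {
      inc <- .acyl_counts(a$carbons, a$double_bonds, a$linkage)
      counts[names(inc)] <- counts[names(inc)] + inc
    }
  } else {
    n_ester <- tpl$n_acyls - tpl$ether_slots
    C <- species$sum_carbons; D <- species$sum_double_bonds
    counts["C"] <- counts["C"] + C
    counts["H"] <- counts["H"] + 2L * C - 2L * D - 2L * n_ester
    counts["O"] <- counts["O"] + n_ester
  }
  if (any(counts < 0)) {
    lip_stop(sprintf("implausible composition for %s", format_lipid_name(species)),
             "ParseError")
  }
  structure(list(counts = counts, monoisotopic_mass = formula_mass(counts)),
            class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat(sprintf("<elemental_composition> %s  %.5f Da\n",
              paste0(names(nz), nz, collapse = ""), x$monoisotopic_mass))
  invisible(x)
}

#' Monoisotopic mass of a lipid species
#' @inheritParams elemental_composition
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(species) {
  elemental_composition(species)$monoisotopic_mass
}

#' Default electrospray adduct table
#'
#' Singly charged adducts commonly formed under ammonium-acetate/formic-acid
#' mobile phases. The `delta` column is the m/z shift relative to the neutral
#' monoisotopic mass (electron mass included).
#'
#' @return data.frame with columns `adduct`, `delta`, `polarity`.
#' @export
default_adducts <- function() {
  nh4 <- .ATOMIC_MASS[["N"]] + 4 * .ATOMIC_MASS[["H"]] - .ELECTRON_MASS
  hcoo <- .ATOMIC_MASS[["C"]] + .ATOMIC_MASS[["H"]] +
    2 * .ATOMIC_MASS[["O"]] + .ELECTRON_MASS
  data.frame(
    adduct = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+HCOO]-"),
    delta = c(.PROTON_MASS, nh4, .ATOMIC_MASS[["Na"]] - .ELECTRON_MASS,
              -.PROTON_MASS, hcoo),
    polarity = c("+", "+", "+", "-", "-"),
    stringsAsFactors = FALSE
  )
}

#' m/z of a neutral mass under an adduct
#'
#' @param mass neutral monoisotopic mass (Da), vectorized.
#' @param adduct one of the adduct names in `adducts` (e.g. `"[M+H]+"`).
#' @param adducts adduct table, see [default_adducts()].
#' @return m/z value(s).
#' @export
mz_for_adduct <- function(mass, adduct, adducts = default_adducts()) {
  stopifnot(all(mass > 0))
  i <- match(adduct, adducts$adduct)
  if (is.na(i)) {
    lip_stop(sprintf("unknown adduct '%s'", adduct), "UnknownAdduct")
  }
  mass + adducts$delta[i]
}

#' Esterified fatty-acid constituents of a molecular species
#'
#' Returns the fatty-acid names contributed by ester- and amide-linked chains
#' (the chains that appear in a FAME preparation). Sphingoid bases and ether
#' alkyls are not esterified fatty acids and are excluded.
#'
#' @param species a `"lipid_species"` or name string.
#' @return character vector of fatty-acid names (possibly empty for
#'   species-sum resolution).
#' @export
lipid_acyls <- function(species) {
  if (is.character(species)) species <- parse_lipid_name(species)
  if (species$resolution != "molecular-acyl") return(character(0))
  keep <- vapply(species$acyls, function(a) a$linkage %in% c("ester", "amide"),
                 logical(1))
  vapply(species$acyls[keep], format_fatty_acid, character(1))
}
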