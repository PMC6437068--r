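# Synthetic two-group lipidome / MS/MS / FAME / transcript generators with
# full ground truth, emulating a 5 + 5 adherent-vs-mammosphere design over
# ~123 species in 8 classes with class-specific spiked internal standards.
#
# The "paper" preset plants the EMT lipidome signature: ceramides up,
# ether-linked PC and PE down, C16:1-containing species up, species with >= 3
# double bonds down, MUFA/SFA indices up and elongation indices (including
# DHA/22:5n3) down, with SCD/ACOX3/FADS1 transcripts up and
# PTPLB/PECR/ELOVL2/ELOVL3 down. The "null" preset removes every effect.

#' The packaged 123-species lipid panel
#'
#' A fixed panel spanning LPC (8), PC (30), PC O- (10), PE (20), PE O- (10),
#' TG (25), SM (12) and Cer (8), written at molecular-acyl resolution where
#' the class rules use acyl evidence and species-sum for SM.
#'
#' @return character vector of 123 shorthand names.
#' @export
default_species_panel <- function() {
  pc <- c("14:0/16:0", "14:0/16:1", "14:0/18:1", "16:0/16:0", "16:0/16:1",
          "16:1/16:1", "16:0/18:0", "16:0/18:1", "16:1/18:1", "16:0/18:2",
          "16:1/18:2", "18:0/18:1", "18:1/18:1", "18:0/18:2", "18:1/18:2",
          "18:2/18:2", "16:0/20:3", "18:1/20:3", "16:0/20:4", "16:1/20:4",
          "18:0/20:4", "18:1/20:4", "16:0/20:5", "16:0/22:5", "18:0/22:5",
          "16:0/22:6", "18:0/22:6", "18:1/22:6", "15:0/18:1", "16:0/18:3")
  lpc <- c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2", "20:4", "22:6")
  pco <- c("O-16:0/16:0", "O-16:0/16:1", "O-16:0/18:1", "O-16:0/18:2",
           "O-16:0/20:4", "O-16:0/22:6", "O-18:0/18:1", "O-18:0/20:4",
           "O-18:1/18:1", "O-18:0/22:6")
  pe <- c("16:0/16:0", "16:0/16:1", "16:0/18:1", "16:0/18:2", "16:0/20:3",
          "16:0/20:4", "16:0/22:5", "16:0/22:6", "16:1/18:1", "18:0/18:1",
          "18:0/18:2", "18:0/20:3", "18:0/20:4", "18:0/22:5", "18:0/22:6",
          "18:1/18:1", "18:1/18:2", "18:1/20:4", "18:1/20:5", "18:1/22:6")
  peo <- c("O-16:0/18:1", "O-16:0/18:2", "O-16:0/20:4", "O-16:0/22:6",
           "O-18:0/18:1", "O-18:0/20:4", "O-18:0/22:6", "O-18:1/18:1",
           "O-18:1/20:4", "O-18:1/22:6")
  tg <- c("14:0/16:0/16:0", "14:0/16:0/18:1", "14:0/16:1/18:1",
          "14:0/18:1/18:2", "16:0/16:0/16:0", "16:0/16:0/18:1",
          "16:0/16:0/18:2", "16:0/16:0/20:4", "16:0/16:0/22:6",
          "16:0/16:1/16:1", "16:0/16:1/18:1", "16:0/18:0/18:1",
          "16:0/18:1/18:1", "16:0/18:1/18:2", "16:0/18:1/20:4",
          "16:0/18:1/22:6", "16:0/18:2/18:2", "16:1/18:1/18:1",
          "18:0/18:1/18:1", "18:1/18:1/18:1", "18:1/18:1/18:2",
          "18:1/18:1/20:4", "18:1/18:1/22:6", "18:1/18:2/18:2",
          "16:1/16:1/18:1")
  sm <- c("d32:1", "d34:1", "d34:2", "d36:1", "d36:2", "d38:1", "d40:1",
          "d40:2", "d42:1", "d42:2", "d42:3", "d44:1")
  cer <- c("d18:1/14:0", "d18:1/16:0", "d18:1/18:0", "d18:1/20:0",
           "d18:1/22:0", "d18:1/24:0", "d18:1/24:1", "d18:1/26:1")
  c(paste0("LPC(", lpc, ")"), paste0("PC(", pc, ")"), paste0("PC(", pco, ")"),
    paste0("PE(", pe, ")"), paste0("PE(", peo, ")"), paste0("TG(", tg, ")"),
    paste0("SM(", sm, ")"), paste0("Cer(", cer, ")"))
}

# Sphere-vs-adherent multipliers on the true FAME composition. Chosen so each
# planted index direction has comfortable power at n = 5 (see the methods
# vignette): the weakest planted log-ratio shift is |log10 0.68| = 0.167
# against a per-sample log10 area noise of 0.03.
.FAME_BASE <- c("14:0" = 2, "16:0" = 22, "16:1" = 4, "18:0" = 12,
                "18:1" = 24, "18:2" = 8, "18:3" = 1, "20:0" = 1,
                "20:4" = 6, "20:5" = 1.5, "22:0" = 0.6, "22:5n3" = 1.5,
                "22:6n3" = 4, "24:0" = 0.9)
.FAME_SPHERE_MULT <- c("14:0" = 1, "16:0" = 1.25, "16:1" = 2.4, "18:0" = 0.85,
                       "18:1" = 1.5, "18:2" = 1, "18:3" = 0.6, "20:0" = 0.63,
                       "20:4" = 0.5, "20:5" = 0.5, "22:0" = 0.44,
                       "22:5n3" = 1, "22:6n3" = 0.4, "24:0" = 1)
.EXPR_MEANS <- c(SCD = 1.5, ACOX3 = 0.8, FADS1 = 0.9, PTPLB = -1.2,
                 PECR = -1.0, ELOVL2 = -2.0, ELOVL3 = -1.1)

#' Generator configuration
#'
#' Defaults encode the study conditions: two groups (Adherent, Sphere), five
#' samples each, the 123-species panel, class-specific internal standards at
#' their spiked amounts, log-normal intensities, and the planted EMT effects.
#' The `"null"` preset keeps the same structure with every effect removed
#' (for type-I error and permutation checks).
#'
#' @param preset `"paper"` (planted EMT effects) or `"null"` (no effects).
#' @param n_per_group samples per group (default 5).
#' @param species character vector of shorthand names (default panel).
#' @param class_effects named multiplicative Sphere/Adherent shifts per class.
#' @param effect_16_1 multiplier for C16:1-containing species.
#' @param effect_pufa multiplier for species containing a chain with >= 3
#'   double bonds (or a species-sum with >= 3 double bonds).
#' @param log10_noise_sd per-sample intensity noise, log10 units.
#' @param species_sd between-species abundance spread, log10 units.
#' @param is_noise_sd internal-standard intensity noise, log10 units.
#' @param fame_noise_sd GC area noise, log10 units.
#' @param fame_mult named Sphere multipliers on the true FAME composition.
#' @param expr_means named mean transcript log2 fold-changes.
#' @param expr_sd transcript log2 fold-change noise.
#' @param mass_error_ppm precursor mass error bound (errors are uniform within
#'   +/- this many ppm, emulating a calibrated instrument).
#' @param decoy_fraction decoy spectra as a fraction of true spectra.
#' @param protein_mean,protein_sd per-sample protein amount (ug).
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(preset = c("paper", "null"),
                         n_per_group = 5,
                         species = default_species_panel(),
                         class_effects = c("Cer" = 2.2, "PC O-" = 0.45,
                                           "PE O-" = 0.45),
                         effect_16_1 = 2.2,
                         effect_pufa = 0.40,
                         log10_noise_sd = 0.10,
                         species_sd = 0.4,
                         is_noise_sd = 0.05,
                         fame_noise_sd = 0.03,
                         fame_mult = .FAME_SPHERE_MULT,
                         expr_means = .EXPR_MEANS,
                         expr_sd = 0.1,
                         mass_error_ppm = 5,
                         decoy_fraction = 0.2,
                         protein_mean = 100,
                         protein_sd = 5) {
  preset <- match.arg(preset)
  if (preset == "null") {
    class_effects[] <- 1
    effect_16_1 <- 1
    effect_pufa <- 1
    fame_mult[] <- 1
    expr_means[] <- 0
  }
  stopifnot(n_per_group >= 2, decoy_fraction >= 0, decoy_fraction <= 1,
            mass_error_ppm >= 0)
  structure(list(preset = preset, n_per_group = n_per_group, species = species,
                 class_effects = class_effects, effect_16_1 = effect_16_1,
                 effect_pufa = effect_pufa, log10_noise_sd = log10_noise_sd,
                 species_sd = species_sd, is_noise_sd = is_noise_sd,
                 fame_noise_sd = fame_noise_sd, fame_mult = fame_mult,
                 expr_means = expr_means, expr_sd = expr_sd,
                 mass_error_ppm = mass_error_ppm,
                 decoy_fraction = decoy_fraction,
                 protein_mean = protein_mean, protein_sd = protein_sd),
            class = "synth_config")
}

.CLASS_LOG10_OFFSET <- c("LPC" = 4.5, "PC" = 6.0, "PC O-" = 5.0, "PE" = 5.8,
                         "PE O-" = 5.0, "TG" = 6.2, "SM" = 5.5, "Cer" = 4.8)

# classify a species against the planted effect model
.species_effect <- function(sp, config) {
  eff <- 1
  ce <- config$class_effects
  if (sp$lipid_class %in% names(ce)) eff <- eff * ce[[sp$lipid_class]]
  if (sp$resolution == "molecular-acyl") {
    dbs <- vapply(sp$acyls, `[[`, integer(1), "double_bonds")
    cs <- vapply(sp$acyls, `[[`, integer(1), "carbons")
    has161 <- any(cs == 16 & dbs == 1)
    pufa <- any(dbs >= 3)
  } else {
    has161 <- FALSE
    pufa <- sp$sum_double_bonds >= 3
  }
  if (has161) eff <- eff * config$effect_16_1
  if (pufa) eff <- eff * config$effect_pufa
  list(effect = eff, has_16_1 = has161, pufa = pufa)
}

#' Generate a two-group synthetic lipidome peak table
#'
#' Log-normal per-class intensities with planted multiplicative Sphere
#' effects, the five spiked internal standards, and per-sample protein
#' amounts. Fully reproducible per seed.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (mandatory for reproducibility).
#' @return list: `table` (a `"peak_table"`), `truth` (per-species effect and
#'   flags, per-sample group).
#' @export
generate_lipidome <- function(config = synth_config(), seed = 1L) {
  parsed <- lapply(config$species, parse_lipid_name)
  classes <- vapply(parsed, `[[`, character(1), "lipid_class")
  if (length(unique(classes)) < 8 && length(config$species) < 8) {
    lip_stop("need at least one species per class (>= 8 species)",
             "InsufficientData")
  }
  n <- config$n_per_group
  groups <- rep(c("Adherent", "Sphere"), each = n)
  sample_ids <- paste0(rep(c("ADH", "SPH"), each = n), seq_len(n))

  effs <- lapply(parsed, .species_effect, config = config)
  effect <- vapply(effs, `[[`, numeric(1), "effect")

  lib <- build_species_library(config$species)
  names_canon <- lib$name

  with_seed(seed, {
    base <- .CLASS_LOG10_OFFSET[classes] +
      stats::rnorm(length(parsed), 0, config$species_sd)
    mu <- outer(base, rep(0, 2 * n), "+")
    mu[, groups == "Sphere"] <- mu[, groups == "Sphere"] + log10(effect)
    ints <- 10^(mu + matrix(stats::rnorm(length(mu), 0, config$log10_noise_sd),
                            nrow(mu)))

    is_map <- default_standard_map()
    std_names <- unique(is_map$standard)
    std_class <- vapply(std_names,
                        function(nm) parse_lipid_name(nm)$lipid_class,
                        character(1))
    std_ints <- 10^(matrix(.CLASS_LOG10_OFFSET[std_class], length(std_names),
                           2 * n) +
                    matrix(stats::rnorm(length(std_names) * 2 * n, 0,
                                        config$is_noise_sd),
                           length(std_names)))
    protein <- stats::rnorm(2 * n, config$protein_mean, config$protein_sd)
    protein <- pmax(protein, config$protein_mean / 2)
  })

  std_lib <- build_species_library(std_names)
  features <- data.frame(
    name = c(names_canon, std_names),
    class = c(classes, std_class),
    mz = c(lib$mz, std_lib$mz),
    rt = seq(2, 30, length.out = length(names_canon) + length(std_names)),
    is_standard = c(rep(FALSE, length(names_canon)),
                    rep(TRUE, length(std_names))),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = sample_ids, group = groups,
                        protein_ug = protein, stringsAsFactors = FALSE)
  tab <- peak_table(rbind(ints, std_ints), features, samples)

  truth <- list(
    species = data.frame(
      name = names_canon, class = classes, effect = effect,
      direction = ifelse(effect > 1, "up", ifelse(effect < 1, "down",
                                                  "unchanged")),
      has_16_1 = vapply(effs, `[[`, logical(1), "has_16_1"),
      pufa = vapply(effs, `[[`, logical(1), "pufa"),
      stringsAsFactors = FALSE),
    groups = groups, seed = seed, preset = config$preset
  )
  list(table = tab, truth = truth)
}

#' Generate MS/MS spectra with hard decoys
#'
#' True spectra carry every required (and optional) class-diagnostic fragment
#' of their species with bounded precursor mass error, fragment m/z jitter and
#' a few random noise peaks. Decoys match a real precursor but carry the
#' diagnostic fragments of a different class with disjoint evidence
#' (fragment-swapped hard negatives), so they violate the class rules.
#'
#' @param species character vector of shorthand names (a rule must exist for
#'   every class).
#' @param rules fragmentation rule table.
#' @param mass_error_ppm precursor error bound (uniform within +/- ppm).
#' @param decoy_fraction decoys as a fraction of true spectra.
#' @param seed integer seed.
#' @param frag_jitter fragment m/z jitter bound in Da (default 0.005).
#' @param n_noise_peaks random peaks added per spectrum (default 5).
#' @return list: `spectra` (list of `"spectrum_record"`), `truth`
#'   (data.frame: title, species or NA, decoy flag).
#' @export
generate_msms <- function(species, rules = fragmentation_rules(),
                          mass_error_ppm = 5, decoy_fraction = 0.2,
                          seed = 1L, frag_jitter = 0.005, n_noise_peaks = 5) {
  lib <- build_species_library(species)
  missing_rules <- setdiff(lib$class, rules$class)
  if (length(missing_rules)) {
    lip_stop(sprintf("no fragmentation rules for class(es): %s",
                     paste(missing_rules, collapse = ", ")), "MissingRule")
  }
  decoy_partner <- c("LPC" = "TG", "PC" = "TG", "PC O-" = "TG", "SM" = "TG",
                     "TG" = "PC", "PE" = "Cer", "PE O-" = "Cer", "Cer" = "PE")
  partner_pool <- split(seq_len(nrow(lib)), lib$class)

  n_true <- nrow(lib)
  n_decoy <- round(decoy_fraction * n_true)
  if (n_decoy > 0) {
    need <- unique(decoy_partner[unique(lib$class)])
    absent <- setdiff(need, lib$class)
    if (length(absent)) {
      lip_stop(sprintf(
        "decoy generation needs fragment-donor class(es) %s in the library",
        paste(absent, collapse = ", ")), "MissingRule")
    }
  }

  with_seed(seed, {
    spectra <- vector("list", n_true + n_decoy)
    truth <- data.frame(title = character(n_true + n_decoy),
                        species = NA_character_, decoy = FALSE,
                        stringsAsFactors = FALSE)
    make_peaks <- function(frag_mz) {
      mz <- frag_mz + stats::runif(length(frag_mz), -frag_jitter, frag_jitter)
      intensity <- 10^stats::runif(length(frag_mz), 3, 5)
      noise_mz <- stats::runif(n_noise_peaks, 100, 900)
      noise_int <- 10^stats::runif(n_noise_peaks, 2, 3)
      cbind(c(mz, noise_mz), c(intensity, noise_int))
    }
    for (i in seq_len(n_true)) {
      err <- stats::runif(1, -mass_error_ppm, mass_error_ppm) * 1e-6
      prec <- lib$mz[i] * (1 + err)
      frags <- expected_fragments(lib$name[i], prec, rules)
      frags <- frags[frags$role %in% c("required", "optional"), , drop = FALSE]
      spectra[[i]] <- spectrum_record(prec, lib$polarity[i],
                                      make_peaks(frags$mz),
                                      rt = stats::runif(1, 2, 30),
                                      title = sprintf("true_%03d", i))
      truth$title[i] <- sprintf("true_%03d", i)
      truth$species[i] <- lib$name[i]
    }
    if (n_decoy > 0) {
      targets <- sample.int(n_true, n_decoy, replace = n_decoy > n_true)
      for (k in seq_len(n_decoy)) {
        i <- targets[k]
        err <- stats::runif(1, -mass_error_ppm, mass_error_ppm) * 1e-6
        prec <- lib$mz[i] * (1 + err)
        partner_class <- decoy_partner[[lib$class[i]]]
        pool <- partner_pool[[partner_class]]
        j <- pool[sample.int(length(pool), 1)]
        frags <- expected_fragments(lib$name[j], prec, rules)
        frags <- frags[frags$role == "required", , drop = FALSE]
        spectra[[n_true + k]] <- spectrum_record(
          prec, lib$polarity[i], make_peaks(frags$mz),
          rt = stats::runif(1, 2, 30), title = sprintf("decoy_%03d", k))
        truth$title[n_true + k] <- sprintf("decoy_%03d", k)
        truth$decoy[n_true + k] <- TRUE
      }
    }
  })
  list(spectra = spectra, truth = truth)
}

#' Generate a synthetic GC-MS FAME area table
#'
#' Areas are `true composition x RRF x per-sample IS scaling x log-normal
#' noise`, with the C23:0 internal standard row included.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param rrf named relative response factors (default: mildly heterogeneous,
#'   returned in the output for use in [fame_composition()]).
#' @return list: `areas` (matrix fatty acids + IS x samples), `rrf`,
#'   `is_name`, `is_amount`, `truth` (true compositions per group, planted
#'   multipliers, expected index directions), `groups`.
#' @export
generate_fame <- function(config = synth_config(), seed = 1L, rrf = NULL) {
  base <- .FAME_BASE / sum(.FAME_BASE) * 100
  mult <- config$fame_mult[names(base)]
  sphere <- base * mult
  sphere <- sphere / sum(sphere) * 100
  n <- config$n_per_group
  groups <- rep(c("Adherent", "Sphere"), each = n)
  sample_ids <- paste0(rep(c("ADH", "SPH"), each = n), seq_len(n))
  fa <- names(base)
  if (is.null(rrf)) {
    rrf <- stats::setNames(rep(c(0.9, 1, 1.1), length.out = length(fa)), fa)
  }
  is_amount <- 5  # ug C23:0 FAME spiked
  true_comp <- cbind(matrix(base, length(fa), n),
                     matrix(sphere, length(fa), n))
  with_seed(seed, {
    total_fa <- stats::rnorm(2 * n, 50, 3)  # ug esterified FA per sample
    is_area <- 10^stats::rnorm(2 * n, 5, config$fame_noise_sd)
    amounts <- sweep(true_comp / 100, 2, total_fa, "*")
    areas <- sweep(amounts * rrf / is_amount, 2, is_area, "*") *
      10^matrix(stats::rnorm(length(amounts), 0, config$fame_noise_sd),
                nrow(amounts))
  })
  areas <- rbind(areas, "23:0" = is_area)
  rownames(areas) <- c(fa, "23:0")
  colnames(areas) <- sample_ids
  expected_dir <- c("16:1/16:0" = "up", "18:1/18:0" = "up",
                    "18:0/16:0" = "down", "20:0/18:0" = "down",
                    "22:0/20:0" = "down", "22:6n3/22:5n3" = "down")
  if (config$preset == "null") expected_dir[] <- "unchanged"
  list(areas = areas, rrf = rrf, is_name = "23:0", is_amount = is_amount,
       groups = groups,
       truth = list(adherent = base, sphere = sphere, mult = mult,
                    index_directions = expected_dir, seed = seed))
}

#' Generate transcript log2 fold-changes for the pathway genes
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return list: `expr` (named numeric log2 fold-changes), `truth` (configured
#'   means and expected signs).
#' @export
generate_expression <- function(config = synth_config(), seed = 1L) {
  mu <- config$expr_means
  expr <- with_seed(seed, mu + stats::rnorm(length(mu), 0, config$expr_sd))
  names(expr) <- names(mu)
  list(expr = expr,
       truth = list(means = mu, signs = sign(mu), seed = seed))
}
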