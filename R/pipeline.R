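# Pipeline orchestration: a validated configuration object and a single entry
# point that chains identify -> quantify -> stats -> pathway on synthetic or
# user-supplied inputs, writing TSV tables plus a JSON summary.

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#'
#' @param seed master seed for every stochastic stage.
#' @param preset synthetic preset forwarded to [synth_config()] when no input
#'   files are given.
#' @param out_dir output directory (created if needed).
#' @param peak_table_file,mgf_file,fame_file,expression_file optional input
#'   paths; when NULL the corresponding synthetic generator supplies the data.
#' @param tol_ppm,frag_tol identification tolerances (ppm / Da).
#' @param p_gate,q_gate statistical gates (defaults 0.05 / 0.10).
#' @param vip_threshold VIP importance cut-off (default 1).
#' @param n_components PLS-DA components, integer or `"auto"`.
#' @param composition_scope `"total"` or `"within-class"`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, preset = "paper", out_dir = tempfile("lipidemt_"),
                            peak_table_file = NULL, mgf_file = NULL,
                            fame_file = NULL, expression_file = NULL,
                            tol_ppm = 10, frag_tol = 0.02,
                            p_gate = 0.05, q_gate = 0.10,
                            vip_threshold = 1, n_components = "auto",
                            composition_scope = "total") {
  cfg <- list(seed = as.integer(seed), preset = preset, out_dir = out_dir,
              peak_table_file = peak_table_file, mgf_file = mgf_file,
              fame_file = fame_file, expression_file = expression_file,
              tol_ppm = tol_ppm, frag_tol = frag_tol, p_gate = p_gate,
              q_gate = q_gate, vip_threshold = vip_threshold,
              n_components = n_components,
              composition_scope = match.arg(composition_scope,
                                            c("total", "within-class")))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys must match the arguments of [pipeline_config()]; unknown keys raise an
#' error.
#'
#' @param path YAML file.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    lip_stop(sprintf("unknown configuration key(s): %s",
                     paste(bad, collapse = ", ")), "ParseError")
  }
  do.call(pipeline_config, vals)
}

.write_tsv <- function(x, dir, name) {
  if (is.matrix(x)) x <- data.frame(feature = rownames(x), x,
                                    check.names = FALSE)
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages run in order: identification (MS/MS spectra against the species
#' library), quantification (internal-standard and protein normalization,
#' compositions), statistics (preprocessing, t-tests with BH FDR, PCA, PLS-DA
#' with VIP and Q2), and pathway (FAME indices, transcript overlay, sign
#' concordance). Every stage's table is written to `config$out_dir` together
#' with `summary.json`; re-running with the same config and seed reproduces
#' the outputs byte for byte.
#'
#' Inputs default to the synthetic generators under `config$preset`; supply
#' file paths in the config to analyze real data (peak table TSV, MGF spectra,
#' FAME area TSV, two-column gene/log2fc TSV).
#'
#' @param config a `"pipeline_config"`.
#' @return (invisibly) a list with the stage results and the summary list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("peak_table_file", "mgf_file", "fame_file", "expression_file")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      lip_stop(sprintf("input file for %s not found: %s", f, config[[f]]),
               "MissingInput")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  scfg <- synth_config(preset = config$preset)

  # --- stage: identify -------------------------------------------------
  if (is.null(config$mgf_file)) {
    ms <- generate_msms(scfg$species, mass_error_ppm = scfg$mass_error_ppm,
                        decoy_fraction = scfg$decoy_fraction, seed = seed)
    spectra <- ms$spectra
  } else {
    spectra <- read_mgf(config$mgf_file)
  }
  library_tbl <- build_species_library(scfg$species)
  hits <- identify_dataset(spectra, library_tbl, tol_ppm = config$tol_ppm,
                           frag_tol = config$frag_tol)
  identified <- confirmed_species(hits)
  .write_tsv(as.data.frame(hits), config$out_dir, "identification.tsv")

  # --- stage: quantify -------------------------------------------------
  if (is.null(config$peak_table_file)) {
    lip <- generate_lipidome(scfg, seed = seed)
    tab <- lip$table
  } else {
    tab <- read_peak_table(config$peak_table_file)
  }
  keep <- tab$features$is_standard | tab$features$name %in% identified
  tab <- tab[keep, ]
  amounts <- is_normalize(tab)
  amounts_prot <- protein_normalize(amounts, tab$samples$protein_ug)
  attr(amounts_prot, "features") <- attr(amounts, "features")
  cls_comp <- class_composition(amounts_prot)
  sp_comp <- species_composition(amounts_prot, scope = config$composition_scope,
                                 classes = attr(amounts, "features")$class)
  .write_tsv(amounts_prot, config$out_dir, "amounts.tsv")
  .write_tsv(cls_comp, config$out_dir, "class_composition.tsv")
  .write_tsv(sp_comp, config$out_dir, "species_composition.tsv")

  # --- stage: stats ----------------------------------------------------
  # univariate gates on log2 amounts; quantile + log + pareto is the
  # multivariate (PCA / PLS-DA) preprocessing
  groups <- tab$samples$group
  X_uni <- preprocess_lipidome(amounts_prot, quantile = FALSE, pareto = FALSE)
  X <- preprocess_lipidome(amounts_prot)
  tests <- ttest_bh(X_uni, groups, p_gate = config$p_gate,
                    q_gate = config$q_gate)
  pc <- pca(X, n_components = 2)
  model <- plsda(X, groups, n_components = config$n_components, seed = seed)
  model$Q2 <- q2_cv(X, groups, n_components = model$n_components,
                    seed = seed)$Q2
  vips <- vip(model)
  .write_tsv(as.data.frame(tests), config$out_dir, "ttest.tsv")
  .write_tsv(data.frame(feature = names(vips), vip = vips), config$out_dir,
             "vip.tsv")
  .write_tsv(pc$scores, config$out_dir, "pca_scores.tsv")

  # --- stage: pathway --------------------------------------------------
  if (is.null(config$fame_file)) {
    fame <- generate_fame(scfg, seed = seed)
    profile <- fame_composition(fame$areas, rrf = fame$rrf,
                                is_name = fame$is_name,
                                is_amount = fame$is_amount)
    fame_groups <- fame$groups
  } else {
    areas <- as.matrix(utils::read.delim(config$fame_file, row.names = 1))
    profile <- fame_composition(areas)
    fame_groups <- groups
  }
  if (is.null(config$expression_file)) {
    expr <- generate_expression(scfg, seed = seed)$expr
  } else {
    e <- utils::read.delim(config$expression_file)
    expr <- stats::setNames(e[[2]], e[[1]])
  }
  map <- default_pathway_map()
  ratios <- compute_indices(profile, map)
  idx <- compare_indices(ratios, fame_groups, p_gate = config$p_gate)
  annotated <- overlay_expression(map, expr)
  conc <- concordance(idx, annotated, seed = seed)
  .write_tsv(as.data.frame(idx), config$out_dir, "index_results.tsv")
  .write_tsv(as.data.frame(annotated), config$out_dir, "pathway_overlay.tsv")

  summary <- list(
    seed = seed,
    preset = if (is.null(config$peak_table_file)) config$preset else "user-data",
    n_spectra = length(spectra),
    n_identified = length(identified),
    n_species_quantified = sum(!tab$features$is_standard),
    n_significant = sum(tests$significant),
    plsda_n_components = model$n_components,
    R2Y = model$R2Y,
    Q2 = model$Q2,
    n_vip_ge_threshold = sum(vips >= config$vip_threshold),
    index_directions = as.list(stats::setNames(idx$direction, idx$step)),
    concordance = conc$concordance,
    concordance_p = conc$p_value
  )
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE)
  writeLines(json, file.path(config$out_dir, "summary.json"))

  invisible(list(hits = hits, amounts = amounts_prot,
                 class_composition = cls_comp, tests = tests, pca = pc,
                 model = model, vip = vips, indices = idx,
                 concordance = conc, summary = summary,
                 out_dir = config$out_dir))
}

#' Univariate and multivariate statistics on a normalized lipid table
#'
#' Reproduces the study's statistical readout on any normalized lipid
#' intensity table (features x samples): pooled t-tests with BH FDR at the
#' P < 0.05 / FDR < 0.10 gates on log2 values, and PLS-DA on the
#' quantile + log + pareto multivariate preprocessing, with first-component
#' VIP counts, R2Y and cross-validated Q2. Intended for externally supplied
#' supplementary tables as well as synthetic data.
#'
#' @param mat features x samples non-negative matrix.
#' @param groups two-level labels, one per column of `mat`.
#' @param p_gate,q_gate,vip_threshold gates (defaults 0.05, 0.10, 1).
#' @param n_components PLS-DA components (`"auto"` maximizes Q2).
#' @param seed seed for cross-validation fold assignment.
#' @return list: `tests`, `n_significant`, `model`, `R2Y`, `Q2`, `vip`,
#'   `n_vip_ge_threshold`.
#' @export
reproduce_lipidome_stats <- function(mat, groups, p_gate = 0.05, q_gate = 0.10,
                                     vip_threshold = 1, n_components = "auto",
                                     seed = 1L) {
  X_uni <- preprocess_lipidome(mat, quantile = FALSE, pareto = FALSE)
  X <- preprocess_lipidome(mat)
  tests <- ttest_bh(X_uni, groups, p_gate = p_gate, q_gate = q_gate)
  model <- plsda(X, groups, n_components = n_components, seed = seed)
  model$Q2 <- q2_cv(X, groups, n_components = model$n_components,
                    seed = seed)$Q2
  v <- vip(model)
  list(tests = tests, n_significant = sum(tests$significant), model = model,
       R2Y = model$R2Y, Q2 = model$Q2, vip = v,
       n_vip_ge_threshold = sum(v >= vip_threshold))
}
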