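# Independent oracles used across the suite. These deliberately re-derive
# expected values by routes separate from the package implementation.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m * p_(j) / j,
# capped at 1, computed with explicit loops.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) {
      best <- min(best, m * p[ord[j]] / j)
    }
    q_sorted[i] <- min(best, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Independent atomic-mass bookkeeping for the elemental oracle.
ORACLE_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                 O = 15.9949146196, P = 30.97376163)

oracle_formula_mass <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  total <- 0
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    total <- total + ORACLE_MASS[[el]] * (if (nzchar(n)) as.numeric(n) else 1)
  }
  total
}

# Literature molecular formulas for one reference species per packaged class
# (standard values for these well-characterized lipids).
REFERENCE_FORMULAS <- c(
  "PC(16:0/16:0)" = "C40H80NO8P",      # DPPC
  "LPC(17:0)" = "C25H52NO7P",
  "PE(16:0/18:1)" = "C39H76NO8P",      # POPE
  "TG(17:0/17:0/17:0)" = "C54H104O6",  # triheptadecanoin
  "SM(d34:1)" = "C39H79N2O6P",
  "Cer(d18:1/16:0)" = "C34H67NO3",     # palmitoyl ceramide
  "PC(O-16:0/18:1)" = "C42H84NO7P",    # plasmanyl PC
  "PE(O-16:0/18:1)" = "C39H78NO7P"     # plasmanyl PE
)

# Enumerated GSEA running sum for the classic (exponent 0) statistic,
# computed step by step without vectorized shortcuts. Signed maximum
# deviation; an exact +/- tie scores 0.
gsea_classic_enumerate <- function(ranked_names, gene_set) {
  n <- length(ranked_names)
  nh <- sum(ranked_names %in% gene_set)
  running <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (ranked_names[i] %in% gene_set) acc <- acc + 1 / nh
    else acc <- acc - 1 / (n - nh)
    running[i] <- acc
  }
  up <- max(running); down <- min(running)
  if (abs(up + down) <= 1e-10 * max(1, abs(up), abs(down))) 0
  else if (up > -down) up else down
}

# Small convenience: a normalized two-group amount matrix from the generator.
synthetic_amounts <- function(seed = 1, preset = "paper", ...) {
  cfg <- synth_config(preset = preset, ...)
  lip <- generate_lipidome(cfg, seed = seed)
  am <- is_normalize(lip$table)
  amp <- protein_normalize(am, lip$table$samples$protein_ug)
  attr(amp, "features") <- attr(am, "features")
  list(amounts = amp, groups = lip$table$samples$group, truth = lip$truth,
       table = lip$table)
}
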