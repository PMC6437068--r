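# lipidemt

Analysis of two-group lipidomics studies of epithelial–mesenchymal
transition (EMT): adherent cancer cells versus mammosphere ("Sphere")
cultures, profiled by LC-MS/MS for complex lipids and GC-MS for esterified
fatty acids (FAMEs), with transcript fold-changes of fatty-acid metabolic
genes integrated on the unsaturated fatty-acid biosynthesis pathway. The
package is written for analytical/computational lipidomics groups who
receive aligned peak tables and MS/MS peak lists and need a tested,
reproducible route from spectra to biology.

## What it computes

* **Nomenclature** — shorthand lipid names (`PC(34:1)`, `SM(d34:1)`,
  `TG(17:0/17:0/17:0)`, `PC(O-16:0/18:1)`) parsed to structured species;
  elemental compositions from backbone templates plus per-chain increments,
  monoisotopic masses, adduct m/z; SFA/MUFA/DUFA/PUFA classes with the
  ≥3-double-bond PUFA rule.
* **Identification** — rule-based MS/MS assignment: precursor candidates
  within a ppm tolerance, then class-diagnostic fragment confirmation
  (head-group ions, neutral losses, acyl carboxylates/losses) with
  deterministic tie-breaking and a per-candidate audit trail. Spectra are
  read from MGF.
* **Quantification** — class-specific internal-standard normalization
  (amount = intensity / standard intensity × spiked ng), protein
  normalization, class/species compositions closed to 100%, lipidome →
  fatty-acid decomposition, and GC-MS FAME composition via relative response
  factors.
* **Statistics** — quantile normalization, log2 with half-minimum
  pseudocount, pareto scaling; pooled-variance Student's t-tests with
  Benjamini–Hochberg FDR (gates P < 0.05 and FDR < 0.10); PCA by SVD;
  PLS-DA by NIPALS with first-component VIP scores
  (VIP² averages to 1), R²Y, and cross-validated Q² = 1 − PRESS/TSS
  (stratified leave-one-out by default); the weighted GSEA running-sum
  enrichment score.
* **Pathway** — product/substrate fatty-acid indices on the desaturation /
  elongation map (16:1/16:0 and 18:1/18:0 for SCD; 18:0/16:0, 20:0/18:0,
  22:0/20:0 for the elongation cycle; the composite ELOVL2-dependent DHA
  index 22:6n3/22:5n3), transcript log2 fold-change overlay, and a
  permutation test of sign concordance between indices and gene expression.
* **Synthetic data** — fully ground-truthed generators emulating the study
  design (two groups, n = 5, 123 species over 8 classes, spiked standards,
  hard-decoy MS/MS spectra, FAME areas, gene fold-changes) for benchmarking
  and recovery testing.

## Worked example

```r
library(lipidemt)

cfg <- synth_config(preset = "paper")          # the planted EMT design
lip <- generate_lipidome(cfg, seed = 1)
lip$table
#> <peak_table> 128 features x 10 samples (5 internal standards)
#>   classes: Cer, LPC, PC, PC O-, PE, PE O-, SM, TG
#>   groups:  Adherent=5, Sphere=5

amounts <- protein_normalize(is_normalize(lip$table),
                             lip$table$samples$protein_ug)
res <- reproduce_lipidome_stats(amounts, lip$table$samples$group, seed = 1)
res$model
#> <plsda> 2 components, 123 features, n = 10
#>   R2Y = 0.9998, Q2 = 0.9822
#>   classes: Adherent (0) vs Sphere (1)
res$n_significant          # species passing P < 0.05 and FDR < 0.10
#> [1] 73
res$n_vip_ge_threshold     # first-component VIP >= 1
#> [1] 56
```

73 of 123 species pass the univariate gates, and the PLS-DA separates the
groups essentially perfectly (R²Y ≈ 1) with high cross-validated predictive
ability (Q² 0.98) — the signature of a strongly shifted lipidome at n = 5
per group. The fatty-acid indices recover the planted enzyme-activity
pattern, and their directions agree with every transcript fold-change
(concordance 1.0):

```r
fame <- generate_fame(cfg, seed = 1)
prof <- fame_composition(fame$areas, fame$rrf, fame$is_name, fame$is_amount)
idx <- compare_indices(compute_indices(prof), fame$groups)
idx[, c("step", "t", "p", "direction")]
#>            step      t        p direction
#> 1     16:1/16:0  12.22 1.87e-06        up
#> 2     18:1/18:0   8.05 4.18e-05        up
#> 3     18:0/16:0  -6.24 2.49e-04      down
#> 4     20:0/18:0  -5.82 3.98e-04      down
#> 5     22:0/20:0  -4.50 2.00e-03      down
#> 6 22:6n3/22:5n3 -18.78 6.67e-08      down

expr <- generate_expression(cfg, seed = 1)$expr   # SCD up, ELOVL2 down, ...
conc <- concordance(idx, overlay_expression(default_pathway_map(), expr))
conc$concordance
#> [1] 1
```

The MUFA/SFA indices rise while every elongation index falls — most sharply
the DHA index 22:6n3/22:5n3, matching the strong ELOVL2 down-regulation.
`run_pipeline(pipeline_config(seed = 1))` chains identification,
quantification, statistics and pathway analysis end to end and writes the
TSV tables plus a JSON summary to an output directory; re-runs with the same
seed are byte-identical.

## Further reading

The methods vignette (`vignettes/lipidemt-methods.Rmd`) documents the
models, default parameters and their rationale, what the synthetic
generators do and do not emulate, numerical edge-case handling, and known
limitations.
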