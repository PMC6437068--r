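---
title: "Models and methods in lipidemt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in lipidemt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidemt)
```

`lipidemt` implements the computational layer of a two-group lipidomics
study design: adherent cancer cells versus mammosphere ("Sphere") cultures
undergoing epithelial–mesenchymal transition, profiled by LC-MS/MS (complex
lipids) and GC-MS (esterified fatty acids as FAMEs), with transcript
fold-changes of fatty-acid metabolic genes overlaid on the unsaturated
fatty-acid biosynthesis pathway. This vignette describes the models, the
tunable parameters, and the choices made where the design was genuinely open.

## Nomenclature and masses

Shorthand lipid names (`PC(34:1)`, `TG(17:0/17:0/17:0)`, `SM(d34:1)`,
`PC(O-16:0/18:1)`) parse to a `lipid_species` with a class, backbone, chain
list and species-sum or molecular-acyl resolution. Elemental compositions are
assembled from packaged backbone templates
(`inst/extdata/lipid_class_templates.tsv`) plus per-chain increments: an
ester chain of c carbons and d double bonds contributes C~c~H~2c−2−2d~O (a
fatty acid minus water), an ether chain C~c~H~2c−2d~, and a sphingolipid with
total composition C:D and a di-hydroxy base contributes
C~C~H~2C+1−2D~NO~3~ over its core. Templates are data, not code, so classes
can be added without touching the parser.

Two conventions to note:

* The sphingoid `d` prefix (di-hydroxy base) is canonical: `Cer(18:1/17:0)`
  — the spiked ceramide standard as protocols often write it — parses and
  re-serializes as `Cer(d18:1/17:0)`.
* Saturation buckets follow the study's definition: 0 double bonds SFA, 1
  MUFA, and **3 or more** PUFA. Di-unsaturated chains get their own DUFA
  bucket rather than being lumped into PUFA, so the three-way SFA/MUFA/PUFA
  summary matches figures drawn with the ≥3 C=C rule. Thresholds are
  arguments of `saturation_class()`.

Adduct m/z values use CODATA monoisotopic masses with explicit electron
bookkeeping. Which adduct is quantified per class is not fully determined by
the acquisition description (ammonium-acetate/formic-acid mobile phases,
both ESI polarities), so the packaged defaults — `[M+H]+` for LPC, PC,
PC O- and SM, `[M+NH4]+` for TG, `[M−H]−` for PE, PE O- and Cer — are
recorded in the class-template TSV and user-overridable; formate adducts
remain available in `default_adducts()`.

## Rule-based MS/MS identification

`identify_dataset()` is the in-silico counterpart of a
library-search-then-manual-confirmation workflow: precursor candidates
within a ppm tolerance (`candidate_species()`), then class-diagnostic
fragment confirmation (`confirm_hit()`). Rules live in
`inst/extdata/fragmentation_rules.tsv` and combine fixed fragments (e.g. the
phosphocholine head group at m/z 184.0733 for the PC family), neutral losses,
and acyl-derived evidence (fatty-acid carboxylates for PE in negative mode;
ammonia-plus-acyl losses for ammoniated TG; fatty-acid losses for PC). Acyl
evidence is what disambiguates exactly isobaric molecular species — the
packaged panel contains 20 such pairs (e.g. `PC(16:0/18:2)` vs
`PC(16:1/18:1)`), and a head-group-only rule cannot separate them.

A candidate is *confirmed* when at least `min_required` required fragments
match within the fragment tolerance and no forbidden fragment is present;
the score (fraction of required evidence matched) is reported for audit. Ties
among confirmed isobars are resolved deterministically: highest score, then
smallest absolute precursor error, then lexicographic name; losing candidates
are downgraded to *tentative*. Defaults are 10 ppm precursor and 0.02 Da
fragment tolerance, matching a QTOF-class instrument; both are arguments.
Spectra are read and written as MGF (a small reader ships with the package).

## Quantification

`is_normalize()` converts intensities to ng-equivalents per the
class-standard rule `amount = intensity / intensity(standard) × spiked ng`,
with the spiked amounts of the five odd-chain standards (400 ng of
LPC(17:0), PC(17:0/17:0), PE(17:0/17:0) and Cer(d18:1/17:0); 2,000 ng of
TG(17:0/17:0/17:0)) packaged in `default_standard_map()`. Two mappings are
assumptions, flagged and overridable: ether classes share their diacyl class
standard, and SM — with no dedicated standard — maps to the nearest
sphingolipid standard, Cer(d18:1/17:0). `protein_normalize()` divides by
per-sample protein. Compositions (`class_composition()`,
`species_composition()`, `fame_composition()`,
`lipidome_to_fa_profile()`) are closed to 100% per sample; the composition
denominator (total lipid vs within-class) is a configuration choice
(`composition.scope`) because "composition" alone does not define it. Zero
intensities propagate as zero amounts — no imputation; the statistics layer
handles zeros with a log pseudocount instead.

FAME quantification uses relative response factors:
`amount_i = area_i / (rrf_i × area_IS) × spiked μg` against the C23:0 FAME
(5 μg) by default; a missing RRF defaults to 1 with a classed warning.

## Statistics

**Preprocessing.** `preprocess_lipidome()` applies quantile normalization
across samples (mean-quantile rule, ties averaged — numerically identical to
`limma::normalizeQuantiles`), `log2(x + pseudocount)` with the pseudocount
defaulting to half the smallest nonzero value, and pareto scaling
((x − mean)/√sd per feature; constant features are centered only). This
stack feeds PCA and PLS-DA. The univariate gates run on log2 amounts
*without* the quantile/pareto steps: that is where the acquisition
description places them, and it keeps the Benjamini-Hochberg procedure
within its positive-dependence guarantee (quantile normalization couples
features across samples).

**Univariate tests.** `ttest_bh()` is the pooled-variance Student's
two-tailed t-test (Welch via `var_equal = FALSE`), with exact BH step-up
q-values from `stats::p.adjust` and significance gates P < 0.05 *and*
FDR < 0.10. Zero pooled variance yields the p = 1 convention with a
`degenerate` flag.

**PCA.** SVD of the column-centered design matrix with a deterministic sign
convention (the largest-magnitude loading of each component is positive).

**PLS-DA.** `plsda()` fits NIPALS PLS1 on the centered 0/1 dummy response:
per component, `w = X'y/‖X'y‖`, `t = Xw`, `p = X't/t't`, `q = y't/t't`,
then deflation of X and y. `R2Y = 1 − RSS/TSS`. VIP scores use
`VIP_j = sqrt(p · Σ_a SS_a w_ja² / Σ_a SS_a)` with `SS_a = q_a² t_a't_a`;
the mean of squared VIPs is 1 by construction, and VIPs are reported from
the first component, the usual convention. `q2_cv()` computes
`Q² = 1 − PRESS/TSS` from test-fold predictions of models fitted on training
folds only; the default scheme is stratified leave-one-out, the natural
choice at n = 10 (k-fold is available; the original report does not state
which scheme produced its Q², so both are exposed). The "optimal" number of
components (`n_components = "auto"`) maximizes leave-one-out Q² over 1–3
components, since no explicit criterion is given for optimality.

**GSEA.** `gsea_es()` computes the weighted running-sum enrichment score:
hits weighted by |ranking weight|^exponent (default 1; 0 gives the classic
Kolmogorov-Smirnov form), misses by 1/(N − N~hit~), ES = the signed maximum
deviation. On the lattice of values the classic statistic takes, the
positive and negative extremes can tie exactly; a tie scores 0, which keeps
the statistic antisymmetric under ranking reversal (and matches
`fgsea::calcGseaStat`). Only the statistic is computed — set-permutation
p-values are out of scope. The ranking metric is the caller's choice
(fold-change, signal-to-noise, ...), as it is not determined by the study
description.

## Pathway indices

`default_pathway_map()` ships the unsaturated fatty-acid biosynthesis steps
as TSV: the two SCD desaturation indices (16:1/16:0, 18:1/18:0), the
saturated elongation chain (18:0/16:0, 20:0/18:0, 22:0/20:0; annotated with
the elongation-cycle genes PTPLB and PECR, plus ELOVL3) and the composite
DHA step 22:6n3/22:5n3 attributed to ELOVL2. The DHA step is deliberately a
single composite index — the intermediate C24 species of the
elongation/desaturation/β-oxidation route are not modeled, because the
reported quantity is the composite ratio. `compute_indices()` forms
product/substrate ratios per sample (closure-invariant; zero substrate gives
a missing value, never ±Inf), `compare_indices()` tests them (pooled t,
direction gate p < 0.05 by default), `overlay_expression()` annotates steps
with transcript log2 fold-changes (uppercase symbol matching, no alias
database), and `concordance()` reports the fraction of steps whose index
direction sign matches the mean gene log2FC sign, with a permutation p-value
over gene-to-step reassignments (a single evaluable step yields p = 1 — no
exchangeable permutations).

## What the synthetic generators emulate — and what they do not

`synth_config()` encodes the study conditions: two groups of n = 5, the
packaged 123-species panel over 8 classes, class-specific internal standards
at their spiked amounts, and log-normal intensities. The `"paper"` preset
plants the EMT signature multiplicatively on Sphere means: Cer ×2.2,
PC O- and PE O- ×0.45, C16:1-containing species ×2.2, species containing a
≥3-double-bond chain ×0.40, FAME multipliers moving all six indices in the
reported directions, and transcript fold-changes with SCD/ACOX3/FADS1
positive and PTPLB/PECR/ELOVL2/ELOVL3 negative. The `"null"` preset removes
every effect.

The magnitudes are declared simulation assumptions, fixed by design: the
per-sample intensity noise (0.10 log10 units) and effect multipliers were
chosen by power analysis so that (i) roughly 60% of species pass the
P < 0.05/FDR < 0.10 gates at n = 5 — the proportion the study design calls
for, as a qualitative not exact target — and (ii) every planted direction
(class shifts, acyl-group shifts, the six index directions) is recovered
with ≥95% probability per seed. For the GC side, the weakest planted index
shift is |log10 0.68| ≈ 0.167 against 0.03 log10 units of area noise
(≈7% CV, a realistic GC-MS precision), giving >99% directional power at
n = 5. Precursor mass errors are uniform within ±`mass_error_ppm`
(default 5), emulating a calibrated instrument with bounded error; decoy
spectra are *hard* negatives — a real precursor paired with the diagnostic
fragments of a different class with disjoint evidence — rather than random
peaks, to stress the rule engine rather than the noise model.

Not emulated: chromatographic drift and retention-time structure, isotope
envelopes and in-source fragments, batch effects, missing-at-random dropout,
and biological covariance between lipid species beyond the shared
internal-standard scaling. Passing recovery tests on this generator
therefore demonstrates the correctness and power of the *pipeline*, not that
real data of this size will behave as cleanly.

## Numerical choices and degenerate inputs

* Quantile normalization resolves ties by averaging the mean-quantile values
  at the tied (fractional) ranks; constant samples map onto the mean
  quantile vector.
* The log pseudocount is half the minimum nonzero value (override by
  argument); all-zero matrices are an error, all-zero samples a
  `DegenerateSample` error at closure.
* PLS components with no X–y covariance (‖X'y‖ < 1e-12) raise an error
  rather than fitting noise; rank-deficient PCA truncates with a warning.
* Identification tie-breaks are deterministic (score, |ppm|, name); repeated
  runs are identical.
* Every generator takes a mandatory seed and restores the caller's RNG
  state.

## Problem sizes used in the test suite

The suite exercises the full study-sized design (123 species × 10 samples):
500 simulated null datasets for the type-I/FDR checks, 200 paper-preset
datasets for direction recovery, 1,000 random p-vectors against a
brute-force BH oracle, 100 random PLS fits for the VIP identity, and 100
label permutations for the Q² null — sizes at which the whole suite
completes in a few minutes on one CPU.

## Known limitations

* The species-sum vs molecular-acyl distinction limits fatty-acid
  decomposition: sum-level species (all packaged SMs) are excluded from
  `lipidome_to_fa_profile()` with a warning.
* The rule tables cover the eight study classes only; other classes need
  template and rule rows (both are plain TSV).
* BH FDR control is exact under independence/positive dependence; the
  shared internal-standard scaling induces mild within-class correlation,
  which stays within that regime, but heavy cross-class correlation in real
  data is not modeled.
* The GSEA module computes the enrichment statistic only; significance
  assessment requires an external permutation framework.
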