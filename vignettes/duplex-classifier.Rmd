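---
title: "Classifying miRNA binding sites from duplex alignment features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying miRNA binding sites from duplex alignment features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirforest)
```

## The problem and the model

Animal miRNAs guide the RISC complex to partially complementary sites,
mostly in 3′UTRs. Recognition is dominated by Watson–Crick pairing of
the miRNA *seed* (positions 2–8 from the 5′ end), with 3′ out-seed
pairing able to compensate imperfections; G:U wobble pairs are
thermodynamically stabilising but functionally detrimental. Alignment
scanners accept many candidate sites; the question this package
answers is *which accepted sites look like real targets*.

The model is a random forest over 34 per-site descriptors. Nothing in
the forest is specific to RNA; all the biology enters through the
aligner that defines a site and the features that describe it. The
package therefore separates three concerns:

* `align_duplex()` — a Smith–Waterman local alignment (Gotoh affine
  gaps) of the miRNA against the reversed target (antiparallel
  geometry), scored +5 (G:C), +5 (A:U), +2 (G:U), −3 (otherwise),
  filtered by four empirical rules, a score threshold and an energy
  threshold;
* `extract_features()` — the 34 features (2 alignment, 1
  thermodynamic, 5 structural counts, 20 per-column categories, 6
  seed-region);
* `train_forest()` / `repeated_cv()` / `permutation_test_auc()` — the
  learning and evaluation protocol.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `match_gc`, `match_au`, `wobble_gu`, `mismatch` | +5, +5, +2, −3 | per-column pairing scores |
| `gap_open`, `gap_extend` | −8, −2 | affine gap penalties; a run of k gap columns costs `gap_open + (k−1)·gap_extend` |
| `score_threshold` | 35 | minimum site score S |
| `energy_threshold` | −7 | maximum duplex ΔG, kcal/mol |
| `n_trees` | 500 | ensemble size; OOB error stabilises well below this |
| `mtry` | ⌊√p⌋ | candidate features per split; tune with `tune_mtry()` |
| `class_weights` | equal | misclassification costs; preset 0.3/0.7 via `weighted_preset()` |
| `decision_threshold` | 0.5 | strict: a site is a target iff p > threshold |

Gap penalties are not part of the published scoring scheme; −8/−2 was
chosen so that gaps are rare (single-gap alignments do occur in real
duplex displays, multi-gap ones essentially never) and is
configurable.

The score/energy thresholds deserve a note. The protocol this package
implements deliberately runs its aligner *permissively*: every site
with the minimal requirements of a binding site is kept, and the
classifier does the refining. The defaults mirror the canonical
aligner's shipped thresholds (140 on its ×4-scaled matrix = 35 here;
energy −7 kcal/mol). Raising them turns the aligner itself into a
selective filter, which changes the population of sites the classifier
sees far more than any classifier parameter does.

## The empirical site rules

Counting alignment columns from the miRNA 5′ end: (i) no mismatches at
columns 2–4; (ii) fewer than five mismatches in 3–12; (iii) at least
one mismatch between column 9 and L−5; (iv) fewer than two mismatches
in the last five columns. Gap columns count as mismatches for the
rules. Two decisions were genuinely open:

* **Wobbles count as pairing.** G:U is positively scored and drawn as
  a pair in duplex displays; the source protocol does not say whether
  its rules treat it as a mismatch. We pair it; the choice is isolated
  in `check_empirical_rules()`.
* **Columns, not bases.** Rule positions and the 20 position features
  index alignment columns (gap columns consume a position), matching
  how published duplex figures number the displayed alignment.

Rule (iii) is why a perfectly complementary site is *rejected*:
complete complementarity signals plant-style cleavage targeting, not
the animal-style seed+compensatory architecture this classifier is
built for.

## The energy model

`duplex_mfe()` scores a *given* alignment, summing Turner-style
nearest-neighbour stacking energies over adjacent paired columns plus
a duplex initiation penalty (+0.5 kcal/mol), with an optional
per-interior-loop penalty (default 0 — unpaired columns already lose
their stacking). Watson–Crick/Watson–Crick steps carry the standard
37 °C values; steps involving G:U use flat approximations (−1.3 with a
WC neighbour, −0.5 between wobbles), shipped as a versioned table in
`extdata/nn_stacks_v1.tsv`. The initiation penalty is set small so
that any alignment with at least one stacked WC step has ΔG ≤ 0; the
feature is used comparatively by the classifier, so relative order
matters more than absolute calibration. `seed_mfe()` applies the same
model to columns 2–8. An `energy_model(backend = "rnaduplex")` adapter
delegates to an RNAduplex-compatible engine instead, refolding the
gap-stripped subsequences; the builtin model keeps the package
self-contained and deterministic.

## Classifier protocol

Training delegates tree growing to the `randomForest` package:
bootstrap samples (~2/3 of rows), per-node random feature subsets,
majority vote, OOB estimates, mean-decrease-Gini importance. Position
features are unordered factors over six levels (the five pairing
categories plus `ABSENT`, used for columns beyond a short alignment —
an explicit level the trees can split on, rather than imputation).

Class weights are misclassification costs applied in vote
aggregation: a site is called a target when its vote fraction exceeds
`w_NON/(w_NON + w_TARGET)` (0.5 for equal weights, preserving the
strict >0.5 rule; 0.7 under the 0.3/0.7 preset). The impurity-prior
route (`classwt`) was rejected after controlled synthetic experiments
showed it moving specificity in the wrong direction — a known quirk of
the underlying implementation.

`tune_mtry()` profiles resampled AUC over `{2, ⌊√p⌋, ⌊p/3⌋, ⌊p/2⌋}`
(repeated stratified CV, per-fold AUCs) and applies the
one-standard-error rule: the smallest `mtry` within one SE of the best
mean. `forward_feature_selection()` trains one forest per prefix of a
fixed Gini ranking and recommends the prefix maximising OOB MCC
(smallest on ties) — MCC being the scalar that balances sensitivity
and specificity. Forward selection reuses the globally tuned `mtry`
rather than retuning per prefix; profiles are flat enough that
retuning only adds variance.

`repeated_cv()` uses stratified folds (both classes in every training
split, sizes within one); per repeat it sums the fold confusion
matrices and pools out-of-fold probabilities for the AUC, then reports
means and standard deviations over repeats plus the repeat-averaged
(fractional) confusion matrix. Whether the historical protocol
stratified its folds is unknown; stratification removes a variance
term and never biases a balanced design.

### Reporting convention

Printed-table reproduction uses `truncate_digits()`: values are
truncated toward zero at the printed precision, not rounded (718.6/824
= 87.208…% prints as 87.20; 48.4/342 = 14.15…% as 14.1). Truncation
reproduces every published cell from its confusion matrix; rounding
mismatches several last digits. Internal computation always keeps full
precision.

Permutation p-values are the plain fraction of permutations with AUC ≥
observed (`corrected = TRUE` gives the (r+1)/(n+1) variant). With 2000
permutations a perfect separator on 40 balanced observations has
p ≤ 0.001 essentially always (the probability that a random relabelling
reproduces AUC = 1 is 1/C(40,20)).

## The synthetic generator: what it emulates, and what not

`generate_pairs()` plants one binding site per target: the reverse
complement of the miRNA, degraded column-wise i.i.d. — seed columns
pair with probability 0.95 (positives) / 0.4 (negatives), out-seed
columns 0.6 / 0.3, a planted pair becomes a wobble with probability
0.08 where chemically possible, and one central column is forced
non-pairing so rule (iii) is satisfiable. Flanks are i.i.d. with 50%
GC. Defaults: 22-nt miRNAs, 500-nt targets, 200 + 200 pairs. No indels
are planted (gaps are rare in real duplexes; gap handling is exercised
by dedicated fixtures). These rates emulate the seed-dominant,
3′-compensatory architecture of animal sites, and a class-identical
configuration gives the null model used for calibration checks.

What the generator does **not** emulate is just as important for
reading the test results:

* **Background competition.** A degraded planted site (expected score
  ≈ 50 at the positive rates) competes with the best random window of
  a 500-nt target, whose extreme-value score under this matrix is of
  the same order. A substantial minority of positive pairs therefore
  yield a best-accepted alignment that is *not* the planted site, and
  their feature rows carry no planted signal.
* **Selection effects.** Negatives that survive the four rules have,
  by construction, well-paired seeds (rule i forces columns 2–4), so
  surviving pseudo-sites resemble real sites much more than raw
  random sequence does.

Both effects compress class separation relative to curated biological
training sets, in which positives are genuine validated sites rather
than stochastically degraded ones. Consequently the cross-validated
AUC on the default synthetic study (computed by
`scripts/acceptance.R`) sits well below what the protocol reaches on
its curated data, with global features (alignment score, total ΔG)
absorbing much of the seed signal in the Gini ranking — the seed-region
ΔG still ranks at or near the top, as it does on real data. Passing
tests on this generator demonstrate that the machinery is correct and
the planted signal is recovered above chance; they do not certify
real-data accuracy, which depends on the training corpus.

## Numerical choices and degenerate inputs

* Alignment ties: the DP prefers pairing over gap states and earlier
  starts only through deterministic argmax order; identical inputs
  give identical alignments.
* Multiple sites per target are taken greedily by descending score
  with previously claimed target positions masked; up to `max_sites`
  (8) per pair.
* `metrics_from_confusion()` marks metrics with zero denominators as
  `NA` rather than fabricating numbers; all-zero matrices are errors.
* `roc_auc()` collapses tied scores into single ROC vertices;
  trapezoidal integration then counts ties ½, so the sweep AUC equals
  the pairwise-ranking definition exactly.
* `scale_features()` maps constant columns to zero with a warning and
  stores its parameters for reuse on held-out data;
  `feature_correlation()` reports zero-variance rows/columns as `NA`.
* Feature tables are TSV with a fixed header (34 snake-case names in
  schema order, label last) so files diff cleanly; position factors
  round-trip with their level sets.
* Seeds: every stochastic entry point takes an explicit integer seed
  and uses it through `withr::with_seed`, so fold assignment, training
  and generation are reproducible and non-intrusive on the session
  RNG. Derived seeds stay far below 2³¹.

## Problem sizes

The test suite and the acceptance workflow run the full study at 200 +
200 generated pairs (≈ 370 surviving rows), 10-fold × 5-repeat
cross-validation with 500-tree forests, 200 alignment-oracle cases and
100 AUC-oracle sets, and 2000-permutation significance tests — sizes
chosen so the whole suite completes in a few minutes on a single core
while keeping every estimate comfortably away from its decision
boundaries.

## Known limitations

* No target-site accessibility or mRNA secondary structure; the
  duplex is scored in isolation.
* No conservation, site multiplicity or UTR-context features.
* The builtin energy model approximates wobble stacking with flat
  constants; absolute ΔG values differ from a full Turner model by a
  few kcal/mol on wobble-rich duplexes (the RNAduplex backend is
  available where absolute values matter).
* The synthetic generator's separability ceiling discussed above: its
  planted positives are weaker than curated positives, by design of
  its degradation model.
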