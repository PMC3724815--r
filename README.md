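# mirforest

Random-forest classification of microRNA binding sites from duplex
alignment features.

Animal miRNAs repress genes by partial, antiparallel base-pairing with
sites in target mRNAs, anchored by near-strict pairing of the miRNA
*seed* (positions 2–8 from the 5′ end). Sequence scanners such as
miRanda find many candidate sites because miRNAs are short and pairing
is imperfect; most hits are not functional. `mirforest` refines such
candidate sites: it aligns miRNA/target pairs with a miRanda-style local
aligner, turns each accepted duplex into a 34-feature description, and
trains a random forest that separates true target sites from
pseudo-target sites.

The pipeline is:

1. **Alignment** — Smith–Waterman local alignment (affine gaps) of the
   miRNA (5′→3′) against the reversed target, under the pairing matrix
   *+5* G:C, *+5* A:U, *+2* G:U wobble, *−3* otherwise. Sites must pass
   four empirical rules (no seed-proximal mismatches at columns 2–4;
   fewer than five mismatches in 3–12; at least one mismatch in the
   central region 9..L−5; fewer than two mismatches in the last five
   columns), a score threshold S, and a duplex free-energy threshold
   ΔG (kcal/mol, nearest-neighbour model or an RNAduplex backend).
2. **Features** — score and length; total ΔG; counts of G:C, A:U, G:U,
   gaps and mismatches; the pairing category of each of alignment
   columns 1–20; and the seed-region ΔG and counts (columns 2–8). That
   is 34 features in five categories (2/1/5/20/6).
3. **Classification** — a 500-tree random forest (bagged CART trees,
   `mtry` random candidate features per split, majority vote). A site
   is called a target when its vote fraction p exceeds 0.5 (strictly).
   Out-of-bag (OOB) data provide error estimates and mean-decrease-Gini
   feature importance.
4. **Evaluation** — ACC/SEN/SPE/MCC from (possibly fold-averaged)
   confusion matrices, ROC/AUC, stratified repeated cross-validation
   (10-fold × 5), `mtry` tuning with the one-standard-error rule,
   Gini-ranked restricted forward feature selection, label-permutation
   AUC significance tests, and partial dependence profiles.

A synthetic-data module generates labelled miRNA/target pairs with
controllable seed and 3′ pairing so the entire pipeline is testable
without downloads.

## Worked example

```r
library(mirforest)

mirna  <- "UGAGGUAGUAGGUUGUAUAGUU"                 # 22-nt mature miRNA
target <- paste0("CCAUACAACC", "AACUAUACAACAUACUACCUCA", "AGGAGGACAU")

hits <- align_duplex(mirna, target,
                     mirna_id = "let-7-like", target_id = "utr-fragment")
hits[[1]]
#> duplex alignment let-7-like ~ utr-fragment (score 102, 22 columns, -35.05 kcal/mol)
#>   5' UGAGGUAGUAGGUUGUAUAGUU 3' miRNA
#>      |||||||||| |||||||||||
#>   3' ACUCCAUCAUACAACAUAUCAA 5' target [11-32]
```

The site pairs perfectly except one central mismatch (required of real
sites — perfect complementarity is characteristic of plant, not animal,
targeting and is rejected by the central-mismatch rule). Its features:

```r
extract_features(hits[[1]])[, c("alignment_score", "alignment_length",
                                "mfe_total", "count_gc_total", "mfe_seed")]
#>   alignment_score alignment_length mfe_total count_gc_total mfe_seed
#> 1             102               22    -35.05              7   -12.84
```

`alignment_score` is the pairing-matrix sum (21 matches, one −3
mismatch), `mfe_total` the duplex free energy in kcal/mol, `mfe_seed`
the same for columns 2–8 alone: a stable, seed-anchored duplex.

Classifier metrics come from confusion matrices; printed-table
reporting truncates (not rounds) to the printed precision:

```r
m <- metrics_from_confusion(confusion_matrix(tp = 425, tn = 293.6,
                                             fp = 48.4, fn = 57))
truncate_digits(m[c("acc", "sen", "spe", "mcc")], c(2, 2, 2, 3))
#> ACC 87.2  SEN 88.17  SPE 85.84  MCC 0.737
```

End to end on synthetic data:

```r
tab <- generate_feature_table(synthetic_config(n_pos = 200, n_neg = 200,
                                               rng_seed = 1))
forest <- train_forest(tab, rf_config(rng_seed = 1))
cv <- repeated_cv(tab, rf_config(rng_seed = 1))   # 10-fold x 5 repeats
tidy(cv)         # metric means/sds over repeats
tidy(forest)     # Gini importance ranking
autoplot(forest) # importance plot
```

A command-line front end wrapping the same functions lives at
`inst/cli/mirforest.R` (subcommands `simulate`, `align`, `extract`,
`train`, `tune`, `select-features`, `evaluate`, `permtest`, `predict`,
`refine`, `run`).

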