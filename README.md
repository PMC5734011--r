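# cassex

Classification of cassette (skipped) exons versus constitutive exons
from genomic sequence features.

Cassette-exon splicing — an internal exon that can be included in or
skipped from the mature transcript — is the most common form of
alternative splicing in mammalian genomes. Exons that get skipped tend
to be shorter, slightly lower in GC content, richer in termination
codons, and, above all, flanked by weaker splice sites. `cassex`
implements a complete pipeline that quantifies these properties and
classifies exons:

* **91 sequence features per exon**: length; mono-, di-, and
  trinucleotide frequencies; termination-codon (TAA/TAG/TGA)
  frequencies; GC content; and 5′/3′ splice-site strengths
  (1 + 4 + 16 + 64 + 3 + 1 + 2 = 91).
* **Maximum-entropy splice-site model**: signal (P⁺) and decoy (P⁻)
  distributions over boundary windows — 3 exonic + 6 intronic positions
  for the donor, 20 intronic + 3 exonic for the acceptor — fit by
  iterative proportional scaling under per-position (order 1) or all
  pairwise (order 2) marginal constraints; a window *x* scores
  `L(x) = log2( P+(x) / P-(x) )` in bits.
* **Conditional-inference forest**: trees split only while a
  permutation test rejects independence between candidate features and
  the label (Bonferroni-adjusted over `mtry` candidates), trained on
  0.632-subsamples without replacement; predictions average leaf class
  proportions. Out-of-bag permutation variable importance, with an
  optional conditional scheme that permutes within strata of correlated
  covariates. KNN and Gini random-forest baselines included.
* **Evaluation**: stratified k-fold cross-validation without leakage
  (scaling and splice models re-fit per fold), sensitivity/specificity/
  total accuracy (`Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
  `TA = (TP+TN)/total`; positives = cassette exons), rank-statistic
  ROC/AUC, grid search, and per-feature Welch t-tests between classes.
* **Synthetic data generator**: plants the class contrasts (length, GC,
  stop-codon frequency, splice-site degradation) into a synthetic
  genome with GT/AG-anchored boundary motifs, so the whole pipeline is
  testable without any downloads.

## Worked example

```r
library(cassex)

# a synthetic genome with 150 cassette + 150 constitutive exons
bundle <- generate_dataset(generator_config(n_cassette = 150,
                                            n_constitutive = 150,
                                            seed = 42))
#> <synthetic_bundle> 300 exons (150 cassette / 150 constitutive) on 1 contig(s), seed 42

# 5-fold pipeline cross-validation: per fold, splice models are trained
# on the training exons, features extracted, scaled, and classified
cv <- cross_validate_exons(bundle$genome, bundle$exons,
                           cforest_fitter(ntree = 100, mtry = 10, seed = 42),
                           k = 5, seed = 42)
round(cv$mean, 3)
#>    Sn    Sp    TA
#> 0.987 0.747 0.867
cv$auc
#> [1] 0.948

# which features separate the classes? (Welch t-tests, sorted by p)
cmp <- compare_feature_groups(cv$features)
head(cmp[, c("feature", "mean_cassette", "mean_constitutive", "p")], 5)
#>        feature mean_cassette mean_constitutive        p
#> 1 ss3_strength        0.5658          9.90e+00 1.35e-78
#> 2 ss5_strength        0.2749          4.26e+00 8.17e-40
#> 3       length      149.4000          1.77e+02 9.31e-04
#> 4          tga        0.0038          2.23e-03 2.05e-03
#> 5     term_tga        0.0038          2.23e-03 2.05e-03

# out-of-bag permutation importance of a forest fit on all exons
sc <- scale_features(cv$features)
model <- fit_forest(sc$matrix, ntree = 100, mtry = 10, seed = 42)
imp <- permutation_importance(model,
                              as.matrix(sc$matrix[, feature_names()]),
                              sc$matrix$label, seed = 42)
head(imp[order(imp$rank), ], 5)
#>         feature importance rank
#> 91 ss3_strength    0.05400    1
#> 90 ss5_strength    0.03255    2
#> 78          tga    0.00209    3
#> 1        length    0.00091    4
#> 88     term_tga    0.00073    5
```

Reading the output: both splice-site strengths are far weaker for the
cassette class (0.57 vs 9.90 bits at the acceptor) and cassette exons
are shorter on average (149 vs 177 nt) — and the forest's importance
ranking identifies exactly those features as the discriminating ones.
At this small sample size sensitivity exceeds specificity; accuracy
and balance improve with more exons (the validation suite uses
500 + 500, where total accuracy exceeds 0.95).

A command-line interface covers the same pipeline (installed to the
package's `exec/` directory):

```sh
cassex simulate --out-dir sim --n-cassette 500 --n-constitutive 500 --seed 7
cassex extract-features --genome sim/genome.fa --exons sim/exons.tsv --out features.tsv --seed 7
cassex cv --features features.tsv --folds 10 --ntree 200 --mtry 10 --out metrics.tsv --seed 7
cassex importance --features features.tsv --out importance.tsv --seed 7
cassex compare-features --features features.tsv --out comparison.tsv
```

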