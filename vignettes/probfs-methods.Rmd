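---
title: "Probability-based features for suicide-risk text classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-based features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probfs)
```

## The problem and the model

Short social-media posts are classified into two classes (here labelled
`suicide` / `non-suicide`). The standard route — term-frequency features
into a linear classifier — works well for linear models but leaves
distance- and tree-based learners struggling in a sparse space with
thousands of columns. The package's central object, the probability-based
feature set (ProBFS), replaces that space with four numbers per document:
the class probabilities assigned by two base learners, a linear SVM and a
logistic regression, both trained on TF-IDF features.

The chain is:

1. **Cleaning** (`preprocess_corpus()`): punctuation runs replaced by one
   space, digits deleted, lowercasing, stop-word removal against a pinned
   Snowball English list shipped in `inst/extdata/`, Porter stemming;
   then whitespace tokenization. Every step is a deterministic character
   or token map, so the pipeline is idempotent over the non-stemming steps
   and reproducible byte-for-byte.
2. **Featurization** (`tfidf()`): raw counts times `log(N / D_t)`, rows
   L2-normalized.
3. **ProBFS generation** (`generate_probfs()`): fit SVM and LR, emit
   `[P1, P2, P3, P4]` with `(P1, P2)` the SVM pair and `(P3, P4)` the LR
   pair, each pair summing to 1, columns within a pair following the
   sorted order of the label values.
4. **Downstream modelling and evaluation**: any of the six wrapped
   classifiers on any feature matrix, stratified 80:20 splits, metrics
   derived from the confusion matrix, k-fold cross-validation, timing.

### Assumptions

* Labels are binary; ProBFS has width `2 × 2 = 4` by definition and the
  package refuses more than two classes.
* Because `P2 = 1 − P1` and `P4 = 1 − P3`, the four columns span at most
  two independent directions (plus intercept). All four are kept anyway:
  the representation is defined that way, and affine-invariant learners
  are unaffected by the redundancy.
* The base learners are fitted on the *whole* input matrix in the default
  `full_fit` mode. This is the faithful procedure, and it is optimistic:
  if the ProBFS output later feeds a train/test split, the test labels
  have already influenced the features. The package treats this as a
  property to be demonstrated, not silently corrected — see "Leakage"
  below.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| SVM kernel / cost | `linear`, `C = 2` | tuned values for this task family; linear kernels suit L2-normalized sparse term vectors |
| LR solver / cost | liblinear-style L2, `C = 2` | mapped to `glmnet(alpha = 0, lambda = 1/(n·C))` |
| RF / ETC | 200 trees, depth ≤ 200 | tuned from 10–500 trees, depth 10–500 |
| GBM | 200 trees, depth ≤ 200, learning rate 0.8 | tuned from the same ranges, rate 0.1–0.9 |
| KNN | `k = 5`, uniform votes | tuned from k ∈ 1–10, uniform/distance |
| idf variant | raw `log(N/D_t)`, natural log | the worked example cannot discriminate variants (all idfs equal); smoothed `log((1+N)/(1+D_t)) + 1` is a config option |
| TF-IDF norm | L2 per row | the worked-example weights (`1/√8`, `1/√4`) are only obtainable with unit-norm rows; `norm = "none"` exposes the raw scores |
| hashing buckets | 1024, signed | vocabulary-free baseline; seedable FNV-1a hash, sign from the top hash bit |
| feature-selection k | 5,000 | the value used in the headline comparisons; alternative settings are plain arguments |

Source texts occasionally quote alternative values for some of these
(300 trees, `k = 3`, learning rate 0.2); each is reachable through
`model_config()` overrides, and the defaults above are the tuned-table
values.

## Numerical choices

* **SVM probabilities.** A linear SVM emits decision values, not
  probabilities. The wrapper fits a Platt-style sigmoid — a binomial GLM
  of the training labels on the decision values — and applies it wherever
  probabilities are requested. This keeps the whole ProBFS computation
  deterministic given a seed (verified bit-for-bit in the tests), unlike
  calibration schemes that shuffle internal folds outside R's RNG.
* **Class order.** Everywhere, columns follow the sorted order of the
  observed label values (`non-suicide` before `suicide`), so downstream
  models are reproducible across runs and serializations.
* **Ties.** Class prediction is the argmax of the probability pair, first
  class winning exact ties; chi-squared selection breaks score ties in
  favour of the lower column index (making top-k sets nested in k); KNN
  breaks distance ties by training-row order.
* **PCA signs.** Each principal axis is flipped so its largest-magnitude
  loading is positive, fixing the projection deterministically.
* **Degenerate inputs.** Empty documents featurize to zero rows (left at
  norm 0); out-of-vocabulary tokens are ignored; a document containing
  only unseen tokens scores as the base learners' response to the zero
  vector; a single-class training set yields a constant predictor; an
  empty corpus into `probfs_transform()` returns a 0 × 4 table.
* **idf of unseen vocabulary terms.** Under the raw variant a term absent
  from the fitting corpus has no defined idf; it is assigned 0 with a
  warning (the smoothed variant is defined everywhere).

## The synthetic generator

`generate_corpus()` draws balanced (configurable) binary-labelled
documents whose tokens come from a class-specific vocabulary with
probability `separability` and from a shared vocabulary otherwise.
Document lengths are `1 + NegBinomial(mean − 1, dispersion)` with mean 58
tokens — the scale of the motivating social-media corpus (exactly balanced
classes, average 58 words per post). Defaults: 800 shared and 150
class-specific terms, separability 0.6, dispersion 5 — sizes chosen so
that a desk-scale corpus of ~2,000 documents has a realistic few-percent
density TF-IDF matrix while the whole suite runs in about a minute.

What it emulates: class balance, document-length skew, a mixture of
class-informative and neutral tokens, tunable difficulty from
`separability = 0` (labels independent of text; downstream accuracy is
chance) to `1` (disjoint supports; linearly separable). What it does
*not* emulate: natural-language syntax, topic structure, author effects,
misspellings, or vocabulary burstiness. Passing tests therefore
demonstrate the pipeline's mechanics and the relative behaviour of
feature sets — not absolute accuracies on real corpora, which depend on
the real data's much messier geometry.

## Leakage: full-fit versus out-of-fold

The faithful `full_fit` mode trains the base learners on all documents
and predicts the same documents. In a high-dimensional regime (more
features than documents) the linear base learners can interpolate even
*permuted* labels, so the four probabilities effectively memorize the
target. The test suite demonstrates both halves: with shuffled labels,
downstream training accuracy on full-fit ProBFS exceeds 0.9, while
out-of-fold ProBFS (`generate_probfs_oof()`, base learners never see a
document's own label) drops held-out accuracy to chance within Monte-Carlo
error. For any genuine evaluation use the out-of-fold variant or
`probfs_cross_validate(..., regenerate = "per_fold")`, which refits the
base learners inside every training fold.

## Problem sizes used by the checks

The end-to-end property checks run on generator corpora of 2,000
documents (five seeds) for the comparative experiment — compact
probability features match or beat the raw term matrices for KNN and SVM
downstream — and 400 documents for the leakage demonstration, where the
~1,100-term vocabulary exceeds the document count, the regime
interpolation requires. Unit-level oracles (brute-force TF-IDF,
contingency chi-squared, eigendecomposition, canonical stemmer pairs) run
on corpora of at most 5 documents × 20 terms.

## Known limitations

* ProBFS is defined for binary problems; width would grow as
  2 × classes × models otherwise, which the package does not implement.
* Four highly-correlated features are too few for deep learners; the
  representation targets classical models.
* The full-fit mode's optimism is inherent to its definition; the package
  reproduces it and documents it rather than hiding it.
* The Porter stemmer implements the classic 1980 algorithm; later
  revisions (e.g. special-casing of short words or `logi` endings) differ
  on a handful of words.
* `benchmark()` timings are wall-clock on whatever machine runs them;
  they are reported for relative comparison only.
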