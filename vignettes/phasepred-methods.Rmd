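---
title: "Predicting phase-separating proteins from sequence embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phase-separating proteins from sequence embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Liquid–liquid phase separation (LLPS) drives the assembly of membraneless
organelles: a small set of scaffold proteins demix, alone or with nucleic
acids, into condensed liquid droplets, and dysregulated condensation is
implicated in neurodegenerative disease. Experimentally verified
phase-separation proteins (PSPs) number only in the hundreds, so a
sequence-only classifier that generalizes beyond specific protein families
(prion-like domains, RGG/FET proteins, pi-contact scorers) is valuable both
for proteome-wide triage and for prioritizing candidates for droplet
assays.

`phasepred` implements such a classifier end to end: proteins are embedded
as fixed-length vectors built from k-mer word vectors and sinusoidal
positional encodings, and a gradient-boosted decision tree (GBDT) is
trained on undersampled positive/negative sets. Because the package is
exercised on synthetic sequences with planted signal, every stage — corpus
generation, embedding training, classification, and the full evaluation
apparatus — runs without any external download.

## The embedding model

Each protein sequence is tokenized into overlapping k-mers (default
`k = 3`, stride 1), which play the role of words. Skip-gram word vectors
with hierarchical softmax are trained on an unlabeled corpus with context
window 8 and dimension `d_model = 200`. No R package provides word2vec
training, so the trainer is implemented in C++ (single-threaded, seeded,
linear learning-rate decay, Huffman-coded output tree); given one worker
and a fixed seed the vectors are bit-reproducible, which the test suite
relies on.

Sequence order is injected with the sinusoidal positional encoding

$$PE_{(pos,\,2i)} = \sin\!\big(pos / 10000^{2i/d_{model}}\big), \qquad
  PE_{(pos,\,2i+1)} = \cos\!\big(pos / 10000^{2i/d_{model}}\big),$$

whose wavelengths form a geometric progression from $2\pi$ to
$10000 \cdot 2\pi$ and for which $PE_{pos+\delta}$ is a fixed per-pair
rotation of $PE_{pos}$. The position index is the k-mer index (0-based):
the tokens, not the residues, are the words being encoded.

### Aggregation: why modulation rather than addition

A transformer adds $PE$ to token vectors and lets attention mix them
nonlinearly. Here the per-token vectors must be collapsed into one
fixed-length vector, and the naive transcription — an elementwise mean of
$v_t + PE(t)$ — is a trap: since
$\operatorname{mean}_t(v_t + PE(t)) = \operatorname{mean}_t(v_t) +
\operatorname{mean}_t(PE(t))$ and the second term depends only on the
number of tokens, that aggregate is invariant under any reordering of the
sequence. It cannot carry order information at all. `embed_protein()`
therefore uses positional *modulation*,

$$h \;=\; \operatorname{mean}_t\, v_t \odot (1 + PE(t)),$$

which expands to the compositional mean $\operatorname{mean}_t v_t$ plus
the order-dependent cross-term $\operatorname{mean}_t v_t \odot PE(t)$,
stays within `d_model` dimensions, and reduces to the plain mean when
positional encoding is disabled (`use_pe = FALSE`). The test suite pins
the intended behavior: with PE off, permuting a sequence's tokens leaves
the vector unchanged; with PE on, it does not.

Out-of-vocabulary k-mers contribute a zero vector but keep their position
and count in the mean denominator; the per-protein OOV rate is attached to
every embedded matrix. The alternative — dropping OOV tokens — would
silently shift all downstream positions.

### The Com-Len baseline

The 21-dimensional baseline encodes each protein as the fractions of the
20 standard amino acids (fixed order `ACDEFGHIKLMNPQRSTVWY`) plus the raw
length. It is order-invariant by construction, which makes it the control
for the claim that embeddings capture more than composition.

## Classification and evaluation

Negatives typically outnumber positives several-fold, so training sets are
built by undersampling: all positives are kept and negatives are drawn
without replacement to ratios 1:1, 1:2 or 1:5. The model grid crosses
those 3 ratios with 2 encodings (embedding + PE, Com-Len) and 7 algorithms
(KNN, SVM, RF, LR, DT, GBDT, NB) — 42 configurations, each evaluated by
stratified 10-fold cross-validation. Per fold the package reports
accuracy, F1, precision, sensitivity, specificity, MCC and the Brier score
(mean squared difference between predicted probability and outcome), with
mean and sample SD (n−1) across folds. The best configuration is the
highest mean accuracy, ties broken by MCC, and is compared to every other
configuration with a two-sided paired t-test on per-fold accuracies
(p-values reported raw).

Three further analyses probe *what* the model learned:

* **Shuffling control** — each source sequence is permuted `n_shuffles`
  times; permutation preserves composition exactly while destroying
  order, so the fraction of shuffled sequences still classified positive
  measures how much of the signal is compositional.
* **PCA projection** — mean-centered PCA of the embedded training
  vectors, with variance fractions, for visualizing class separation in
  the learned space.
* **Recall-vs-acceptance curve and proteome thresholding** — for a score
  threshold set at the upper $x$-quantile of a background (proteome)
  score distribution, the curve reports the recall of known positives as
  a function of the accepted fraction $x$; `proteome_threshold()` returns
  the top-fraction (default 1.8%) acceptance set with ties at the
  threshold all accepted.

## The synthetic-sequence generator

`generator_config()` fixes the study conditions for all tests:

| parameter | default | rationale |
|---|---|---|
| lengths | 100–400 residues | typical single-domain to mid-size proteins |
| positive motif | `RGGRGG`, 4 copies | RGG-box-like repeat; plants *sequential* signal |
| positive composition | G/R/S/Y/Q up-weighted 3x | low-complexity bias of known PSPs (*compositional* signal) |
| negative composition | near-uniform | folded-domain stand-in |
| `X` frequency | 0.005 | trace ambiguity letter, keeps the 21-letter alphabet exercised |
| corpus | 1000 sequences, 50/50 class mixture | covers both classes' k-mer vocabulary |

Positives therefore differ from negatives in both composition and k-mer
order. For experiments that must isolate *sequential* signal, the
`decoy_in_negatives` option plants residue-permuted copies of the motif in
every negative: the two classes then match in residue composition (the
Com-Len baseline drops to chance) and differ only in k-mer identity and
order. Motif and decoy copies are placed jointly non-overlapping at
uniformly random positions, overwriting the background so lengths are
unchanged.

What the generator does **not** emulate: real PSP length and disorder
distributions, homology structure between sequences (no shared ancestry,
so no similarity-based leakage between CV folds), database noise, or
multi-domain architecture. Passing tests demonstrate that the pipeline
recovers planted signal of both kinds under controlled conditions — not
that the quantitative accuracies transfer to curated PSP databases.

## Numerical choices

* Ambiguity letters B, Z, U, O, J are normalized to `X` on input; `*` and
  `-` are stripped with a warning. A single wildcard keeps the k-mer
  vocabulary at $\le 21^k$.
* 0/0 metric cells (precision of an all-negative predictor, MCC with an
  empty margin) are defined as 0 and flagged `degenerate`.
* Scores exactly at the decision threshold (default 0.5) classify
  positive.
* Paired t-tests with all-zero differences report $t=0, p=1$; constant
  nonzero differences (zero variance) report $p=0$ with a degeneracy
  flag, using the same near-zero-variance criterion `stats::t.test`
  applies before refusing constant data.
* GBDT uses `xgboost` with exact greedy splits (`tree_method = "exact"`,
  100 trees, depth 3, learning rate 0.1): histogram binning places split
  thresholds on data-adjacent bin edges, which misclassifies held-out
  margin points even on widely separated classes. The remaining six
  algorithms use their library defaults (KNN `k = 5`).
* SVM probabilities come from the library's Platt-scaled calibration;
  every seed-sensitive fit is wrapped in a private, restored RNG stream
  so package calls never perturb the caller's RNG.
* The recall-curve threshold is an observed background score (upper
  empirical quantile, "higher" interpolation) for bit-exact
  reproducibility; at acceptance fraction 1 the threshold is $-\infty$ so
  that everything — including positives scoring below the background
  minimum — is accepted.
* The embedding text format stores vectors with `%.17g`, which
  round-trips doubles exactly.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to keep a
laptop-class, single-CPU run comfortable: embedding-quality and
planted-signal-recovery checks use 200+200 labeled sequences with a
1000-sequence corpus at the full `d_model = 200`; the 42-configuration
grid runs on 60 positives against a 300-negative pool with 50-dimensional
embeddings; vocabulary-coverage uses a 5000-sequence corpus; the shuffling
control books 60 sources x 100 permutations. These are the package's own
fixture scales, stated here so results are interpreted at the scale that
produced them.

## Limitations

* The aggregation rule is a design choice isolated behind
  `embed_protein()`; other order-preserving aggregations (concatenated
  positional pools, recurrent readouts) are deliberately out of scope.
* Skip-gram training is single-threaded by design: determinism is traded
  for speed, which matters for corpora far larger than the fixtures.
* Probability calibration differs across the seven algorithms; Brier
  scores are comparable within an algorithm across configurations, less
  so between algorithms.
* With heavily saturated classifiers (many tied scores at 1.0), the
  top-fraction tie rule can accept far more than the requested fraction;
  the report includes both the requested and the actual count.
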