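# phasepred

Sequence-based prediction of liquid–liquid phase-separating proteins
(PSPs).

Membraneless organelles — nucleoli, stress granules, P-bodies — assemble
when scaffold proteins demix from the cytoplasm by liquid–liquid phase
separation (LLPS). Experimentally verified PSPs are scarce and first
generation predictors key on narrow features (prion-like domains, pi–pi
contacts, RGG/tyrosine content), so `phasepred` implements a general
sequence-only classifier together with the full training and evaluation
apparatus around it, for computational biologists who want to score
candidate proteins, audit what such a classifier actually learns, or
stress-test the method on data with known ground truth.

## Method

A protein of length $L$ is tokenized into $L-k+1$ overlapping k-mers
(default $k=3$, stride 1). Skip-gram word vectors $v_t \in \mathbb{R}^{d}$
($d = 200$, context window 8, hierarchical softmax) are trained on an
unlabeled corpus, and each protein is collapsed to one fixed-length
vector by positionally modulated averaging

$$h \;=\; \frac{1}{T}\sum_{t=0}^{T-1} v_t \odot \big(1 + PE(t)\big),
\qquad
PE_{(t,2i)} = \sin\frac{t}{10000^{2i/d}},\;\;
PE_{(t,2i+1)} = \cos\frac{t}{10000^{2i/d}},$$

so the embedding carries both composition (the mean term) and sequence
order (the cross-term; see the methods vignette for why a purely additive
mean cannot). A gradient-boosted decision tree is trained on undersampled
positive/negative sets (ratios 1:1, 1:2, 1:5) and compared against six
other algorithms (KNN, SVM, RF, LR, DT, NB) and a 21-dimensional
composition-plus-length baseline (Com-Len) in a 3 × 2 × 7 model grid under
stratified 10-fold cross-validation, with accuracy, F1, precision,
sensitivity, specificity, MCC and Brier score per configuration, paired
t-tests against the best model, sequence-shuffling controls, PCA
projections of the embedding space, recall-vs-acceptance curves and
top-fraction (1.8%) proteome thresholding.

A synthetic-sequence generator plants compositional signal (G/R/S/Y/Q
bias) and sequential signal (non-overlapping `RGGRGG` repeats) into
positive sequences, so the whole pipeline trains and evaluates without
any external database.

## Worked example

```r
library(phasepred)

cfg  <- generator_config(seed = 42, n_pos = 50, n_neg = 100, corpus_size = 200)
sets <- generate_labeled_sets(cfg)
emb  <- train_skipgram(generate_corpus(cfg), d_model = 64, epochs = 3, seed = 42)
emb
#> <embedding_model> 8397 k-mers (k=3), 64 dims, window 8, skipgram_hs, seed 42

xp <- embed_records(sets$positives, emb)   # 50 x 64, scheme "W2V_PE"
xn <- embed_records(sets$negatives, emb)
ds <- build_dataset(xp, xn, ratio = c(1, 1), seed = 42)
cv <- cross_validate(ds, classifier_spec("GBDT", seed = 42),
                     folds = 10, seed = 42)
cv
#> <cv_result> 10 folds: accuracy 0.9900 +/- 0.0316, mcc 0.9816

model <- train_classifier(ds, classifier_spec("GBDT", seed = 42))
head(predict_scores(model, xn), 3)
#>         id     score label
#> 1 neg_0001 0.0199075     0
#> 2 neg_0002 0.0199075     0
#> 3 neg_0003 0.0199075     0

sh <- shuffle_experiment(sets$positives, 20, model, emb, seed = 42)
round(c(shuffled_positive_fraction = sh$mean, sd = sh$sd), 4)
#> shuffled_positive_fraction                         sd
#>                     0.7670                     0.1803
```

The cross-validated accuracy (0.99) says the classifier recovers the
planted signal almost perfectly; the shuffle control says roughly 77% of
order-destroyed positives are still accepted, i.e. most — but not all —
of what the model uses here is compositional, with the remainder
attributable to k-mer order.

The same pipeline is scriptable from a shell via the installed entry
point (`system.file("cli", "phasepred", package = "phasepred")`), with
subcommands `synth`, `embed`, `train`, `predict`, `evaluate`, `grid`,
`shuffle-test` and `scan`, `--key value` flags, `--config FILE` defaults,
and a JSON run manifest written next to every output.

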