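#' Confusion matrix from truth and predicted labels
#'
#' @param truth,predicted Binary 0/1 vectors of equal length.
#' @return List of class `confusion_matrix` with counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 1)
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  structure(list(tp = sum(truth == 1 & predicted == 1),
                 fp = sum(truth == 0 & predicted == 1),
                 tn = sum(truth == 0 & predicted == 0),
                 fn = sum(truth == 1 & predicted == 0)),
            class = "confusion_matrix")
}

# 0/0 cells define the metric as 0 (degenerate-predictor convention).
safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Confusion-matrix classification metrics
#'
#' Computes Accuracy, F1, Precision, Sensitivity (recall), Specificity and
#' the Matthews correlation coefficient.  Any 0/0 ratio (e.g. precision of
#' an all-negative predictor, or MCC with an empty margin) is defined as 0
#' and flagged in the `degenerate` field.
#'
#' @param cm A [confusion_matrix()], or a list/vector with named elements
#'   `tp`, `fp`, `tn`, `fn`.
#' @return List of class `metrics_report`: `accuracy`, `f1`, `precision`,
#'   `sensitivity`, `specificity`, `mcc`, `degenerate`.
#' @examples
#' compute_metrics(list(tp = 9, fn = 1, tn = 8, fp = 2))
#' @export
compute_metrics <- function(cm) {
  cm <- as.list(cm)[c("tp", "fp", "tn", "fn")]
  counts <- as.numeric(cm)
  if (anyNA(counts) || any(counts < 0)) {
    stop("confusion-matrix counts must be non-negative")
  }
  tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
  total <- tp + fp + tn + fn
  if (total < 1) stop("confusion matrix is empty")
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  degenerate <- (tp + fp == 0) || (tp + fn == 0) || (tn + fp == 0) ||
    (tn + fn == 0) || (precision + sensitivity == 0)
  structure(list(
    accuracy = (tp + tn) / total,
    f1 = safe_div(2 * precision * sensitivity, precision + sensitivity),
    precision = precision,
    sensitivity = sensitivity,
    specificity = safe_div(tn, tn + fp),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    degenerate = degenerate),
    class = "metrics_report")
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; 0 for a perfect confident predictor, 0.25 for a constant 0.5.
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param outcomes Binary 0/1 vector of the same length.
#' @return Scalar in \[0, 1\].
#' @export
brier_score <- function(probabilities, outcomes) {
  if (length(probabilities) != length(outcomes)) {
    stop("probabilities and outcomes differ in length")
  }
  if (length(probabilities) == 0) stop("empty input")
  mean((probabilities - as.numeric(outcomes))^2)
}

# Stratified fold assignment: within each class, ids are shuffled and dealt
# round-robin, so per-class fold sizes differ by at most one.
stratified_folds <- function(y, folds, seed) {
  with_private_seed(seed, {
    assign <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < folds) {
        stop("class ", cls, " has ", length(idx),
             " members; need >= ", folds, " for ", folds, "-fold CV")
      }
      assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Assigns stratified, seeded folds, trains on each training split and
#' scores the held-out fold, collecting the six confusion-matrix metrics
#' plus the Brier score per fold, with mean and sample standard deviation
#' across folds.
#'
#' @param dataset A [build_dataset()] result.
#' @param spec A [classifier_spec()].
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return List of class `cv_result`: `per_fold` (data frame, one row per
#'   fold), `mean`, `sd` (named numeric), `folds`, `seed`.
#' @export
cross_validate <- function(dataset, spec, folds = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"), folds >= 2)
  assign <- stratified_folds(dataset$y, folds, seed)
  metric_names <- c("accuracy", "f1", "precision", "sensitivity",
                    "specificity", "mcc", "brier")
  per_fold <- matrix(NA_real_, nrow = folds, ncol = length(metric_names),
                     dimnames = list(NULL, metric_names))
  for (f in seq_len(folds)) {
    tr <- assign != f
    train <- structure(list(x = dataset$x[tr, , drop = FALSE],
                            y = dataset$y[tr], ids = dataset$ids[tr],
                            ratio = dataset$ratio, scheme = dataset$scheme,
                            seed = dataset$seed),
                       class = "labeled_dataset")
    model <- train_classifier(train, spec)
    held <- predict_scores(model, dataset$x[!tr, , drop = FALSE])
    m <- compute_metrics(confusion_matrix(dataset$y[!tr], held$label))
    per_fold[f, ] <- c(m$accuracy, m$f1, m$precision, m$sensitivity,
                       m$specificity, m$mcc,
                       brier_score(held$score, dataset$y[!tr]))
  }
  per_fold <- as.data.frame(per_fold)
  structure(list(per_fold = per_fold,
                 mean = vapply(per_fold, mean, numeric(1)),
                 sd = vapply(per_fold, stats::sd, numeric(1)),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: accuracy %.4f +/- %.4f, mcc %.4f\n",
              x$folds, x$mean[["accuracy"]], x$sd[["accuracy"]],
              x$mean[["mcc"]]))
  invisible(x)
}

#' Paired t-test with explicit degenerate-case handling
#'
#' Two-sided paired t-test on matched per-fold metric values.  If every
#' difference is exactly zero the test is reported as `t = 0`, `p = 1`; if
#' the differences are constant but nonzero (zero variance, so the t
#' statistic is unbounded) `p` is reported as 0 with `degenerate = TRUE`.
#'
#' @param folds_a,folds_b Equal-length numeric vectors (length >= 2).
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
paired_ttest <- function(folds_a, folds_b) {
  if (length(folds_a) != length(folds_b)) {
    stop("fold vectors differ in length")
  }
  n <- length(folds_a)
  if (n < 2) stop("need at least 2 paired values")
  d <- folds_a - folds_b
  m <- mean(d)
  stderr <- stats::sd(d) / sqrt(n)
  # same near-zero-variance criterion t.test uses to refuse constant data
  if (stderr <= 10 * .Machine$double.eps * max(abs(m), 1e-300)) {
    if (abs(m) <= stderr) {
      return(list(t = 0, p = 1, df = n - 1L, degenerate = FALSE))
    }
    return(list(t = sign(m) * Inf, p = 0, df = n - 1L, degenerate = TRUE))
  }
  tt <- stats::t.test(folds_a, folds_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Run the full ratio x encoding x algorithm model grid
#'
#' Builds one undersampled dataset per (ratio, encoding) pair, cross
#' validates every algorithm on it, and summarizes the grid: under the
#' defaults (3 ratios x 2 encodings x 7 algorithms) exactly 42
#' configurations.  The best model is the highest mean CV accuracy with
#' ties broken by mean MCC; the best model is compared to every other
#' configuration by paired t-test on per-fold accuracies.
#'
#' @param positives,negative_pool Named lists of feature matrices, one per
#'   encoding (e.g. `list(W2V_PE = ..., COM_LEN = ...)`).
#' @param ratios List of integer pairs (default 1:1, 1:2, 1:5).
#' @param algorithms Character vector of algorithm names.
#' @param folds CV folds.
#' @param seed Master seed for undersampling and fold assignment.
#' @return List of class `grid_result`: `table` (one row per
#'   configuration: ratio, encoding, algorithm, per-metric mean/sd, t-test
#'   vs best), `cv` (named list of `cv_result`), `best` (name of the best
#'   configuration).
#' @export
run_grid <- function(positives, negative_pool,
                     ratios = list(c(1L, 1L), c(1L, 2L), c(1L, 5L)),
                     algorithms = ALGORITHMS,
                     folds = 10L, seed = 1L) {
  stopifnot(is.list(positives), is.list(negative_pool),
            setequal(names(positives), names(negative_pool)))
  encodings <- names(positives)
  cv <- list()
  rows <- list()
  for (ri in seq_along(ratios)) {
    ratio <- ratios[[ri]]
    for (enc in encodings) {
      ds <- build_dataset(positives[[enc]], negative_pool[[enc]], ratio,
                          seed = seed + ri)
      for (algo in algorithms) {
        key <- sprintf("%d:%d|%s|%s", ratio[1], ratio[2], enc, algo)
        res <- cross_validate(ds, classifier_spec(algo, seed = seed),
                              folds = folds, seed = seed)
        cv[[key]] <- res
        rows[[key]] <- data.frame(
          ratio = sprintf("%d:%d", ratio[1], ratio[2]),
          encoding = enc, algorithm = algo,
          accuracy = res$mean[["accuracy"]], accuracy_sd = res$sd[["accuracy"]],
          f1 = res$mean[["f1"]], precision = res$mean[["precision"]],
          sensitivity = res$mean[["sensitivity"]],
          specificity = res$mean[["specificity"]],
          mcc = res$mean[["mcc"]], brier = res$mean[["brier"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  keys <- names(cv)
  ord <- order(-table$accuracy, -table$mcc)
  best <- keys[ord[1]]
  best_acc <- cv[[best]]$per_fold$accuracy
  tt <- lapply(keys, function(k) {
    if (k == best) {
      list(t = NA_real_, p = NA_real_, degenerate = FALSE)
    } else {
      paired_ttest(best_acc, cv[[k]]$per_fold$accuracy)
    }
  })
  table$t_vs_best <- vapply(tt, function(z) z$t, numeric(1))
  table$p_vs_best <- vapply(tt, function(z) z$p, numeric(1))
  structure(list(table = table, cv = cv, best = best,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d configurations, best: %s (accuracy %.4f)\n",
              nrow(x$table), x$best,
              max(x$table$accuracy)))
  invisible(x)
}

#' Sequence-shuffling control experiment
#'
#' Scores `n_shuffles` random residue permutations of every source
#' sequence and reports, per source, the fraction of its permutations
#' classified positive, plus the mean and sample SD of that fraction
#' across sources.  Because shuffling preserves composition and destroys
#' order, a large drop from the intact positive rate indicates the model
#' uses sequential information.
#'
#' @param records Source protein records.
#' @param n_shuffles Permutations per source.
#' @param model A `trained_model` fitted on embedding features.
#' @param embedding The `embedding_model` used for those features.
#' @param seed Shuffling seed.
#' @param use_pe Embed shuffled sequences with positional encoding.
#' @return List: `mean`, `sd`, `per_source` (named fractions), `n_scored`.
#' @export
shuffle_experiment <- function(records, n_shuffles, model, embedding,
                               seed = 1L, use_pe = TRUE) {
  shuffled <- shuffle_sequences(records, n_shuffles, seed)
  x <- embed_records(shuffled, embedding, use_pe = use_pe)
  scores <- predict_scores(model, x)
  frac <- tapply(scores$label, shuffled$source_id, mean)
  frac <- frac[unique(shuffled$source_id)]   # source order, not alphabetical
  list(mean = mean(frac), sd = stats::sd(frac),
       per_source = frac, n_scored = nrow(shuffled))
}

#' PCA projection of protein vectors
#'
#' Mean-centered principal component analysis of a feature matrix, for
#' visualizing how the embedding separates the two classes.
#'
#' @param vectors Feature matrix (>= 2 rows).
#' @param components Number of leading components to keep.
#' @return List: `coordinates` (rows x components score matrix),
#'   `variance_fraction` (all components, non-increasing, summing to <= 1).
#' @export
pca_project <- function(vectors, components = 2L) {
  stopifnot(is.matrix(vectors), nrow(vectors) >= 2)
  if (components > ncol(vectors)) {
    stop("components (", components, ") exceeds feature width (",
         ncol(vectors), ")")
  }
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  list(coordinates = pc$x[, seq_len(components), drop = FALSE],
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2))
}

#' Recall as a function of accepted background fraction
#'
#' For each acceptance fraction `x`, the score threshold is set so that a
#' fraction `x` of the background (e.g. whole-proteome) scores is
#' accepted, and recall is the fraction of positive scores at or above
#' that threshold.  The threshold is an observed background score (upper
#' empirical quantile); at `x = 1` everything is accepted.
#'
#' @param positive_scores,background_scores Non-empty numeric vectors.
#' @param acceptance_fractions Grid of fractions in (0, 1].
#' @return Data frame with columns `fraction_accepted`, `threshold`,
#'   `recall`; recall is monotone non-decreasing in the fraction.
#' @export
recall_vs_acceptance <- function(positive_scores, background_scores,
                                 acceptance_fractions =
                                   seq(0.02, 1, by = 0.02)) {
  if (length(positive_scores) == 0 || length(background_scores) == 0) {
    stop("positive and background scores must be non-empty")
  }
  stopifnot(all(acceptance_fractions > 0), all(acceptance_fractions <= 1))
  s <- sort(background_scores)
  n <- length(s)
  out <- lapply(acceptance_fractions, function(x) {
    if (x >= 1) {
      thr <- -Inf
    } else {
      thr <- s[min(n, floor((1 - x) * n) + 1L)]
    }
    data.frame(fraction_accepted = x, threshold = thr,
               recall = mean(positive_scores >= thr))
  })
  do.call(rbind, out)
}

#' Top-fraction proteome threshold
#'
#' Accepts the `ceiling(top_fraction * n)` highest-scoring proteins; the
#' reported threshold is the minimum accepted score, and ties at the
#' threshold are all accepted (the accepted set may therefore exceed the
#' ceiling).
#'
#' @param scores Named numeric vector of scores (names = protein ids).
#' @param top_fraction Fraction of the proteome to accept (default 0.018,
#'   the high-confidence tier).
#' @return List: `threshold`, `accepted_ids`, `n_accepted`, `n_requested`.
#' @export
proteome_threshold <- function(scores, top_fraction = 0.018) {
  if (length(scores) == 0) stop("empty score vector")
  stopifnot(top_fraction > 0, top_fraction <= 1)
  n <- length(scores)
  m <- ceiling(top_fraction * n)
  thr <- sort(scores, decreasing = TRUE)[m]
  accepted <- which(scores >= thr)
  list(threshold = thr,
       accepted_ids = names(scores)[accepted] %||% accepted,
       n_accepted = length(accepted),
       n_requested = m)
}
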