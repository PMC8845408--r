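# Independent oracle: expands a confusion matrix into explicit truth and
# prediction vectors and recomputes every metric from those vectors with
# base-R summaries (MCC as the Pearson correlation of the two 0/1 vectors).
oracle_metrics <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  prec <- if (sum(pred) == 0) 0 else mean(truth[pred == 1])
  sens <- if (sum(truth) == 0) 0 else mean(pred[truth == 1])
  mcc <- suppressWarnings(stats::cor(truth, pred))
  list(accuracy = mean(truth == pred),
       f1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens),
       precision = prec,
       sensitivity = sens,
       specificity = if (sum(1 - truth) == 0) 0 else mean(1 - pred[truth == 0]),
       mcc = if (is.na(mcc)) 0 else mcc)
}

test_that("worked confusion-matrix example evaluates correctly", {
  m <- compute_metrics(list(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 9 / 11, tolerance = 1e-12)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$mcc, 0.7035, tolerance = 1e-4)

  perfect <- compute_metrics(list(tp = 10, fn = 0, tn = 10, fp = 0))
  expect_equal(unlist(perfect[c("accuracy", "f1", "precision",
                                "sensitivity", "specificity", "mcc")]),
               c(accuracy = 1, f1 = 1, precision = 1, sensitivity = 1,
                 specificity = 1, mcc = 1))
  expect_error(compute_metrics(list(tp = -1, fp = 0, tn = 1, fn = 0)),
               "non-negative")
})

test_that("degenerate all-positive predictor follows the 0/0 rule", {
  m <- compute_metrics(list(tp = 25, fn = 0, tn = 0, fp = 25))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_equal(m$mcc, 0)
  expect_true(m$degenerate)
})

test_that("metrics agree with the expanded-vector oracle on random matrices", {
  set.seed(42)
  for (rep in 1:200) {
    cm <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("tp", "fp", "tn", "fn")))
    if (sum(unlist(cm)) == 0) next
    got <- compute_metrics(cm)
    want <- oracle_metrics(cm$tp, cm$fp, cm$tn, cm$fn)
    for (metric in names(want)) {
      expect_equal(got[[metric]], want[[metric]], tolerance = 1e-12,
                   info = sprintf("%s at tp=%d fp=%d tn=%d fn=%d",
                                  metric, cm$tp, cm$fp, cm$tn, cm$fn))
    }
  }
})

test_that("MCC is symmetric under simultaneous class/prediction swap", {
  set.seed(7)
  for (rep in 1:50) {
    cm <- sample(0:20, 4, replace = TRUE)
    a <- compute_metrics(list(tp = cm[1], fp = cm[2], tn = cm[3], fn = cm[4]))
    b <- compute_metrics(list(tp = cm[3], fp = cm[4], tn = cm[1], fn = cm[2]))
    expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
  }
})

test_that("brier score matches its closed forms", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.25)
  expect_equal(brier_score(c(0, 1), c(1, 0)), 1)
  expect_error(brier_score(c(0.5, 0.5), 1), "length")
})

test_that("cross-validation is stratified, seeded and exact on separable data", {
  ds <- toy_dataset(n_per_class = 50)
  cv <- cross_validate(ds, classifier_spec("GBDT", seed = 3), folds = 10,
                       seed = 3)
  expect_equal(nrow(cv$per_fold), 10L)
  expect_equal(cv$mean[["accuracy"]], 1.0)
  expect_equal(cv$sd[["accuracy"]], 0.0)
  # aggregates recomputable from the fold table
  expect_equal(cv$mean[["mcc"]], mean(cv$per_fold$mcc))
  expect_equal(cv$sd[["brier"]], stats::sd(cv$per_fold$brier))
  expect_error(cross_validate(ds, classifier_spec("GBDT"), folds = 60),
               "need >=")
})

test_that("label permutation drives CV accuracy to the null band", {
  ds <- toy_dataset(n_per_class = 100)
  set.seed(19)
  ds$y <- sample(ds$y)
  cv <- cross_validate(ds, classifier_spec("DT", seed = 19), folds = 10,
                       seed = 19)
  expect_gte(cv$mean[["accuracy"]], 0.35)
  expect_lte(cv$mean[["accuracy"]], 0.65)
})

test_that("stratified folds differ by at most one member per class", {
  y <- c(rep(1L, 53), rep(0L, 97))
  assign <- phasepred:::stratified_folds(y, 10L, seed = 2)
  for (cls in c(0L, 1L)) {
    sizes <- table(assign[y == cls])
    expect_lte(max(sizes) - min(sizes), 1L)
  }
})

test_that("paired t-test handles regular and degenerate inputs", {
  a <- c(0.9, 0.8, 0.7)
  b <- c(0.85, 0.75, 0.75)
  got <- paired_ttest(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  # hand evaluation: d = (0.05, 0.05, -0.05), mean 1/60, sd(d) = 0.05774,
  # t = (1/60) / (0.05774 / sqrt(3)) = 0.5, p = 2*pt(-0.5, df = 2) = 2/3
  expect_equal(got$t, 0.5, tolerance = 1e-10)
  expect_equal(got$p, 2 * stats::pt(-0.5, 2), tolerance = 1e-10)

  same <- paired_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$degenerate)

  const <- paired_ttest(c(0.9, 0.8, 0.95, 0.85), c(0.7, 0.6, 0.75, 0.65))
  expect_true(const$degenerate)
  expect_equal(const$p, 0)
  expect_error(paired_ttest(a, a[1:2]), "length")
})

test_that("PCA matches a dense eigendecomposition oracle", {
  set.seed(31)
  x <- matrix(rnorm(200 * 12), ncol = 12) %*% matrix(rnorm(12 * 12), 12)
  got <- pca_project(x, components = 3)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  # prcomp divides by n-1 as cov does; fractions must agree
  expect_equal(got$variance_fraction, ev / sum(ev), tolerance = 1e-9)
  expect_true(all(diff(got$variance_fraction) <= 1e-12))

  # rank-1 data: first component explains everything
  base <- rnorm(3)
  collinear <- outer(seq_len(20), base)
  frac <- pca_project(collinear, 1)$variance_fraction
  expect_equal(frac[1], 1, tolerance = 1e-9)

  # rank-2 data reconstruct exactly from 2 components
  r2 <- matrix(rnorm(40), ncol = 2) %*% matrix(rnorm(2 * 6), 2)
  pr <- stats::prcomp(r2, center = TRUE)
  recon <- pr$x[, 1:2] %*% t(pr$rotation[, 1:2])
  recon <- sweep(recon, 2, -pr$center)
  expect_equal(recon, r2, tolerance = 1e-9)
  expect_error(pca_project(r2, components = 10), "exceeds")
})

test_that("recall-acceptance curve is monotone with correct endpoints", {
  set.seed(5)
  bg <- runif(500)
  pos <- runif(200, min = 0.5)
  curve <- recall_vs_acceptance(pos, bg, c(0.05, 0.1, 0.25, 0.5, 1))
  expect_true(all(diff(curve$recall) >= 0))
  expect_true(all(curve$recall >= 0 & curve$recall <= 1))
  expect_equal(curve$recall[curve$fraction_accepted == 1], 1)
  # positives strictly above the background maximum: recall 1 everywhere
  hi <- recall_vs_acceptance(rep(2, 10), bg, c(0.01, 0.5, 1))
  expect_equal(hi$recall, rep(1, 3))
  expect_error(recall_vs_acceptance(numeric(0), bg), "non-empty")
})

test_that("shuffle experiment books the right number of sequences", {
  emb <- tiny_embedding()
  cfg <- small_config(n_pos = 8L, n_neg = 8L)
  sets <- generate_labeled_sets(cfg)
  ds <- build_dataset(embed_records(sets$positives, emb),
                      embed_records(sets$negatives, emb),
                      c(1L, 1L), seed = 4)
  model <- train_classifier(ds, classifier_spec("GBDT", seed = 4))
  res <- shuffle_experiment(sets$positives, 5L, model, emb, seed = 4)
  expect_equal(res$n_scored, 8L * 5L)
  expect_length(res$per_source, 8L)
  expect_true(all(res$per_source >= 0 & res$per_source <= 1))
})

test_that("proteome thresholding accepts the requested top fraction", {
  set.seed(8)
  scores <- stats::setNames(sample(seq(0, 1, length.out = 1000)),
                            sprintf("q%04d", 1:1000))
  got <- proteome_threshold(scores, 0.018)
  expect_equal(got$n_requested, 18L)
  expect_equal(got$n_accepted, 18L)
  expect_equal(sort(got$accepted_ids),
               sort(names(sort(scores, decreasing = TRUE)[1:18])))
  expect_true(all(scores[got$accepted_ids] >= got$threshold))

  expect_equal(proteome_threshold(scores, 1)$n_accepted, 1000L)
  ties <- stats::setNames(rep(0.5, 40), sprintf("t%02d", 1:40))
  expect_equal(proteome_threshold(ties, 0.1)$n_accepted, 40L)
  expect_error(proteome_threshold(numeric(0)), "empty")
})

test_that("a reduced grid has the right cardinality and bookkeeping", {
  b <- toy_blobs(n_per_class = 30, seed = 13)
  pool <- toy_blobs(n_per_class = 90, seed = 14)$neg
  grid <- run_grid(positives = list(TOY = b$pos),
                   negative_pool = list(TOY = pool),
                   ratios = list(c(1L, 1L), c(1L, 2L)),
                   algorithms = c("GBDT", "DT", "NB"),
                   folds = 5L, seed = 13)
  expect_equal(nrow(grid$table), 2L * 1L * 3L)
  expect_true(grid$best %in% rownames(grid$table) ||
              grid$best %in% names(grid$cv))
  expect_true(is.na(grid$table$p_vs_best[
    sprintf("%s|%s|%s", grid$table$ratio, grid$table$encoding,
            grid$table$algorithm) == grid$best]))
  # identical per-fold accuracies give t = 0, p = 1 against the best
  seps <- grid$table$accuracy == 1
  if (sum(seps) >= 2) {
    expect_true(all(grid$table$p_vs_best[seps][-1] %in% c(1, NA)))
  }
})
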