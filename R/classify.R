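ALGORITHMS <- c("KNN", "SVM", "RF", "LR", "DT", "GBDT", "NB")

#' Assemble an undersampled labeled training set
#'
#' Keeps every positive vector and samples negatives from the pool without
#' replacement to reach the requested positive:negative ratio exactly, then
#' shuffles the row order.  Deterministic given `seed`.
#'
#' @param positives Numeric feature matrix of positive proteins (ids as
#'   rownames).
#' @param negative_pool Numeric feature matrix to undersample negatives
#'   from (same width as `positives`).
#' @param ratio Integer pair `c(pos, neg)`, e.g. `c(1, 2)` for 1:2; the
#'   sampled negative count is `nrow(positives) * neg / pos` (rounded).
#' @param seed Integer sampling seed.
#' @return List of class `labeled_dataset` with `x` (feature matrix), `y`
#'   (0/1 integer labels, 1 = positive), `ids`, `ratio`, `scheme`, `seed`.
#' @export
build_dataset <- function(positives, negative_pool, ratio = c(1L, 1L),
                          seed = 1L) {
  stopifnot(is.matrix(positives), is.matrix(negative_pool),
            ncol(positives) == ncol(negative_pool),
            length(ratio) == 2, all(ratio >= 1))
  n_pos <- nrow(positives)
  n_neg <- as.integer(round(n_pos * ratio[2] / ratio[1]))
  if (nrow(negative_pool) < n_neg) {
    stop("negative pool too small: need ", n_neg, ", have ",
         nrow(negative_pool))
  }
  pos_ids <- rownames(positives) %||% sprintf("pos_%d", seq_len(n_pos))
  pool_ids <- rownames(negative_pool) %||%
    sprintf("neg_%d", seq_len(nrow(negative_pool)))
  with_private_seed(seed, {
    keep <- sample.int(nrow(negative_pool), n_neg)
    x <- rbind(positives, negative_pool[keep, , drop = FALSE])
    y <- c(rep(1L, n_pos), rep(0L, n_neg))
    ids <- c(pos_ids, pool_ids[keep])
    ord <- sample.int(nrow(x))
    structure(list(x = x[ord, , drop = FALSE], y = y[ord], ids = ids[ord],
                   ratio = as.integer(ratio),
                   scheme = attr(positives, "scheme") %||% "unknown",
                   seed = as.integer(seed)),
              class = "labeled_dataset")
  })
}

#' Specify one of the seven supported classifiers
#'
#' @param algorithm One of `"KNN"`, `"SVM"`, `"RF"`, `"LR"`, `"DT"`,
#'   `"GBDT"`, `"NB"`.
#' @param params Named list of hyperparameter overrides.  Defaults: KNN
#'   `k = 5`; GBDT `nrounds = 100`, `max_depth = 3`, `eta = 0.1`; the other
#'   algorithms use their library defaults.
#' @param seed Integer seed for seed-sensitive algorithms.
#' @param threshold Decision threshold on the positive-class probability;
#'   scores `>= threshold` classify positive.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm, params = list(), seed = 1L,
                            threshold = 0.5) {
  algorithm <- toupper(algorithm)
  if (!algorithm %in% ALGORITHMS) {
    stop("unknown algorithm '", algorithm, "'; must be one of ",
         paste(ALGORITHMS, collapse = ", "))
  }
  stopifnot(threshold > 0, threshold < 1)
  structure(list(algorithm = algorithm, params = params,
                 seed = as.integer(seed), threshold = threshold),
            class = "classifier_spec")
}

#' Train a classifier on a labeled dataset
#'
#' Fits the algorithm named in `spec` and returns a model exposing
#' positive-class probabilities.  Seed-sensitive algorithms (SVM's
#' probability calibration, RF, GBDT) are seeded from `spec$seed`, so
#' refitting with the same spec reproduces identical scores.
#'
#' @param dataset A [build_dataset()] result (must contain both classes).
#' @param spec A [classifier_spec()].
#' @return List of class `trained_model` with the fitted state, `spec`,
#'   `scheme` and `width`.
#' @export
train_classifier <- function(dataset, spec) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(spec, "classifier_spec"))
  x <- dataset$x
  y <- dataset$y
  if (length(unique(y)) < 2) {
    stop("dataset contains a single class; need both")
  }
  p <- spec$params
  fit <- with_private_seed(spec$seed, switch(
    spec$algorithm,
    KNN = list(train_x = x, train_y = y, k = p$k %||% 5L),
    SVM = e1071::svm(x, factor(y, levels = c(0, 1)), probability = TRUE,
                     kernel = p$kernel %||% "radial",
                     cost = p$cost %||% 1),
    RF = randomForest::randomForest(
      x, factor(y, levels = c(0, 1)),
      ntree = p$ntree %||% 500L),
    LR = suppressWarnings(stats::glm(
      y ~ ., data = data.frame(y = y, x = I(x)),
      family = stats::binomial())),
    DT = rpart::rpart(
      y ~ ., data = data.frame(y = factor(y, levels = c(0, 1)), x = I(x)),
      method = "class"),
    GBDT = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = p$max_depth %||% 3L,
                    eta = p$eta %||% 0.1,
                    tree_method = p$tree_method %||% "exact",
                    nthread = 1L,
                    seed = spec$seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = p$nrounds %||% 100L, verbose = 0),
    NB = e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
  ))
  structure(list(fit = fit, spec = spec, scheme = dataset$scheme,
                 width = ncol(x)),
            class = "trained_model")
}

#' Score proteins with a trained model
#'
#' @param model A [train_classifier()] result.
#' @param vectors Feature matrix with the same width (and encoding scheme)
#'   the model was trained on.
#' @return Data frame with columns `id`, `score` (positive-class
#'   probability in \[0, 1\]) and `label` (1 iff `score >= threshold`), in
#'   input row order.
#' @export
predict_scores <- function(model, vectors) {
  stopifnot(inherits(model, "trained_model"), is.matrix(vectors))
  if (nrow(vectors) == 0) {
    return(data.frame(id = character(0), score = numeric(0),
                      label = integer(0)))
  }
  if (ncol(vectors) != model$width) {
    stop("feature width ", ncol(vectors), " does not match model width ",
         model$width)
  }
  spec <- model$spec
  score <- with_private_seed(spec$seed, switch(
    spec$algorithm,
    KNN = {
      pred <- class::knn(model$fit$train_x, vectors,
                         factor(model$fit$train_y, levels = c(0, 1)),
                         k = model$fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    SVM = {
      pr <- stats::predict(model$fit, vectors, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    RF = stats::predict(model$fit, vectors, type = "prob")[, "1"],
    LR = as.numeric(stats::predict(model$fit,
                                   data.frame(x = I(vectors)),
                                   type = "response")),
    DT = stats::predict(model$fit, data.frame(x = I(vectors)),
                        type = "prob")[, "1"],
    GBDT = as.numeric(stats::predict(
      model$fit, xgboost::xgb.DMatrix(vectors, nthread = 1L))),
    NB = stats::predict(model$fit, vectors, type = "raw")[, "1"]
  ))
  score <- pmin(pmax(as.numeric(score), 0), 1)
  data.frame(id = rownames(vectors) %||% as.character(seq_len(nrow(vectors))),
             score = score,
             label = as.integer(score >= spec$threshold),
             stringsAsFactors = FALSE)
}

#' Persist / restore a trained model bundle
#'
#' The bundle keeps the classifier spec, the fitted state and the feature
#' scheme together so `predict` runs can be separated from training.
#'
#' @param model A `trained_model`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   `trained_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(list(format = "phasepred_model", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "phasepred_model")) {
    stop("not a phasepred model bundle: ", path)
  }
  bundle$model
}
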