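#' Configuration for the pair-alignment classifier
#'
#' The fusion stages cast entity alignment as binary classification on
#' per-pair similarity features. Three model families are supported:
#' logistic regression, a decision tree (unlimited depth, minimum leaf
#' size 2) and a single-hidden-layer neural network (16 units, 200
#' epochs). Features are z-scored on the training split; the data are
#' split 8:2 into train and held-out test by default.
#'
#' @param model One of `"mlp"`, `"logreg"`, `"dtree"`.
#' @param decision_threshold Probability above which a pair is declared a
#'   match (in `(0, 1)`).
#' @param split_ratio Training fraction (in `(0, 1)`).
#' @param seed Integer seed controlling the split and model fitting.
#' @param mlp_hidden Hidden layer size for the `mlp` model.
#' @return A `pair_classifier_config` list.
#' @export
pair_classifier_config <- function(model = c("mlp", "logreg", "dtree"),
                                   decision_threshold = 0.5,
                                   split_ratio = 0.8, seed = 1L,
                                   mlp_hidden = 16L) {
  model <- match.arg(model)
  stopifnot(decision_threshold > 0, decision_threshold < 1,
            split_ratio > 0, split_ratio < 1)
  structure(list(
    model = model, decision_threshold = decision_threshold,
    split_ratio = split_ratio, seed = as.integer(seed),
    mlp_hidden = as.integer(mlp_hidden)
  ), class = "pair_classifier_config")
}

#' Precision / recall / F1 of binary predictions
#'
#' Precision is defined as 0 when nothing is predicted positive, and F1 as
#' 0 when precision and recall are both 0.
#'
#' @param pred Logical or 0/1 predictions.
#' @param truth 0/1 labels.
#' @return List with `precision`, `recall`, `f1`, `n`.
#' @export
prf_metrics <- function(pred, truth) {
  pred <- as.logical(pred)
  truth <- as.integer(truth) == 1L
  tp <- sum(pred & truth)
  p <- if (sum(pred) == 0) 0 else tp / sum(pred)
  r <- if (sum(truth) == 0) 0 else tp / sum(truth)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, n = length(pred))
}

#' Train a pair classifier on labeled feature vectors
#'
#' Splits the labeled pairs into train/test by `split_ratio`, z-scores the
#' features on the training split (constant features get unit scale), fits
#' the configured model and reports precision/recall/F1 on the held-out
#' fraction at the decision threshold. Deterministic given the config
#' seed.
#'
#' @param features Data frame or matrix of numeric feature columns.
#' @param labels Integer vector of 0/1 labels (both classes must be
#'   present in the training split).
#' @param config A [pair_classifier_config()].
#' @return A `pair_classifier` with elements `fit`, `center`, `scale`,
#'   `feature_names`, `metrics` (a `FusionMetrics`-style list with
#'   `precision`, `recall`, `f1`, `n_train`, `n_test`) and `config`.
#' @export
train_pair_classifier <- function(features, labels, config = pair_classifier_config()) {
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  withr::with_seed(config$seed, {
    n <- nrow(X)
    tr <- sort(sample.int(n, max(1, floor(n * config$split_ratio))))
    te <- setdiff(seq_len(n), tr)
    if (length(unique(y[tr])) < 2) {
      stop("training split contains a single class; cannot fit a classifier")
    }
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    Z <- scale(X, center = ctr, scale = scl)
    fit <- fit_pair_model(Z[tr, , drop = FALSE], y[tr], config)
    obj <- structure(list(
      fit = fit, center = ctr, scale = scl, feature_names = colnames(X),
      config = config
    ), class = "pair_classifier")
    if (length(te) > 0) {
      pr <- predict_pairs(obj, X[te, , drop = FALSE])
      m <- prf_metrics(pr > config$decision_threshold, y[te])
    } else {
      m <- list(precision = NA_real_, recall = NA_real_, f1 = NA_real_, n = 0L)
    }
    obj$metrics <- list(precision = m$precision, recall = m$recall, f1 = m$f1,
                        n_train = length(tr), n_test = length(te))
    obj
  })
}

fit_pair_model <- function(Z, y, config) {
  df <- as.data.frame(Z)
  df$.y <- y
  switch(config$model,
    logreg = suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    ),
    dtree = rpart::rpart(
      factor(.y) ~ ., data = df, method = "class",
      control = rpart::rpart.control(minsplit = 4, minbucket = 2, cp = 0,
                                     maxdepth = 30, xval = 0)
    ),
    mlp = nnet::nnet(
      Z, y, size = config$mlp_hidden, maxit = 200, decay = 1e-4,
      entropy = TRUE, trace = FALSE
    )
  )
}

#' Match probabilities for feature rows
#'
#' @param object A `pair_classifier`.
#' @param features Feature rows on the original (unscaled) scale, with the
#'   training feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_pairs <- function(object, features) {
  X <- as.matrix(as.data.frame(features)[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  Z <- scale(X, center = object$center, scale = object$scale)
  df <- as.data.frame(Z)
  fit <- object$fit
  p <- switch(object$config$model,
    logreg = suppressWarnings(
      stats::predict(fit, newdata = df, type = "response")
    ),
    dtree = stats::predict(fit, newdata = df, type = "prob")[, "1"],
    mlp = drop(stats::predict(fit, Z, type = "raw"))
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

# convenience: extract the standard feature columns of a stage
feature_columns <- function(stage = c("tail", "head")) {
  stage <- match.arg(stage)
  if (stage == "tail") c("semantic", "transr_cos", "jaccard")
  else c("same_tails", "set_jaccard", "transr_cos")
}
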