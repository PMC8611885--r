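# Per-(cancer, site) binary classification of metastatic progression with a
# leakage-safe protocol: 30% of the real samples are held out, stratified by
# class, before any synthetic oversampling, so no test sample ever serves as
# a SMOTE parent.

#' Stratified holdout split of real samples
#'
#' @param labels named binary vector (sample IDs -> 0/1), real samples only,
#'   or a `progression_labels` object.
#' @param holdout_fraction fraction held out per class (default 0.3).
#' @param seed integer seed; the same seed reproduces the same split.
#' @return object of class `split_plan`: list with `train`, `test` (ID
#'   vectors), `holdout_fraction`, `stratified = TRUE`, `seed`.
#' @export
split_holdout <- function(labels, holdout_fraction = 0.3, seed = 1) {
  if (inherits(labels, "progression_labels")) labels <- labels$labels
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  y <- as_binary01(labels)
  ids <- names(y)
  if (is.null(ids)) ids <- as.character(seq_along(y))
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab < 2)) stop("each class needs at least 2 samples to split")
  test <- withr::with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cls) {
      idx <- which(y == cls)
      n_test <- round_half_away(holdout_fraction * length(idx))
      n_test <- min(max(1L, as.integer(n_test)), length(idx) - 1L)
      sort(sample(idx, n_test))
    }))
  })
  structure(list(train = ids[-test], test = ids[sort(test)],
                 holdout_fraction = holdout_fraction, stratified = TRUE,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Binary site-model configuration
#'
#' @param model `"rf"` (random forest, default) or `"gbt"` (gradient-boosted
#'   trees); the architecture uses both interchangeably.
#' @param num_trees forest size for `"rf"`.
#' @param nrounds,max_depth,eta boosting parameters for `"gbt"`.
#' @param seed integer seed.
#' @return object of class `site_model_config`.
#' @export
site_model_config <- function(model = c("rf", "gbt"), num_trees = 300,
                              nrounds = 300, max_depth = 3, eta = 0.1,
                              seed = 1) {
  model <- match.arg(model)
  structure(list(model = model, num_trees = as.integer(num_trees),
                 nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 seed = as.integer(seed)),
            class = "site_model_config")
}

#' Turn posterior probabilities into class calls
#'
#' The classifier reports the rounded posterior: probability at or above
#' 0.5 is the positive class (the exact tie at 0.5 rounds up by convention).
#'
#' @param prob numeric vector of positive-class posteriors.
#' @return integer 0/1 vector.
#' @export
posterior_to_class <- function(prob) as.integer(prob >= 0.5)

#' Train a binary site-progression classifier
#'
#' @param X numeric matrix of training instances (real + synthetic),
#'   restricted to the pair's selected candidate features.
#' @param y binary labels for the rows of `X`.
#' @param cfg a [site_model_config()].
#' @return object of class `site_model`.
#' @export
train_site_model <- function(X, y, cfg = site_model_config()) {
  stopifnot(inherits(cfg, "site_model_config"))
  X <- as.matrix(X)
  y01 <- as_binary01(y)
  if (length(unique(y01)) < 2) stop("single-class training input")
  fit <- if (cfg$model == "rf") {
    df <- as.data.frame(X)
    names(df) <- make.names(colnames(X), unique = TRUE)
    ranger::ranger(x = df, y = factor(y01, levels = c(0, 1)),
                   num.trees = cfg$num_trees, probability = TRUE,
                   seed = cfg$seed, num.threads = 1)
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = y01)
    xgboost::xgb.train(params = list(objective = "binary:logistic",
                                     max_depth = cfg$max_depth, eta = cfg$eta,
                                     nthread = 1, seed = cfg$seed),
                       data = dtrain, nrounds = cfg$nrounds, verbose = 0)
  }
  structure(list(fit = fit, features = colnames(X), config = cfg),
            class = "site_model")
}

#' Predict progression posteriors and classes
#'
#' @param object a `site_model`.
#' @param newdata numeric matrix with the model's feature columns.
#' @param ... unused.
#' @return list with `prob` (positive-class posterior) and `class` (0/1 via
#'   [posterior_to_class()]).
#' @export
predict.site_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  prob <- if (object$config$model == "rf") {
    df <- as.data.frame(newdata)
    names(df) <- make.names(colnames(newdata), unique = TRUE)
    predict(object$fit, data = df, num.threads = 1)$predictions[, "1"]
  } else {
    predict(object$fit, xgboost::xgb.DMatrix(newdata))
  }
  names(prob) <- rownames(newdata)
  list(prob = prob, class = stats::setNames(posterior_to_class(prob),
                                            names(prob)))
}

#' Evaluate a binary site model on the held-out real samples
#'
#' @param model a `site_model`.
#' @param split a `split_plan`; only `split$test` rows are evaluated.
#' @param X numeric matrix of real samples (rownames = sample IDs).
#' @param y named binary labels for the rows of `X`.
#' @param pair optional pair identifier carried into the report.
#' @return object of class `binary_eval`: confusion counts, positive-class
#'   precision/recall/F1, accuracy, negative-class metrics, and `n_test`.
#'   Metrics with an empty denominator are `NA`.
#' @export
evaluate_binary <- function(model, split, X, y, pair = NULL) {
  stopifnot(inherits(split, "split_plan"))
  y01 <- as_binary01(y)
  if (is.null(names(y01))) names(y01) <- rownames(X)
  test_ids <- split$test
  stopifnot(all(test_ids %in% rownames(X)))
  pred <- predict(model, X[test_ids, , drop = FALSE])$class
  truth <- y01[test_ids]
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  n <- length(test_ids)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  npv <- safe_div(tn, tn + fn)
  spec <- safe_div(tn, tn + fp)
  f1_neg <- if (is.na(npv) || is.na(spec)) NA_real_
            else if (npv + spec == 0) 0 else 2 * npv * spec / (npv + spec)
  structure(list(pair = pair, tp = tp, fp = fp, fn = fn, tn = tn,
                 n_test = n,
                 precision = precision, recall = recall, f1 = f1,
                 accuracy = (tp + tn) / n,
                 negative = c(precision = npv, recall = spec, f1 = f1_neg)),
            class = "binary_eval")
}

#' @export
print.binary_eval <- function(x, ...) {
  if (!is.null(x$pair)) cat("Pair:", paste(x$pair, collapse = " | "), "\n")
  cat(sprintf("TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n_test))
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f  accuracy %.3f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Aggregate per-pair reports into a per-cancer table
#'
#' Cancer-level metrics are the unweighted mean of the per-site metrics.
#'
#' @param reports list of `binary_eval` objects whose `pair` is
#'   `c(cancer, site)`.
#' @return data.frame with one row per cancer: mean precision, recall, F1
#'   and accuracy across its sites.
#' @export
aggregate_site_reports <- function(reports) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(cancer = if (is.null(r$pair)) NA_character_ else r$pair[[1]],
               precision = r$precision, recall = r$recall, f1 = r$f1,
               accuracy = r$accuracy, stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(rows[, c("precision", "recall", "f1", "accuracy")],
                          by = list(cancer = rows$cancer),
                          FUN = mean, na.rm = TRUE)
  agg[order(agg$cancer), , drop = FALSE]
}

#' Run the full leakage-safe analysis for one (cancer, site) pair
#'
#' Convenience wrapper chaining the per-pair protocol: stratified 70/30
#' holdout of real samples, SMOTE balancing of the training split only,
#' blockwise consensus feature selection on the balanced training data,
#' model training on the selected candidates, and evaluation on the real
#' held-out samples.
#'
#' @param X numeric matrix of real samples (samples x transcripts).
#' @param labels named binary labels or a `progression_labels` object.
#' @param smote_cfg,selection_cfg,model_cfg stage configurations.
#' @param holdout_fraction held-out fraction (default 0.3).
#' @param seed split seed.
#' @param pair optional pair identifier for the report.
#' @return list with `split`, `balanced`, `candidates`, `model`, `report`.
#' @export
run_pair_analysis <- function(X, labels, smote_cfg = smote_config(),
                              selection_cfg = selection_config(),
                              model_cfg = site_model_config(),
                              holdout_fraction = 0.3, seed = 1, pair = NULL) {
  if (inherits(labels, "progression_labels")) {
    if (is.null(pair)) pair <- labels$pair
    labels <- labels$labels
  }
  y <- as_binary01(labels)
  ids <- names(y)
  stopifnot(!is.null(ids), all(ids %in% rownames(X)))
  split <- split_holdout(y, holdout_fraction, seed = seed)
  X_train <- X[split$train, , drop = FALSE]
  y_train <- y[split$train]
  balanced <- balance_dataset(X_train, y_train, smote_cfg)
  candidates <- select_candidates(balanced$X, balanced$y, selection_cfg)
  model <- train_site_model(balanced$X[, candidates$candidates, drop = FALSE],
                            balanced$y, model_cfg)
  report <- evaluate_binary(model, split,
                            X[, candidates$candidates, drop = FALSE],
                            y, pair = pair)
  list(split = split, balanced = balanced, candidates = candidates,
       model = model, report = report)
}
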