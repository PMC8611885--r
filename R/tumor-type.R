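# Multiclass classification of cancer type from transcriptomes: the first
# stage of the architecture. A gradient-boosted tree ensemble predicts a
# class and a posterior probability vector per sample.

#' Gradient-boosted tree configuration for the tumor-type stage
#'
#' @param nrounds boosting rounds.
#' @param max_depth tree depth.
#' @param eta learning rate.
#' @param seed integer seed.
#' @param nthread xgboost threads (1 for full determinism).
#' @return object of class `tumor_type_config`.
#' @export
tumor_type_config <- function(nrounds = 300, max_depth = 3, eta = 0.1,
                              seed = 1, nthread = 1) {
  stopifnot(nrounds >= 1, max_depth >= 1, eta > 0)
  structure(list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, seed = as.integer(seed),
                 nthread = as.integer(nthread)),
            class = "tumor_type_config")
}

#' Train the multiclass tumor-type classifier
#'
#' @param X numeric matrix (samples x transcripts).
#' @param cancer_labels character/factor cancer-type codes per sample (merge
#'   COAD/READ upstream with [merge_coadread_codes()] if desired).
#' @param cfg a [tumor_type_config()].
#' @return object of class `tumor_type_model`.
#' @export
train_tumor_type <- function(X, cancer_labels, cfg = tumor_type_config()) {
  stopifnot(inherits(cfg, "tumor_type_config"))
  y <- factor(cancer_labels)
  if (nlevels(y) < 2) stop("at least two classes required")
  tab <- table(y)
  small <- names(tab)[tab < 2]
  if (length(small))
    warning("classes with < 2 training samples (too small to model well): ",
            paste(small, collapse = ", "))
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = as.integer(y) - 1L)
  params <- list(objective = "multi:softprob", num_class = nlevels(y),
                 max_depth = cfg$max_depth, eta = cfg$eta,
                 nthread = cfg$nthread, seed = cfg$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = cfg$nrounds, verbose = 0)
  structure(list(booster = booster, classes = levels(y), config = cfg),
            class = "tumor_type_model")
}

#' Predict tumor type and class posteriors
#'
#' @param object a `tumor_type_model`.
#' @param newdata numeric matrix of samples to classify.
#' @param ... unused.
#' @return list with `class` (factor) and `prob` (matrix, rows summing to 1,
#'   columns named by class).
#' @export
predict.tumor_type_model <- function(object, newdata, ...) {
  prob <- predict(object$booster, xgboost::xgb.DMatrix(as.matrix(newdata)))
  prob <- matrix(prob, ncol = length(object$classes), byrow = FALSE)
  colnames(prob) <- object$classes
  rownames(prob) <- rownames(newdata)
  cls <- factor(object$classes[max.col(prob, ties.method = "first")],
                levels = object$classes)
  list(class = cls, prob = prob)
}

#' Compute multiclass metrics from a confusion matrix
#'
#' Per-class precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic
#' mean (0 when both are 0); macro averages are unweighted means over the
#' classes present in the test set. Classes absent from the test set are
#' excluded from the macro averages with a warning; a class never predicted
#' has undefined precision (`NaN`), also excluded from the macro mean.
#'
#' @param confusion square matrix of counts, true classes in rows and
#'   predicted classes in columns.
#' @return object of class `multiclass_report`: list with `confusion`,
#'   `per_class` (data.frame), and `macro` (named numeric).
#' @export
multiclass_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  k <- nrow(confusion)
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- as.character(seq_len(k))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  support <- rowSums(confusion)
  precision <- ifelse(tp + fp == 0, NaN, tp / (tp + fp))
  recall <- ifelse(support == 0, NaN, tp / (tp + fn))
  f1 <- ifelse(is.nan(precision) | is.nan(recall), NaN,
               ifelse(precision + recall == 0, 0,
                      2 * precision * recall / (precision + recall)))
  absent <- support == 0
  if (any(absent))
    warning("classes absent from the test set excluded from macro averages: ",
            paste(classes[absent], collapse = ", "))
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          stringsAsFactors = FALSE)
  keep <- !absent
  macro <- c(precision = mean(precision[keep], na.rm = TRUE),
             recall = mean(recall[keep], na.rm = TRUE),
             f1 = mean(f1[keep], na.rm = TRUE))
  structure(list(confusion = confusion, per_class = per_class, macro = macro),
            class = "multiclass_report")
}

#' Evaluate a tumor-type model on a held-out test set
#'
#' @param model a `tumor_type_model`.
#' @param X_test,y_test held-out samples and their true labels (must be
#'   disjoint from training).
#' @return a `multiclass_report`.
#' @export
evaluate_multiclass <- function(model, X_test, y_test) {
  pred <- predict(model, X_test)$class
  truth <- factor(as.character(y_test), levels = model$classes)
  confusion <- table(true = truth, predicted = pred)
  multiclass_metrics(unclass(as.matrix(confusion)))
}

#' @export
print.multiclass_report <- function(x, ...) {
  cat("Multiclass report over", nrow(x$confusion), "classes\n")
  cat(sprintf("Macro precision %.3f | recall %.3f | F1 %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  print(x$per_class, digits = 3)
  invisible(x)
}
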