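#' Leave-one-subject-out folds
#'
#' One fold per subject, in sorted subject order: the fold's test set is
#' exactly that subject's samples and its training set is everything else,
#' so no subject contributes to both sides of any fold.
#'
#' @param subjects Vector of per-sample subject identifiers.
#' @return List of folds, each `list(subject, train, test)` with integer
#'   row indices.
#' @export
loso_folds <- function(subjects) {
  ids <- sort(unique(subjects))
  if (length(ids) < 2) stop("LOSO requires at least 2 subjects")
  lapply(ids, function(s) {
    test <- which(subjects == s)
    list(subject = s, train = setdiff(seq_along(subjects), test), test = test)
  })
}

#' Standardise features with training statistics only
#'
#' Per-feature z-scoring using the training mean and (population) standard
#' deviation; the same statistics are applied to the test rows, so no
#' information flows from test to train. Features with zero training
#' standard deviation map to 0 in both sets.
#'
#' @param train Numeric training feature matrix.
#' @param test Optional test feature matrix (same columns).
#' @return `list(train, test, center, scale)`.
#' @export
standardize_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (!nrow(train)) stop("training set must be non-empty")
  mu <- colMeans(train)
  sd <- sqrt(colMeans(sweep(train, 2, mu)^2))
  scale_ <- ifelse(sd > 0, sd, 1)
  tr <- sweep(sweep(train, 2, mu), 2, scale_, "/")
  tr[, sd == 0] <- 0
  te <- NULL
  if (!is.null(test)) {
    te <- sweep(sweep(as.matrix(test), 2, mu), 2, scale_, "/")
    te[, sd == 0] <- 0
  }
  list(train = tr, test = te, center = mu, scale = sd)
}

#' Confusion matrix with fixed class levels
#'
#' @param true,predicted Label vectors.
#' @param levels Class levels fixing row/column order; default the sorted
#'   union of both vectors.
#' @return Integer matrix `counts[true, predicted]` of class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted, levels = NULL) {
  levels <- levels %||% sort(unique(c(as.character(true), as.character(predicted))))
  m <- table(true = factor(true, levels = levels),
             predicted = factor(predicted, levels = levels))
  structure(unclass(m), class = c("confusion_matrix", "matrix"))
}

#' Accuracy and class-averaged F1 of a confusion matrix
#'
#' Accuracy is `trace/total`. Per-class F1 is the harmonic mean of that
#' class's precision and recall (defined as 0 when precision + recall = 0);
#' the reported F1 is the unweighted (macro) mean over classes. Classes with
#' no true instances in the matrix are skipped in the macro average, which
#' matters only for per-fold metrics on incomplete test sets.
#'
#' @param confusion A `confusion_matrix` (or square counts matrix).
#' @return List with `accuracy`, `macro_f1`, and per-class `precision`,
#'   `recall`, `f1` vectors. All metrics are proportions in `[0, 1]`.
#' @export
classification_metrics <- function(confusion) {
  m <- unclass(as.matrix(confusion))
  if (!nrow(m) || sum(m) == 0) stop("confusion matrix must be non-empty")
  tp <- diag(m)
  prec <- ifelse(colSums(m) > 0, tp / colSums(m), 0)
  rec <- ifelse(rowSums(m) > 0, tp / rowSums(m), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(m) > 0
  list(accuracy = sum(tp) / sum(m),
       macro_f1 = mean(f1[present]),
       precision = prec, recall = rec, f1 = f1)
}

#' Collapse labels to the binary Fall / No Fall task
#'
#' @param labels Character or factor labels from the seven-class roster.
#' @return Factor with levels `Fall`, `No Fall`.
#' @export
binarize_labels <- function(labels) {
  factor(ifelse(as.character(labels) == "Fall", "Fall", "No Fall"),
         levels = c("Fall", "No Fall"))
}

#' Run leave-one-subject-out cross-validation
#'
#' For each fold: features are standardised with training statistics,
#' optionally restricted to a feature subset, the classifier is trained and
#' the held-out subject's events are predicted. Aggregate accuracy and
#' class-averaged F1 are the arithmetic means of the per-fold metrics;
#' confusion matrices are pooled (summed) over folds. When the classifier
#' is a decision tree, per-fold feature importances are collected for use
#' with [select_features()].
#'
#' @param data data.frame with columns `subject`, `label` and one column
#'   per feature (e.g. from [extract_study_features()]).
#' @param spec A [model_spec()].
#' @param task `"binary"` collapses labels to Fall / No Fall;
#'   `"multiclass"` keeps the seven classes.
#' @param feature_subset Optional character vector of feature names to use;
#'   `NULL` uses all features.
#' @return An object of class `loso_report`.
#' @export
run_loso <- function(data, spec, task = c("multiclass", "binary"),
                     feature_subset = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(spec, "model_spec"),
            all(c("subject", "label") %in% names(data)))
  feat_cols <- setdiff(names(data), c("subject", "label"))
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, feat_cols)
    if (length(missing))
      stop("unknown features in feature_subset: ",
           paste(missing, collapse = ", "))
    feat_cols <- feature_subset
  }
  x <- as.matrix(data[, feat_cols, drop = FALSE])
  y <- if (task == "binary") binarize_labels(data$label)
       else factor(data$label, levels = intersect(activity_classes(),
                                                  unique(data$label)))
  lev <- levels(y)
  folds <- loso_folds(data$subject)
  pooled <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  per_fold <- data.frame(subject = vapply(folds, `[[`, folds[[1]]$subject, "subject"),
                         accuracy = NA_real_, macro_f1 = NA_real_)
  importance <- if (spec$family == "decision_tree")
    matrix(NA_real_, length(folds), length(feat_cols),
           dimnames = list(NULL, feat_cols)) else NULL
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    std <- standardize_features(x[fold$train, , drop = FALSE],
                                x[fold$test, , drop = FALSE])
    model <- train_model(spec, std$train, y[fold$train])
    pred <- predict(model, std$test)
    cm <- confusion_matrix(y[fold$test], pred, levels = lev)
    met <- classification_metrics(cm)
    per_fold$accuracy[i] <- met$accuracy
    per_fold$macro_f1[i] <- met$macro_f1
    pooled <- pooled + unclass(cm)
    if (!is.null(importance))
      importance[i, ] <- dt_importance(model)
  }
  structure(list(task = task, spec = spec, features = feat_cols,
                 per_fold = per_fold,
                 accuracy = mean(per_fold$accuracy),
                 macro_f1 = mean(per_fold$macro_f1),
                 confusion = structure(pooled, class = c("confusion_matrix", "matrix")),
                 importance = importance, n = nrow(data)),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat(sprintf("LOSO evaluation (%s task, %s, %d features, %d events, %d folds)\n",
              x$task, x$spec$family, length(x$features), x$n,
              nrow(x$per_fold)))
  cat(sprintf("  accuracy: %.2f%%   class-averaged F1: %.2f%%\n",
              100 * x$accuracy, 100 * x$macro_f1))
  cat("Pooled confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x$confusion))
  invisible(x)
}

#' @export
summary.loso_report <- function(object, ...) {
  met <- classification_metrics(object$confusion)
  cat(sprintf("Per-fold accuracy: mean %.4f, range [%.4f, %.4f]\n",
              mean(object$per_fold$accuracy), min(object$per_fold$accuracy),
              max(object$per_fold$accuracy)))
  cat(sprintf("Per-fold macro F1: mean %.4f, range [%.4f, %.4f]\n",
              mean(object$per_fold$macro_f1), min(object$per_fold$macro_f1),
              max(object$per_fold$macro_f1)))
  cat("Pooled per-class recall:\n")
  print(round(met$recall, 4))
  invisible(object)
}

#' Decision-tree feature importance
#'
#' Importance of each predictor: the sum, over internal nodes that split on
#' the predictor, of the risk decrease `risk(node) - risk(left) -
#' risk(right)`, divided by the number of branch (internal) nodes. The risk
#' of a node is its probability times its Gini impurity. Features never
#' split on have importance 0; a stump-free tree (single leaf) yields all
#' zeros.
#'
#' @param model A fitted `fallsense_decision_tree` model from
#'   [train_model()].
#' @return Named numeric vector of importances (>= 0), one per training
#'   feature.
#' @export
dt_importance <- function(model) {
  if (!inherits(model, "fallsense_decision_tree"))
    stop("dt_importance requires a fitted decision tree")
  fit <- model$fit
  frame <- fit$frame
  imp <- stats::setNames(numeric(length(model$feature_names)),
                         model$feature_names)
  internal <- which(frame$var != "<leaf>")
  if (!length(internal)) return(imp)
  nodes <- as.integer(rownames(frame))
  K <- length(attr(fit, "ylevels"))
  probs <- frame$yval2[, (K + 2):(2 * K + 1), drop = FALSE]
  nodeprob <- frame$yval2[, 2 * K + 2]
  risk <- nodeprob * (1 - rowSums(probs^2))
  for (i in internal) {
    kids <- match(c(2L * nodes[i], 2L * nodes[i] + 1L), nodes)
    drop_ <- risk[i] - sum(risk[kids])
    v <- as.character(frame$var[i])
    imp[v] <- imp[v] + drop_
  }
  imp / length(internal)
}

#' Select features by mean decision-tree importance
#'
#' Averages per-fold importances and keeps the features whose mean
#' importance is strictly greater than the threshold.
#'
#' @param importance Per-fold importance matrix (folds x features), e.g.
#'   the `importance` field of a decision-tree [run_loso()] report.
#' @param threshold Strict lower bound on the mean importance.
#'   Default 0.0002.
#' @return Character vector of selected feature names (in feature order).
#' @export
select_features <- function(importance, threshold = 0.0002) {
  importance <- as.matrix(importance)
  if (!nrow(importance)) stop("importance must contain at least one fold")
  means <- colMeans(importance)
  names(means)[means > threshold]
}

#' Reference 13-feature subset
#'
#' The curated subset of 13 features that the decision-tree importance
#' screening selects under the full chest-accelerometer study design:
#' shipped as a named preset so the reduced feature set can be evaluated
#' directly, independent of any selection run.
#'
#' @return Character vector of 13 feature names.
#' @export
selected_feature_preset <- function() {
  c("mean.x", "mean.z", "rms.x", "rms.z", "sd.z", "skew.z", "kurt.z",
    "acf_peak2_pos.y",
    "psd_peak1_amp.x", "psd_peak2_amp.x", "psd_peak3_pos.z",
    "bandpower_0.5_5.z", "bandpower_5_10.z")
}
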