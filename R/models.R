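#' Classifier specification
#'
#' Describes one member of the classifier suite: k-nearest neighbours
#' (k in 1, 3, 5, 7 in the study grid), linear SVM, RBF SVM, linear
#' discriminant analysis, or a CART decision tree. LDA and the tree use
#' empirical class frequencies as priors; SVM hyperparameters default to
#' cost 1 and kernel width `1/d` on standardised inputs (`d` = number of
#' features).
#'
#' @param family One of `"knn"`, `"linear_svm"`, `"rbf_svm"`, `"lda"`,
#'   `"decision_tree"`.
#' @param k Neighbour count for kNN; must be a positive odd integer
#'   (study grid: 1, 3, 5, 7). Default 5.
#' @param cost SVM regularisation constant. Default 1.
#' @param gamma RBF kernel width; `NULL` means `1/d` at training time.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("knn", "linear_svm", "rbf_svm", "lda",
                                  "decision_tree"),
                       k = 5L, cost = 1, gamma = NULL) {
  family <- match.arg(family)
  if (family == "knn") {
    k <- as.integer(k)
    if (k < 1 || k %% 2 == 0) stop("knn requires a positive odd k")
  }
  structure(list(family = family, k = k, cost = cost, gamma = gamma),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  extra <- switch(x$family,
                  knn = sprintf(" (k = %d)", x$k),
                  linear_svm = ,
                  rbf_svm = sprintf(" (cost = %g, gamma = %s)", x$cost,
                                    if (is.null(x$gamma)) "1/d" else format(x$gamma)),
                  "")
  cat("Model spec: ", x$family, extra, "\n", sep = "")
  invisible(x)
}

check_training_input <- function(x, y) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("features must be finite numeric values")
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("training set must contain at least 2 classes")
  list(x = x, y = droplevels(y))
}

#' Train one classifier
#'
#' Fits the classifier described by `spec` on a feature matrix. SVM
#' specifications with more than two classes are automatically wrapped in a
#' one-vs-one ECOC ensemble (see [train_ecoc()]). All fits are
#' deterministic given the training data.
#'
#' @param spec A [model_spec()].
#' @param x Numeric feature matrix (rows = events); standardise first when
#'   features are on different scales (see [standardize_features()]).
#' @param y Class labels (factor or character).
#' @return A fitted model of class `fallsense_model` (subclass per family)
#'   or `fallsense_ecoc`, with a `predict()` method.
#' @export
train_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  inp <- check_training_input(x, y)
  x <- inp$x; y <- inp$y
  if (spec$family %in% c("linear_svm", "rbf_svm") && nlevels(y) > 2)
    return(train_ecoc(spec, x, y))
  fit <- switch(spec$family,
    knn = list(x = x, y = y),
    lda = fit_lda(x, y),
    decision_tree = fit_tree(x, y),
    linear_svm = ,
    rbf_svm = fit_svm(spec, x, y))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 d = ncol(x), feature_names = colnames(x)),
            class = c(paste0("fallsense_", spec$family), "fallsense_model"))
}

fit_svm <- function(spec, x, y) {
  e1071::svm(x, y, kernel = if (spec$family == "linear_svm") "linear" else "radial",
             cost = spec$cost, gamma = spec$gamma %||% (1 / ncol(x)),
             scale = FALSE)
}

# LDA with pooled within-class covariance and a small ridge
# (1e-8 * mean diagonal) so collinear or constant columns are tolerated.
fit_lda <- function(x, y) {
  lev <- levels(y)
  n <- nrow(x); d <- ncol(x); K <- length(lev)
  means <- t(vapply(lev, function(l) colMeans(x[y == l, , drop = FALSE]),
                    numeric(d)))
  W <- matrix(0, d, d)
  for (l in lev) {
    xc <- sweep(x[y == l, , drop = FALSE], 2, means[l, ])
    W <- W + crossprod(xc)
  }
  W <- W / max(1, n - K)
  ridge <- 1e-8 * max(mean(diag(W)), .Machine$double.eps)
  Winv <- solve(W + diag(ridge, d))
  list(means = means, Winv = Winv,
       log_prior = log(as.numeric(table(y)[lev]) / n))
}

fit_tree <- function(x, y) {
  df <- data.frame(x, check.names = FALSE)
  df$.label <- y
  rpart::rpart(.label ~ ., data = df, method = "class",
               parms = list(split = "gini"),
               control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                              cp = 0, xval = 0, maxdepth = 30))
}

check_predict_input <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop("feature dimensionality (", ncol(newdata),
         ") does not match training (", object$d, ")")
  newdata
}

#' @export
predict.fallsense_model <- function(object, newdata, ...) {
  newdata <- check_predict_input(object, newdata)
  pred <- switch(object$spec$family,
    knn = predict_knn(object, newdata),
    lda = predict_lda(object, newdata),
    decision_tree = {
      df <- data.frame(newdata, check.names = FALSE)
      colnames(df) <- object$feature_names
      as.character(predict(object$fit, df, type = "class"))
    },
    linear_svm = ,
    rbf_svm = as.character(predict(object$fit, newdata)))
  factor(pred, levels = object$levels)
}

# deterministic kNN: Euclidean distance, distance ties resolved by the
# lowest training index (stable order()), vote ties by the nearest
# neighbour whose class is among the tied classes
predict_knn <- function(object, newdata) {
  xtr <- object$fit$x; ytr <- object$fit$y; k <- object$spec$k
  apply(newdata, 1, function(q) {
    d2 <- colSums((t(xtr) - q)^2)
    ord <- order(d2)               # stable: ties keep training order
    nn <- ytr[ord[seq_len(min(k, length(ord)))]]
    tab <- table(nn)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1) return(winners)
    as.character(nn[match(TRUE, as.character(nn) %in% winners)])
  })
}

predict_lda <- function(object, newdata) {
  f <- object$fit
  disc <- newdata %*% f$Winv %*% t(f$means)
  offs <- -0.5 * rowSums((f$means %*% f$Winv) * f$means) + f$log_prior
  scores <- sweep(disc, 2, offs, "+")
  object$levels[max.col(scores, ties.method = "first")]
}

#' @export
print.fallsense_model <- function(x, ...) {
  cat("Fitted", x$spec$family, "classifier:", length(x$levels), "classes,",
      x$d, "features\n")
  invisible(x)
}

#' Train a one-vs-one ECOC ensemble
#'
#' Error-correcting output codes with the one-versus-one coding design:
#' one binary base classifier per unordered class pair (`K*(K-1)/2` models
#' for `K` classes), each trained only on that pair's samples. Decoding is
#' by pairwise majority vote; ties are broken by the largest sum of signed
#' decision margins over the tied classes, then by the smallest class index.
#'
#' @param spec A [model_spec()] with family `"linear_svm"` or `"rbf_svm"`.
#' @param x Numeric feature matrix.
#' @param y Class labels (>= 2 classes).
#' @return An object of class `fallsense_ecoc`.
#' @export
train_ecoc <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$family %in% c("linear_svm", "rbf_svm"))
    stop("ECOC base learners must be linear_svm or rbf_svm")
  inp <- check_training_input(x, y)
  x <- inp$x; y <- inp$y
  lev <- levels(y)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    fit_svm(spec, x[sel, , drop = FALSE], factor(y[sel], levels = pr))
  })
  structure(list(spec = spec, pairs = pairs, models = models, levels = lev,
                 d = ncol(x), feature_names = colnames(x)),
            class = "fallsense_ecoc")
}

#' @export
predict.fallsense_ecoc <- function(object, newdata, ...) {
  newdata <- check_predict_input(object, newdata)
  lev <- object$levels
  n <- nrow(newdata)
  votes <- margin <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  for (m in seq_along(object$models)) {
    pr <- object$pairs[[m]]
    p <- predict(object$models[[m]], newdata, decision.values = TRUE)
    dv <- as.numeric(attr(p, "decision.values"))
    # e1071 labels the decision value "first/second": positive favours pr[1]
    if (colnames(attr(p, "decision.values"))[1] != paste(pr[1], pr[2], sep = "/"))
      dv <- -dv
    won <- ifelse(as.character(p) == pr[1], 1L, 2L)
    votes[cbind(seq_len(n), match(pr[won], lev))] <-
      votes[cbind(seq_len(n), match(pr[won], lev))] + 1
    margin[, pr[1]] <- margin[, pr[1]] + dv
    margin[, pr[2]] <- margin[, pr[2]] - dv
  }
  out <- vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      best <- top[margin[i, top] == max(margin[i, top])]
      top <- best
    }
    lev[min(top)]
  }, "")
  factor(out, levels = lev)
}

#' @export
print.fallsense_ecoc <- function(x, ...) {
  cat("One-vs-one ECOC ensemble:", length(x$models), x$spec$family,
      "base models over", length(x$levels), "classes\n")
  invisible(x)
}
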