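test_that("LOSO folds partition the dataset by subject", {
  subjects <- rep(c(3, 1, 2), times = c(4, 5, 6))
  folds <- loso_folds(subjects)
  expect_length(folds, 3)
  expect_equal(vapply(folds, `[[`, 1, "subject"), c(1, 2, 3))
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(all_test, seq_along(subjects))          # covers exactly once
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), seq_along(subjects))
    expect_equal(unique(subjects[f$test]), f$subject)  # one subject per fold
    expect_false(f$subject %in% subjects[f$train])     # no leakage
  }
  expect_error(loso_folds(rep(1, 5)), "2 subjects")
})

test_that("standardisation uses training statistics only", {
  train <- matrix(c(0, 2, 5, 5), 2, 2, dimnames = list(NULL, c("a", "b")))
  test <- matrix(c(1, 3, 7, 9), 2, 2, dimnames = list(NULL, c("a", "b")))
  std <- standardize_features(train, test)
  expect_equal(colMeans(std$train), c(a = 0, b = 0))
  expect_equal(sqrt(colMeans(std$train^2))[["a"]], 1)  # population sd 1
  expect_equal(std$train[, "b"], c(0, 0))              # constant -> all zero
  expect_equal(std$test[, "b"], c(0, 0))
  expect_equal(unname(std$test[1, "a"]), 0)            # (1 - 1) / 1
  # test values cannot influence the transform
  std2 <- standardize_features(train, test * 100)
  expect_identical(std$center, std2$center)
  expect_identical(std$scale, std2$scale)
  expect_identical(std$train, std2$train)
})

test_that("metrics agree with a brute-force precision/recall computation", {
  set.seed(14)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    m <- matrix(stats::rpois(K * K, 8), K, K,
                dimnames = list(LETTERS[1:K], LETTERS[1:K]))
    got <- classification_metrics(m)
    want <- brute_metrics(m)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$macro_f1, want$macro_f1, tolerance = 1e-12)
    expect_equal(unname(got$f1), want$f1, tolerance = 1e-12)
  }
  perfect <- diag(5) * 10
  got <- classification_metrics(perfect)
  expect_equal(got$accuracy, 1)
  expect_equal(got$macro_f1, 1)
})

test_that("a constant majority classifier on a 315/210 split scores 60% / 37.5%", {
  cm <- confusion_matrix(true = rep(c("Fall", "No Fall"), c(315, 210)),
                         predicted = rep("Fall", 525),
                         levels = c("Fall", "No Fall"))
  met <- classification_metrics(cm)
  expect_equal(met$accuracy, 0.60)
  expect_equal(met$macro_f1, 0.375)
})

test_that("decision-tree importance is risk decrease per branch node", {
  # balanced binary data split perfectly by feature 1:
  # root risk = 1 * 0.5, children pure -> importance 0.5 for f1, 0 elsewhere
  x <- matrix(c(rep(0, 20), rep(1, 20), stats::rnorm(40)), 40, 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("A", "B"), each = 20)
  m <- train_model(model_spec("decision_tree"), x, y)
  imp <- dt_importance(m)
  expect_equal(imp[["f1"]], 0.5, tolerance = 1e-12)
  expect_equal(imp[["f2"]], 0)
  expect_true(all(imp >= 0))
  set.seed(15)
  x2 <- matrix(stats::rnorm(200), 50, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  y2 <- factor(ifelse(x2[, 2] > 0, "A", "B"))
  imp2 <- dt_importance(train_model(model_spec("decision_tree"), x2, y2))
  expect_true(all(imp2 >= 0))
  m_lda <- train_model(model_spec("lda"), x2, y2)
  expect_error(dt_importance(m_lda), "decision tree")
})

test_that("feature selection applies a strict mean-importance threshold", {
  imp <- rbind(c(a = 0.001, b = 0.0001, c = 0.00021),
               c(a = 0.001, b = 0.0001, c = 0.00021))
  expect_equal(select_features(imp), c("a", "c"))
  exact <- rbind(c(a = 0.0002, b = 0.001))
  expect_equal(select_features(exact), "b")         # exactly 0.0002 excluded
  expect_equal(select_features(rbind(c(a = 0, b = 0))), character(0))
  expect_length(selected_feature_preset(), 13)
  expect_true(all(selected_feature_preset() %in% feature_names()))
})

test_that("run_loso with all features named is identical to the default", {
  feats <- tiny_study_features()
  spec <- model_spec("knn", k = 5)
  r1 <- run_loso(feats, spec, task = "binary")
  r2 <- run_loso(feats, spec, task = "binary",
                 feature_subset = setdiff(names(feats), c("subject", "label")))
  expect_equal(r1$accuracy, r2$accuracy)
  expect_identical(unclass(r1$confusion), unclass(r2$confusion))
  expect_error(run_loso(feats, spec, feature_subset = "nope"), "unknown feature")
})

test_that("run_loso is reproducible and its report is self-consistent", {
  feats <- tiny_study_features()
  r1 <- run_loso(feats, model_spec("lda"), task = "multiclass")
  r2 <- run_loso(feats, model_spec("lda"), task = "multiclass")
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(unclass(r1$confusion), unclass(r2$confusion))
  expect_equal(sum(r1$confusion), nrow(feats))      # pooled total = dataset size
  expect_equal(r1$accuracy, mean(r1$per_fold$accuracy))
  expect_true(all(r1$per_fold$accuracy >= 0 & r1$per_fold$accuracy <= 1))
  expect_output(print(r1), "LOSO evaluation")
})

test_that("permuting labels collapses accuracy to the chance band", {
  feats <- tiny_study_features()
  set.seed(77)
  feats$label <- sample(feats$label)
  r <- run_loso(feats, model_spec("linear_svm"), task = "binary")
  expect_gte(r$accuracy, 0.35)
  expect_lte(r$accuracy, 0.75)
})

test_that("importance screening recovers planted informative features", {
  # three complementary informative features: each marks its own subgroup of
  # fall events, so a full recovery needs all three splits
  recovered <- 0
  for (s in 1:10) {
    df <- planted_signal_dataset(seed = 1000 + s)
    rep_ <- run_loso(df, model_spec("decision_tree"), task = "binary")
    sel <- select_features(rep_$importance, 0.0002)
    if (all(attr(df, "informative") %in% sel) && length(sel) <= 3 + 7)
      recovered <- recovered + 1
  }
  expect_gte(recovered, 9)
})
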