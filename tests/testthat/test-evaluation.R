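test_that("splits have the derived test size and are reproducible", {
  y <- rep(c("a", "b"), 50)
  sp <- split_data(y, ratio = 0.8, seed = 1)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_setequal(c(sp$train, sp$test), 1:100)
  sp2 <- split_data(y, ratio = 0.8, seed = 1)
  expect_identical(sp$test, sp2$test)
  expect_false(identical(sp$test, split_data(y, ratio = 0.8, seed = 2)$test))
})

test_that("stratified splits preserve class proportions within one sample", {
  set.seed(3)
  for (seed in 1:4) {
    y <- sample(rep(c("a", "b"), c(37, 64)))
    sp <- split_data(y, ratio = 0.8, seed = seed)
    tab_all <- table(y) / length(y)
    tab_test <- table(y[sp$test])
    expect_true(all(abs(tab_test - tab_all * length(sp$test)) <= 1))
  }
  expect_error(split_data(c("a", "b", "b"), ratio = 0.5), "at least 2")
})

test_that("metrics derive exactly from the confusion matrix", {
  conf <- matrix(c(40, 10, 5, 45), 2, 2, byrow = TRUE,
                 dimnames = list(c("neg", "pos"), c("neg", "pos")))
  m <- metrics_from_confusion(conf)
  expect_equal(m$accuracy, 85 / 100)
  # recompute every metric independently from the counts
  prec <- c(40 / 45, 45 / 55); rec <- c(40 / 50, 45 / 50)
  f1 <- 2 * prec * rec / (prec + rec)
  w <- c(0.5, 0.5)  # balanced support
  expect_equal(m$precision, sum(w * prec), tolerance = 1e-12)
  expect_equal(m$recall, sum(w * rec), tolerance = 1e-12)
  expect_equal(m$f1, sum(w * f1), tolerance = 1e-12)
})

test_that("balanced symmetric confusion makes all weighted metrics equal accuracy", {
  conf <- matrix(c(90, 10, 10, 90), 2, 2)
  m <- metrics_from_confusion(conf)
  expect_equal(m$precision, m$accuracy, tolerance = 1e-12)
  expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
  expect_equal(m$f1, m$accuracy, tolerance = 1e-12)
})

test_that("the printed large-corpus count pairs give the published accuracies", {
  # 43,021 correct of 46,316 predictions
  conf <- matrix(c(21511, 1697, 1598, 21510), 2, 2, byrow = TRUE)
  expect_equal(sum(conf), 46316)
  expect_equal(sum(diag(conf)), 43021)
  acc <- metrics_from_confusion(conf)$accuracy
  expect_equal(round(acc, 4), 0.9289)
  expect_equal(round(acc, 2), 0.93)
  # 44,238 correct of 46,316
  conf2 <- matrix(c(22119, 1039, 1039, 22119), 2, 2, byrow = TRUE)
  expect_equal(sum(diag(conf2)), 44238)
  expect_equal(round(metrics_from_confusion(conf2)$accuracy, 4), 0.9551)
  expect_equal(round(metrics_from_confusion(conf2)$accuracy, 2), 0.96)
})

test_that("evaluate reports a consistent confusion matrix and perfect-case metrics", {
  co <- small_synth(n = 120, separability = 1, seed = 2)
  X <- as.matrix(tfidf(co))
  sp <- split_data(co$label, 0.8, seed = 1)
  fit <- fit_model(X[sp$train, ], co$label[sp$train], model_config("SVM"))
  rep <- evaluate(fit, X[sp$test, ], co$label[sp$test])
  expect_equal(sum(rep$confusion), rep$n_test)
  m2 <- metrics_from_confusion(rep$confusion, rep$averaging)
  for (k in c("accuracy", "precision", "recall", "f1")) {
    expect_equal(rep[[k]], m2[[k]], tolerance = 1e-12)
  }
  # disjoint class vocabularies: the linear SVM is perfect here
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$f1, 1.0)
  expect_gte(rep$predict_time, 0)
  expect_error(evaluate(fit, X[0, , drop = FALSE], character(0)), "empty test set")
})

test_that("tidy and glance views expose the metrics", {
  co <- small_synth(n = 80, seed = 2)
  X <- as.matrix(tfidf(co))
  fit <- fit_model(X, co$label, model_config("LR"))
  rep <- evaluate(fit, X, co$label)
  td <- tidy(rep)
  expect_equal(td$metric, c("accuracy", "precision", "recall", "f1"))
  expect_true(all(td$value >= 0 & td$value <= 1))
  gl <- glance(rep)
  expect_equal(gl$model, "LR")
  expect_equal(gl$accuracy, rep$accuracy)
})

test_that("cross-validation partitions rows and summarises fold accuracies", {
  co <- small_synth(n = 90, separability = 1, seed = 5)
  X <- as.matrix(tfidf(co))
  cv <- cross_validate(X, co$label, model_config("KNN"), n_folds = 5, seed = 1)
  expect_length(cv$fold_scores, 5L)
  expect_gte(cv$mean, min(cv$fold_scores))
  expect_lte(cv$mean, max(cv$fold_scores))
  # disjoint vocabularies: every fold is perfect, so sd is exactly 0
  expect_equal(cv$sd, 0)
  expect_error(cross_validate(X, co$label, model_config("KNN"), n_folds = 1),
               "at least 2")
  expect_error(cross_validate(X, co$label, model_config("KNN"), n_folds = 91),
               "exceeds")
})

test_that("benchmark emits one labelled row per cell and survives cell failure", {
  co <- small_synth(n = 100, seed = 7)
  y <- co$label
  fs <- list(tfidf = tfidf(co),
             probfs = probfs_features(generate_probfs(tfidf(co), y, seed = 1)))
  tb <- benchmark(fs, y, list(model_config("LR"), model_config("KNN")),
                  ratio = 0.8, seed = 1)
  expect_equal(nrow(tb), 4L)
  expect_setequal(unique(tb$feature_set), c("tfidf", "probfs"))
  expect_setequal(unique(tb$model), c("LR", "KNN"))
  expect_true(all(tb$accuracy >= 0 & tb$accuracy <= 1))
  expect_true(all(tb$fit_time >= 0))
  # a broken feature set yields an NA row, not an error
  bad <- fs
  bad$broken <- feature_matrix(matrix(NaN, 100, 2), provenance = "bow")
  expect_warning(
    tb2 <- benchmark(bad, y, list(model_config("LR")), ratio = 0.8, seed = 1),
    "failed"
  )
  expect_true(is.na(tb2$accuracy[tb2$feature_set == "broken"]))
  expect_false(anyNA(tb2$accuracy[tb2$feature_set != "broken"]))
})

test_that("probfs evaluation is cheaper to predict than full tf-idf", {
  co <- small_synth(n = 300, seed = 9)
  y <- co$label
  Xt <- as.matrix(tfidf(co))
  Xp <- as.matrix(probfs_features(generate_probfs(tfidf(co), y, seed = 1)))
  expect_lt(ncol(Xp), ncol(Xt))  # 4 columns versus the full vocabulary
})
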