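# Evaluation harness: stratified splitting, confusion-matrix metrics,
# k-fold cross-validation and a feature-set x model benchmark table.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Train/test split
#'
#' Reproducible split of `n` rows with test size `round(n * (1 - ratio))`.
#' Under stratification the test-set class counts are apportioned by
#' largest remainder, so class proportions are preserved within one sample.
#'
#' @param labels label vector (used for stratification and to define `n`).
#' @param ratio training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @param stratify preserve class proportions (default TRUE).
#' @return an object of class `split_spec` with `train` and `test` index
#'   vectors.
#' @export
split_data <- function(labels, ratio = 0.8, seed = 0L, stratify = TRUE) {
  stopifnot(ratio > 0, ratio < 1)
  n <- length(labels)
  n_test <- round(n * (1 - ratio))
  test <- .with_seed(seed, {
    if (stratify) {
      y <- factor(labels)
      counts <- table(y)
      if (any(counts < 2L)) {
        abort("every class needs at least 2 members for a stratified split")
      }
      exact <- n_test * as.numeric(counts) / n
      take <- floor(exact)
      rem <- n_test - sum(take)
      if (rem > 0L) {
        extra <- order(-(exact - take))[seq_len(rem)]
        take[extra] <- take[extra] + 1L
      }
      unlist(lapply(seq_along(levels(y)), function(k) {
        idx <- which(y == levels(y)[k])
        sample(idx, take[k])
      }), use.names = FALSE)
    } else {
      sample.int(n, n_test)
    }
  })
  test <- sort(test)
  structure(
    list(train = setdiff(seq_len(n), test), test = test,
         ratio = ratio, seed = seed, stratified = stratify),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec> ", length(x$train), " train / ", length(x$test),
      " test (ratio ", x$ratio, if (x$stratified) ", stratified" else "",
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Metrics from a 2x2 confusion matrix
#'
#' Computes accuracy, precision, recall and F1 from a confusion matrix with
#' actual classes in rows and predicted classes in columns. `"weighted"`
#' averaging weights per-class scores by class support; `"macro"` averages
#' them unweighted. On a balanced test set with symmetric errors all four
#' weighted metrics coincide.
#'
#' @param confusion 2x2 numeric matrix, rows = actual, columns = predicted,
#'   both in the same class order.
#' @param averaging `"weighted"` or `"macro"`.
#' @return a list with `accuracy`, `precision`, `recall`, `f1` and a
#'   `per_class` tibble.
#' @export
metrics_from_confusion <- function(confusion, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  stopifnot(is.matrix(confusion), all(dim(confusion) == 2L), all(confusion >= 0))
  total <- sum(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  prec <- ifelse(predicted > 0, diag(confusion) / predicted, 0)
  rec <- ifelse(support > 0, diag(confusion) / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- if (averaging == "weighted") support / total else rep(0.5, 2L)
  list(
    accuracy = sum(diag(confusion)) / total,
    precision = sum(w * prec),
    recall = sum(w * rec),
    f1 = sum(w * f1),
    per_class = tibble(
      class = rownames(confusion) %||% c("class1", "class2"),
      support = as.numeric(support),
      precision = as.numeric(prec),
      recall = as.numeric(rec),
      f1 = as.numeric(f1)
    )
  )
}

#' Evaluate a fitted model on a test set
#'
#' Predicts the test documents (timing the prediction), tabulates the 2x2
#' confusion matrix (actual in rows, predicted in columns, sorted class
#' order) and derives accuracy, precision, recall and F1 from it.
#'
#' @param object a [fit_model()] result.
#' @param X_test feature matrix of test documents.
#' @param y_test their true labels.
#' @param averaging `"weighted"` (default) or `"macro"`.
#' @return an object of class `eval_report`.
#' @export
evaluate <- function(object, X_test, y_test, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  if (length(y_test) == 0L) abort("empty test set")
  stopifnot(nrow(.as_dense(X_test)) == length(y_test))
  t0 <- proc.time()["elapsed"]
  pred <- predict(object, X_test, type = "class")
  predict_time <- unname(proc.time()["elapsed"] - t0)
  cls <- object$class_order
  confusion <- as.matrix(table(
    actual = factor(y_test, levels = cls),
    predicted = factor(pred, levels = cls)
  ))
  m <- metrics_from_confusion(confusion, averaging)
  structure(
    c(m, list(confusion = confusion, averaging = averaging,
              n_test = length(y_test), model = object$config$name,
              fit_time = object$fit_time, predict_time = predict_time)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$model, " on ", x$n_test, " test documents\n", sep = "")
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f (%s)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$averaging))
  cat("  confusion (actual x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(
    metric = c("accuracy", "precision", "recall", "f1"),
    value = c(x$accuracy, x$precision, x$recall, x$f1),
    averaging = x$averaging
  )
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    model = x$model, n_test = x$n_test,
    accuracy = x$accuracy, precision = x$precision,
    recall = x$recall, f1 = x$f1,
    fit_time = x$fit_time %||% NA_real_, predict_time = x$predict_time
  )
}

# stratified fold assignment, one fold id per row
.fold_ids <- function(labels, n_folds, seed) {
  y <- factor(labels)
  folds <- integer(length(y))
  .with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' K-fold cross-validation
#'
#' Stratified k-fold cross-validation of one model configuration; reports
#' the per-fold accuracy and its mean and standard deviation.
#'
#' @param X feature matrix.
#' @param labels binary labels.
#' @param config a [model_config()].
#' @param n_folds number of folds (>= 2, <= number of rows).
#' @param seed seed for the fold partition.
#' @return an object of class `cv_report` with `fold_scores`, `mean`, `sd`.
#' @export
cross_validate <- function(X, labels, config, n_folds = 10L, seed = 0L) {
  n <- length(labels)
  if (n_folds < 2L) abort("n_folds must be at least 2")
  if (n_folds > n) abort("n_folds exceeds the number of documents")
  Xd <- .as_dense(X)
  folds <- .fold_ids(labels, n_folds, seed)
  scores <- vapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    fit <- fit_model(Xd[tr, , drop = FALSE], labels[tr], config)
    mean(predict(fit, Xd[!tr, , drop = FALSE]) == labels[!tr])
  }, numeric(1L))
  structure(
    list(fold_scores = scores, mean = mean(scores), sd = sd(scores),
         n_folds = n_folds, model = config$name, seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$model, ", ", x$n_folds, "-fold: mean accuracy ",
      sprintf("%.4f +/- %.4f", x$mean, x$sd), "\n", sep = "")
  invisible(x)
}

#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  tibble(fold = seq_along(x$fold_scores), accuracy = x$fold_scores)
}

#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(model = x$model, n_folds = x$n_folds, mean = x$mean, sd = x$sd)
}

#' Benchmark feature sets against models
#'
#' Fits and evaluates every (feature set, model) pair on a shared
#' train/test split and returns a tidy table of metrics and timings. A
#' failing cell is recorded with NA metrics and a warning rather than
#' aborting the whole grid.
#'
#' @param feature_sets named list of `feature_matrix` objects sharing row
#'   order.
#' @param labels labels aligned with the rows.
#' @param configs list of [model_config()] objects.
#' @param split a [split_data()] result; built from `ratio`/`seed` when NULL.
#' @param ratio,seed used when `split` is NULL.
#' @param averaging metric averaging, `"weighted"` or `"macro"`.
#' @return a tibble (class `benchmark_tbl`) with one row per cell:
#'   `feature_set`, `model`, `accuracy`, `precision`, `recall`, `f1`,
#'   `fit_time`, `predict_time`.
#' @export
benchmark <- function(feature_sets, labels, configs, split = NULL,
                      ratio = 0.8, seed = 0L,
                      averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  stopifnot(length(feature_sets) > 0L, length(configs) > 0L)
  if (is.null(names(feature_sets))) {
    names(feature_sets) <- vapply(feature_sets, provenance, character(1L))
  }
  if (is.null(split)) split <- split_data(labels, ratio = ratio, seed = seed)
  rows <- list()
  for (fs_name in names(feature_sets)) {
    Xd <- .as_dense(feature_sets[[fs_name]])
    for (cfg in configs) {
      row <- tryCatch({
        fit <- fit_model(Xd[split$train, , drop = FALSE],
                         labels[split$train], cfg)
        rep <- evaluate(fit, Xd[split$test, , drop = FALSE],
                        labels[split$test], averaging)
        tibble(feature_set = fs_name, model = cfg$name,
               accuracy = rep$accuracy, precision = rep$precision,
               recall = rep$recall, f1 = rep$f1,
               fit_time = fit$fit_time, predict_time = rep$predict_time)
      }, error = function(e) {
        warn(paste0("benchmark cell ", fs_name, " x ", cfg$name,
                    " failed: ", conditionMessage(e)))
        tibble(feature_set = fs_name, model = cfg$name,
               accuracy = NA_real_, precision = NA_real_,
               recall = NA_real_, f1 = NA_real_,
               fit_time = NA_real_, predict_time = NA_real_)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("benchmark_tbl", class(out))
  out
}
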