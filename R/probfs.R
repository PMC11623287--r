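# ProBFS: the probability-based feature set. TF-IDF features are fed to a
# linear SVM and a logistic regression; their per-class probabilities for
# every document are concatenated into a compact 4-column representation
# [P1, P2, P3, P4] = [SVM class probabilities, LR class probabilities],
# columns within each pair following the sorted label order.

.probfs_tbl <- function(p_svm, p_lr, row_ids, mode, class_order) {
  out <- tibble(
    row_id = row_ids,
    P1 = as.numeric(p_svm[, 1L]), P2 = as.numeric(p_svm[, 2L]),
    P3 = as.numeric(p_lr[, 1L]), P4 = as.numeric(p_lr[, 2L])
  )
  class(out) <- c("probfs_tbl", class(out))
  attr(out, "mode") <- mode
  attr(out, "class_order") <- class_order
  out
}

#' Generate the probability-based feature set (full-fit mode)
#'
#' Fits the two base learners (linear SVM and logistic regression) on the
#' TF-IDF features of *all* documents and emits their predicted class
#' probabilities for those same documents as four new features. This is the
#' faithful procedure; note that when the output later feeds a train/test
#' evaluation, the base learners have already seen the test labels, which
#' inflates downstream scores. Use [generate_probfs_oof()] for a
#' leakage-safe variant.
#'
#' @param X a `feature_matrix` of TF-IDF features (a different provenance
#'   triggers a warning, not an error).
#' @param labels binary labels aligned with rows.
#' @param svm_config,lr_config base-learner configurations; defaults are the
#'   tuned linear SVM (C = 2) and liblinear-style LR (C = 2).
#' @param seed integer seed forwarded to both base learners.
#' @return a tibble of class `probfs_tbl` with columns `row_id`,
#'   `P1`..`P4`; `P1 + P2 == 1` and `P3 + P4 == 1` per row. The fitted base
#'   learners are attached as attribute `"bundle"` (see [probfs_bundle()]).
#' @export
generate_probfs <- function(X, labels,
                            svm_config = model_config("SVM"),
                            lr_config = model_config("LR"),
                            seed = 0L) {
  if (inherits(X, "feature_matrix") && !identical(X$provenance, "tfidf")) {
    warn(paste0("ProBFS is defined over TF-IDF features; input provenance is '",
                X$provenance, "'"))
  }
  y <- .binary_labels(labels)
  if (nlevels(droplevels(y)) != 2L) {
    abort("ProBFS requires exactly two label values")
  }
  Xd <- .as_dense(X)
  svm_config$seed <- as.integer(seed)
  lr_config$seed <- as.integer(seed)
  svm_fit <- fit_model(Xd, y, svm_config)
  lr_fit <- fit_model(Xd, y, lr_config)
  bundle <- structure(
    list(svm = svm_fit, lr = lr_fit, n_features = ncol(Xd),
         class_order = svm_fit$class_order, seed = as.integer(seed)),
    class = "base_learner_bundle"
  )
  out <- .probfs_tbl(
    predict_proba(svm_fit, Xd), predict_proba(lr_fit, Xd),
    row_ids = rownames(Xd) %||% as.character(seq_len(nrow(Xd))),
    mode = "full_fit", class_order = bundle$class_order
  )
  attr(out, "bundle") <- bundle
  out
}

#' Leakage-safe ProBFS via out-of-fold prediction
#'
#' Each document's four probabilities come from base learners fitted on the
#' folds that exclude it, so no document's own label reaches the features
#' that describe it. Same shape and simplex invariants as
#' [generate_probfs()].
#'
#' @inheritParams generate_probfs
#' @param n_folds number of folds (>= 2, <= number of documents).
#' @return a `probfs_tbl` with `mode = "out_of_fold"` (no bundle: there is no
#'   single pair of base learners).
#' @export
generate_probfs_oof <- function(X, labels,
                                svm_config = model_config("SVM"),
                                lr_config = model_config("LR"),
                                n_folds = 5L, seed = 0L) {
  y <- .binary_labels(labels)
  if (nlevels(droplevels(y)) != 2L) {
    abort("ProBFS requires exactly two label values")
  }
  Xd <- .as_dense(X)
  n <- nrow(Xd)
  if (n_folds < 2L) abort("n_folds must be at least 2")
  if (n_folds > n) abort("n_folds exceeds the number of documents")
  svm_config$seed <- as.integer(seed)
  lr_config$seed <- as.integer(seed)
  folds <- .fold_ids(y, n_folds, seed)
  p_svm <- matrix(NA_real_, n, 2L)
  p_lr <- matrix(NA_real_, n, 2L)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    svm_fit <- fit_model(Xd[tr, , drop = FALSE], y[tr], svm_config)
    lr_fit <- fit_model(Xd[tr, , drop = FALSE], y[tr], lr_config)
    p_svm[!tr, ] <- predict_proba(svm_fit, Xd[!tr, , drop = FALSE])
    p_lr[!tr, ] <- predict_proba(lr_fit, Xd[!tr, , drop = FALSE])
  }
  .probfs_tbl(p_svm, p_lr,
              row_ids = rownames(Xd) %||% as.character(seq_len(n)),
              mode = "out_of_fold", class_order = sort(levels(droplevels(y))))
}

#' The fitted base learners behind a full-fit ProBFS
#'
#' @param probfs a `probfs_tbl` from [generate_probfs()].
#' @return the `base_learner_bundle` (fitted SVM and LR plus metadata).
#' @export
probfs_bundle <- function(probfs) {
  b <- attr(probfs, "bundle")
  if (is.null(b)) abort("no bundle attached (out-of-fold ProBFS has none)")
  b
}

#' @export
print.base_learner_bundle <- function(x, ...) {
  cat("<base_learner_bundle> SVM + LR on ", x$n_features,
      " TF-IDF features; classes: ", paste(x$class_order, collapse = " < "),
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Score new documents with an existing ProBFS bundle
#'
#' Applies the already-fitted base learners to new TF-IDF features (built
#' with the same vocabulary/idf model) without refitting; this is how a
#' ProBFS-trained downstream model scores unseen text.
#'
#' @param bundle a [probfs_bundle()].
#' @param X new TF-IDF `feature_matrix` (same width as at fit time).
#' @return a `probfs_tbl` with `mode = "transform"`; `0 x 4` for an empty
#'   corpus.
#' @export
probfs_transform <- function(bundle, X) {
  stopifnot(inherits(bundle, "base_learner_bundle"))
  Xd <- .as_dense(X)
  if (ncol(Xd) != bundle$n_features && nrow(Xd) > 0L) {
    abort(paste0("feature dimension mismatch: bundle expects ",
                 bundle$n_features, " features, got ", ncol(Xd)))
  }
  if (nrow(Xd) == 0L) {
    return(.probfs_tbl(matrix(numeric(0), 0L, 2L), matrix(numeric(0), 0L, 2L),
                       character(0), "transform", bundle$class_order))
  }
  .probfs_tbl(
    predict_proba(bundle$svm, Xd), predict_proba(bundle$lr, Xd),
    row_ids = rownames(Xd) %||% as.character(seq_len(nrow(Xd))),
    mode = "transform", class_order = bundle$class_order
  )
}

#' ProBFS tibble as a feature matrix
#'
#' @param probfs a `probfs_tbl`.
#' @return a `feature_matrix` with columns `P1`..`P4`, provenance
#'   `"probfs"`, ready for any downstream [fit_model()].
#' @export
probfs_features <- function(probfs) {
  m <- as.matrix(probfs[, c("P1", "P2", "P3", "P4")])
  feature_matrix(m, provenance = "probfs", feature_names = colnames(m),
                 row_ids = probfs$row_id)
}

#' @method glance probfs_tbl
#' @export
glance.probfs_tbl <- function(x, ...) {
  tibble(
    n_documents = nrow(x),
    n_features = 4L,
    mode = attr(x, "mode"),
    max_simplex_error = if (nrow(x) == 0L) 0 else
      max(abs(x$P1 + x$P2 - 1), abs(x$P3 + x$P4 - 1))
  )
}

#' Cross-validate a downstream model on ProBFS features
#'
#' Two protocols: `regenerate = "per_fold"` refits the base learners inside
#' every training fold (leakage-safe); `"precomputed"` generates one
#' full-fit ProBFS on all documents first and cross-validates the downstream
#' model on it (the optimistic protocol).
#'
#' @param X TF-IDF `feature_matrix`.
#' @param labels binary labels.
#' @param config downstream [model_config()].
#' @param n_folds folds.
#' @param seed seed for folds and base learners.
#' @param regenerate `"per_fold"` or `"precomputed"`.
#' @return a `cv_report`.
#' @export
probfs_cross_validate <- function(X, labels, config, n_folds = 10L, seed = 0L,
                                  regenerate = c("per_fold", "precomputed")) {
  regenerate <- match.arg(regenerate)
  if (regenerate == "precomputed") {
    pf <- generate_probfs(X, labels, seed = seed)
    return(cross_validate(probfs_features(pf), labels, config,
                          n_folds = n_folds, seed = seed))
  }
  n <- length(labels)
  if (n_folds < 2L || n_folds > n) abort("invalid n_folds")
  Xd <- .as_dense(X)
  folds <- .fold_ids(labels, n_folds, seed)
  scores <- vapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    pf_train <- generate_probfs(Xd[tr, , drop = FALSE], labels[tr], seed = seed)
    fit <- fit_model(probfs_features(pf_train), labels[tr], config)
    pf_test <- probfs_transform(probfs_bundle(pf_train), Xd[!tr, , drop = FALSE])
    mean(predict(fit, probfs_features(pf_test)) == labels[!tr])
  }, numeric(1L))
  structure(
    list(fold_scores = scores, mean = mean(scores), sd = sd(scores),
         n_folds = n_folds, model = config$name, seed = seed),
    class = "cv_report"
  )
}

#' Write a ProBFS table to disk
#'
#' CSV with header `row_id,P1,P2,P3,P4` plus a JSON metadata sidecar
#' (`<path>.json`) recording mode, class order and base-learner settings.
#'
#' @param probfs a `probfs_tbl`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_probfs <- function(probfs, path) {
  utils::write.csv(as.data.frame(probfs), path, row.names = FALSE)
  bundle <- attr(probfs, "bundle")
  meta <- list(
    mode = attr(probfs, "mode"),
    class_order = attr(probfs, "class_order"),
    n_documents = nrow(probfs)
  )
  if (!is.null(bundle)) {
    meta$seed <- bundle$seed
    meta$base_models <- list(
      svm = bundle$svm$config$hyperparameters,
      lr = bundle$lr$config$hyperparameters
    )
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
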