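# Feature reduction: chi-squared selection and PCA projection.

#' Chi-squared scores of features against a binary label
#'
#' For each (non-negative) feature column, sums the feature mass observed in
#' each class and compares it with the mass expected under independence of
#' feature and class, giving the standard one-degree-of-freedom chi-squared
#' statistic per feature. Features constant across classes in proportion to
#' class frequency score 0.
#'
#' @param X a `feature_matrix` or non-negative numeric matrix.
#' @param labels binary label vector aligned with rows.
#' @return numeric vector of scores, one per feature.
#' @export
chi2_scores <- function(X, labels) {
  m <- if (inherits(X, "feature_matrix")) X$values else methods::as(X, "CsparseMatrix")
  if (min(m) < 0) abort("chi-squared selection requires non-negative features")
  y <- factor(labels)
  stopifnot(nrow(m) == length(y))
  Y <- sparseMatrix(i = seq_along(y), j = as.integer(y), x = 1,
                    dims = c(length(y), nlevels(y)))
  observed <- as.matrix(Matrix::t(Y) %*% m)           # classes x features
  feature_total <- Matrix::colSums(m)
  class_prob <- as.numeric(table(y)) / length(y)
  expected <- outer(class_prob, feature_total)
  with_mass <- feature_total > 0
  dev <- (observed - expected)^2
  scores <- numeric(ncol(m))
  scores[with_mass] <- colSums(dev[, with_mass, drop = FALSE] /
                                 expected[, with_mass, drop = FALSE])
  scores
}

#' Chi-squared feature selection
#'
#' Keeps the `k` features with the highest chi-squared score against the
#' label; ties are broken in favour of the lower column index. Selected
#' columns keep their original relative order, so the result for `k` is
#' always a column-subset of the result for any `k' >= k`.
#'
#' @inheritParams chi2_scores
#' @param k number of features to keep (<= number of features).
#' @return a `feature_matrix` with `k` columns, provenance `"chi2"`.
#' @export
chi2_select <- function(X, labels, k = 5000L) {
  m <- if (inherits(X, "feature_matrix")) X$values else methods::as(X, "CsparseMatrix")
  if (k > ncol(m)) abort("k exceeds the number of features")
  scores <- chi2_scores(X, labels)
  keep <- sort(order(-scores, seq_along(scores))[seq_len(k)])
  feature_matrix(m[, keep, drop = FALSE], provenance = "chi2",
                 feature_names = colnames(m)[keep], row_ids = rownames(m))
}

#' PCA feature reduction
#'
#' Projects the (densified, column-centered) feature matrix onto its top
#' principal components. Component signs are fixed deterministically: each
#' loading vector is flipped so its largest-magnitude entry is positive.
#'
#' @param X a `feature_matrix` or numeric matrix.
#' @param n_components number of components, at most `min(n_docs, n_features)`.
#' @return a `feature_matrix` of scores, provenance `"pca"`, carrying the
#'   rotation and center as attributes `"rotation"` and `"center"`.
#' @export
pca_reduce <- function(X, n_components) {
  m <- .as_dense(X)
  if (n_components > min(dim(m))) {
    abort("n_components exceeds min(n_documents, n_features)")
  }
  p <- prcomp(m, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1L))
  rotation <- sweep(p$rotation, 2L, flip, `*`)
  scores <- sweep(p$x[, seq_len(n_components), drop = FALSE], 2L,
                  flip[seq_len(n_components)], `*`)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  out <- feature_matrix(scores, provenance = "pca",
                        feature_names = colnames(scores),
                        row_ids = rownames(if (inherits(X, "feature_matrix")) X$values else m))
  attr(out, "rotation") <- rotation
  attr(out, "center") <- p$center
  attr(out, "sdev") <- p$sdev
  out
}
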