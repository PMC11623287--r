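# Sparse documents-by-features container with provenance, the common
# currency between featurizers, reducers and model wrappers.

#' Construct a feature matrix
#'
#' A thin S3 wrapper around a sparse `Matrix::dgCMatrix`: rows are documents,
#' columns are features, and a provenance tag records which featurizer built
#' it (`"bow"`, `"tfidf"`, `"hashing"`, `"chi2"`, `"pca"` or `"probfs"`).
#'
#' @param values numeric matrix or Matrix (documents x features).
#' @param provenance character tag.
#' @param feature_names optional character vector aligned with columns.
#' @param row_ids optional document identifiers aligned with rows.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, provenance,
                           feature_names = colnames(values),
                           row_ids = rownames(values)) {
  m <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == ncol(m))
    colnames(m) <- feature_names
  }
  if (is.null(row_ids)) row_ids <- as.character(seq_len(nrow(m)))
  stopifnot(length(row_ids) == nrow(m))
  rownames(m) <- as.character(row_ids)
  structure(list(values = m, provenance = provenance), class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " documents x ", ncol(x$values),
      " features  [", x$provenance, "]\n", sep = "")
  nz <- Matrix::nnzero(x$values)
  cat("  nonzero entries: ", nz, " (",
      sprintf("%.2f%%", 100 * nz / max(1, prod(dim(x$values)))), ")\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) as.matrix(x$values)

#' @rdname feature_matrix
#' @param x a `feature_matrix`.
#' @param ... unused.
#' @method as_tibble feature_matrix
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  out <- as_tibble(as.matrix(x$values), .name_repair = "minimal")
  if (is.null(colnames(x$values))) {
    names(out) <- paste0("f", seq_len(ncol(out)))
  }
  dplyr::bind_cols(tibble(row_id = rownames(x$values)), out)
}

#' Feature names of a feature matrix
#' @param x a `feature_matrix`.
#' @return character vector or NULL (hashing has no names).
#' @export
feature_names <- function(x) colnames(x$values)

#' Provenance tag of a feature matrix
#' @param x a `feature_matrix`.
#' @export
provenance <- function(x) x$provenance

# internal: dense numeric matrix from anything the model wrappers accept
.as_dense <- function(X) {
  if (inherits(X, "feature_matrix")) X <- X$values
  if (is.data.frame(X)) {
    X <- as.matrix(X[vapply(X, is.numeric, logical(1L))])
  }
  m <- as.matrix(X)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

#' Write a feature matrix to disk
#'
#' Serializes as MatrixMarket (`<prefix>.mtx`) plus a sidecar TSV of feature
#' names (`<prefix>.features.tsv`, when names exist) and a JSON header
#' (`<prefix>.json`) carrying provenance, dimensions and row identifiers.
#'
#' @param x a `feature_matrix`.
#' @param prefix file path prefix.
#' @return `prefix`, invisibly.
#' @export
write_feature_matrix <- function(x, prefix) {
  Matrix::writeMM(x$values, paste0(prefix, ".mtx"))
  fn <- colnames(x$values)
  if (!is.null(fn)) {
    utils::write.table(
      data.frame(term = fn, index = seq_along(fn) - 1L),
      paste0(prefix, ".features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  jsonlite::write_json(
    list(provenance = x$provenance, n_documents = nrow(x$values),
         n_features = ncol(x$values), row_ids = rownames(x$values)),
    paste0(prefix, ".json"), auto_unbox = TRUE
  )
  invisible(prefix)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param prefix file path prefix.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  fn_path <- paste0(prefix, ".features.tsv")
  fn <- NULL
  if (file.exists(fn_path)) {
    fn <- utils::read.table(fn_path, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer"))$term
  }
  feature_matrix(m, provenance = meta$provenance,
                 feature_names = fn, row_ids = meta$row_ids)
}
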