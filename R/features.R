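# Featurizers: vocabulary, bag-of-words counts, TF-IDF weighting and signed
# feature hashing.

.tokens_of <- function(corpus) {
  if (is.data.frame(corpus)) {
    if (!"tokens" %in% names(corpus)) {
      abort("corpus data frame must carry a 'tokens' list-column (see preprocess_corpus())")
    }
    return(corpus$tokens)
  }
  stopifnot(is.list(corpus))
  corpus
}

.row_ids_of <- function(corpus) {
  if (is.data.frame(corpus) && "id" %in% names(corpus)) {
    return(as.character(corpus$id))
  }
  NULL
}

#' Fit a vocabulary on a tokenized corpus
#'
#' @param corpus a list of character token vectors, or a data frame with a
#'   `tokens` list-column.
#' @return an object of class `vocabulary`: sorted distinct terms with a
#'   term-to-column index.
#' @export
fit_vocabulary <- function(corpus) {
  tokens <- .tokens_of(corpus)
  if (length(tokens) == 0L) abort("cannot fit a vocabulary on an empty corpus")
  terms <- sort(unique(unlist(tokens, use.names = FALSE)))
  if (length(terms) == 0L) warn("vocabulary is empty: no tokens in corpus")
  structure(
    list(terms = terms, index = setNames(seq_along(terms), terms)),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", length(x$terms), " terms\n", sep = "")
  if (length(x$terms) > 0L) {
    cat("  ", paste(head(x$terms, 8L), collapse = ", "),
        if (length(x$terms) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.vocabulary <- function(x) length(x$terms)

# document/term triplets over a fitted vocabulary; OOV tokens dropped
.count_triplets <- function(tokens, vocab) {
  doc_lens <- lengths(tokens)
  all_tokens <- unlist(tokens, use.names = FALSE)
  doc_of <- rep.int(seq_along(tokens), doc_lens)
  col_of <- vocab$index[all_tokens]
  keep <- !is.na(col_of)
  list(i = doc_of[keep], j = unname(col_of[keep]))
}

#' Bag-of-words transform
#'
#' Counts each vocabulary term per document; out-of-vocabulary tokens are
#' ignored.
#'
#' @inheritParams fit_vocabulary
#' @param vocab a fitted [fit_vocabulary()] object.
#' @return a `feature_matrix` of non-negative integer counts, provenance
#'   `"bow"`.
#' @export
bow_transform <- function(corpus, vocab) {
  tokens <- .tokens_of(corpus)
  tr <- .count_triplets(tokens, vocab)
  m <- sparseMatrix(i = tr$i, j = tr$j, x = 1,
                    dims = c(length(tokens), length(vocab$terms)))
  feature_matrix(m, provenance = "bow", feature_names = vocab$terms,
                 row_ids = .row_ids_of(corpus))
}

#' Inverse document frequency
#'
#' `idf = log(N / D_t)` with `N` the number of documents and `D_t` the number
#' of documents containing the term (natural log). The smoothed variant is
#' `log((1 + N) / (1 + D_t)) + 1`, defined even for unseen terms.
#'
#' @param n_docs number of documents `N`.
#' @param doc_freq document frequency `D_t` (vectorized).
#' @param variant `"raw"` or `"smooth"`.
#' @return idf weight(s).
#' @examples
#' idf_weight(2, 1)  # log(2)
#' idf_weight(4, 2)  # log(2)
#' @export
idf_weight <- function(n_docs, doc_freq, variant = c("raw", "smooth")) {
  variant <- match.arg(variant)
  switch(variant,
    raw = log(n_docs / doc_freq),
    smooth = log((1 + n_docs) / (1 + doc_freq)) + 1
  )
}

#' Fit a TF-IDF model
#'
#' Computes per-term idf weights on the fitting corpus. When evaluating a
#' train/test split, fit on the training documents only and reuse the model
#' on the test documents to avoid leaking test-set document frequencies.
#'
#' @inheritParams fit_vocabulary
#' @param vocab optional pre-fitted vocabulary; fitted on `corpus` when NULL.
#' @param idf_variant `"raw"` (log(N / D_t)) or `"smooth"`.
#' @param norm `"l2"` (rows scaled to unit Euclidean norm) or `"none"`.
#' @return an object of class `tfidf_model`.
#' @export
fit_tfidf <- function(corpus, vocab = NULL, idf_variant = c("raw", "smooth"),
                      norm = c("l2", "none")) {
  idf_variant <- match.arg(idf_variant)
  norm <- match.arg(norm)
  tokens <- .tokens_of(corpus)
  if (length(tokens) == 0L || all(lengths(tokens) == 0L)) {
    abort("cannot fit TF-IDF on an all-empty corpus")
  }
  if (is.null(vocab)) vocab <- fit_vocabulary(tokens)
  df <- setNames(numeric(length(vocab$terms)), vocab$terms)
  seen <- table(unlist(lapply(tokens, function(tk) unique(tk[tk %in% vocab$terms]))))
  df[names(seen)] <- as.numeric(seen)
  idf <- idf_weight(length(tokens), df, idf_variant)
  if (idf_variant == "raw" && any(df == 0)) {
    warn("vocabulary terms absent from the fitting corpus get idf 0 under the raw variant")
    idf[df == 0] <- 0
  }
  structure(
    list(vocab = vocab, idf = unname(idf), doc_freq = unname(df),
         n_docs = length(tokens), idf_variant = idf_variant, norm = norm),
    class = "tfidf_model"
  )
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("<tfidf_model> ", length(x$vocab$terms), " terms, fitted on ",
      x$n_docs, " documents (idf: ", x$idf_variant, ", norm: ", x$norm, ")\n",
      sep = "")
  invisible(x)
}

# rows with at least one nonzero scaled to unit Euclidean norm
.l2_normalize_rows <- function(m) {
  nrm <- sqrt(Matrix::rowSums(m^2))
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  Diagonal(x = scale) %*% m
}

#' TF-IDF transform
#'
#' Weights raw term counts by the fitted idf (`tf-idf = TF_{t,d} * idf_t`)
#' and, under the default `"l2"` norm, scales every non-empty row to unit
#' Euclidean norm.
#'
#' @inheritParams fit_vocabulary
#' @param model a fitted [fit_tfidf()] model.
#' @return a `feature_matrix`, provenance `"tfidf"`.
#' @export
tfidf_transform <- function(corpus, model) {
  stopifnot(inherits(model, "tfidf_model"))
  counts <- bow_transform(corpus, model$vocab)$values
  m <- counts %*% Diagonal(x = model$idf)
  if (model$norm == "l2") m <- .l2_normalize_rows(m)
  feature_matrix(m, provenance = "tfidf", feature_names = model$vocab$terms,
                 row_ids = .row_ids_of(corpus))
}

#' One-shot TF-IDF on a corpus
#'
#' Fits the idf weights on `corpus` and transforms the same corpus.
#'
#' @inheritParams fit_tfidf
#' @return a `feature_matrix`, provenance `"tfidf"`.
#' @export
tfidf <- function(corpus, vocab = NULL, idf_variant = "raw", norm = "l2") {
  tfidf_transform(corpus, fit_tfidf(corpus, vocab, idf_variant, norm))
}

# ---- signed feature hashing ------------------------------------------------

# 32-bit FNV-1a over the token's UTF-8 bytes, with the seed mixed into the
# offset basis. Exact arithmetic in doubles via 16-bit halves.
.xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

.mul32 <- function(a, b) {
  (((a %/% 65536) * b) %% 65536) * 65536 + (a %% 65536) * b
}

.fnv1a32 <- function(token, seed = 0) {
  h <- .xor32(2166136261, seed %% 4294967296)
  for (b in as.integer(charToRaw(token))) {
    h <- .xor32(h, b)
    h <- .mul32(h, 16777619) %% 4294967296
  }
  h
}

#' Hash tokens to signed buckets
#'
#' Maps each token to a bucket in `1..n_buckets` and a sign in `{-1, +1}`
#' using a seedable 32-bit FNV-1a hash (bucket from the hash value modulo
#' `n_buckets`, sign from the top hash bit). Exposed so collision structures
#' can be constructed and inspected.
#'
#' @param tokens character vector.
#' @param n_buckets number of buckets (>= 1).
#' @param seed integer hash seed.
#' @return a tibble with columns `token`, `bucket`, `sign`.
#' @export
hash_bucket <- function(tokens, n_buckets, seed = 0) {
  stopifnot(n_buckets >= 1)
  h <- vapply(tokens, .fnv1a32, numeric(1L), seed = seed, USE.NAMES = FALSE)
  tibble(
    token = tokens,
    bucket = as.integer(h %% n_buckets) + 1L,
    sign = ifelse(h %/% 2147483648 == 0, 1, -1)
  )
}

#' Signed feature-hashing transform
#'
#' Vocabulary-free featurization: each token is hashed to one of `n_buckets`
#' columns with a sign, bucket contributions are summed per document, and
#' non-empty rows are scaled to unit Euclidean norm (under the default
#' `"l2"`). Collisions within a bucket add (same sign) or cancel (opposite
#' signs).
#'
#' @inheritParams fit_vocabulary
#' @param n_buckets number of hash buckets (>= 1).
#' @param signed use the hash sign bit; when FALSE all contributions are +1.
#' @param seed integer hash seed.
#' @param norm `"l2"` or `"none"`.
#' @return a `feature_matrix` with `n_buckets` columns, provenance
#'   `"hashing"`, no feature names.
#' @export
hashing_transform <- function(corpus, n_buckets = 1024L, signed = TRUE,
                              seed = 0, norm = c("l2", "none")) {
  norm <- match.arg(norm)
  stopifnot(n_buckets >= 1)
  tokens <- .tokens_of(corpus)
  uniq <- unique(unlist(tokens, use.names = FALSE))
  m <- Matrix::Matrix(0, nrow = length(tokens), ncol = n_buckets, sparse = TRUE)
  if (length(uniq) > 0L) {
    hb <- hash_bucket(uniq, n_buckets, seed)
    bucket_of <- setNames(hb$bucket, hb$token)
    sign_of <- setNames(if (signed) hb$sign else rep(1, nrow(hb)), hb$token)
    doc_of <- rep.int(seq_along(tokens), lengths(tokens))
    tok <- unlist(tokens, use.names = FALSE)
    m <- sparseMatrix(i = doc_of, j = unname(bucket_of[tok]),
                      x = unname(sign_of[tok]),
                      dims = c(length(tokens), n_buckets))
  }
  if (norm == "l2") m <- .l2_normalize_rows(m)
  feature_matrix(m, provenance = "hashing", feature_names = NULL,
                 row_ids = .row_ids_of(corpus))
}
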