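# Shared helpers: independent brute-force oracles and tiny corpus builders.

# Brute-force TF-IDF: per-cell evaluation of tf * log(N / D_t) with optional
# L2 row normalization, written with plain loops so it shares no code with
# the package's sparse implementation.
oracle_tfidf <- function(tokens_list, norm = "l2", variant = "raw") {
  terms <- sort(unique(unlist(tokens_list)))
  N <- length(tokens_list)
  mat <- matrix(0, N, length(terms), dimnames = list(NULL, terms))
  for (d in seq_len(N)) {
    for (t in terms) {
      tf <- sum(tokens_list[[d]] == t)
      Dt <- sum(vapply(tokens_list, function(x) t %in% x, logical(1)))
      idf <- if (variant == "raw") log(N / Dt) else log((1 + N) / (1 + Dt)) + 1
      mat[d, t] <- tf * idf
    }
  }
  if (norm == "l2") {
    for (d in seq_len(N)) {
      nr <- sqrt(sum(mat[d, ]^2))
      if (nr > 0) mat[d, ] <- mat[d, ] / nr
    }
  }
  mat
}

# Random tiny corpus: n_docs documents over an alphabet of n_terms symbols.
random_tiny_corpus <- function(n_docs, n_terms, seed, max_len = 12L) {
  set.seed(seed)
  alphabet <- sprintf("t%02d", seq_len(n_terms))
  lapply(seq_len(n_docs), function(i) {
    sample(alphabet, sample.int(max_len, 1L), replace = TRUE)
  })
}

# Search deterministic candidate tokens for a hash-collision structure:
# one bucket receiving `n_pair` same-signed tokens plus `n_single` further
# tokens occupying distinct other buckets. Returns the token vector.
find_collision_tokens <- function(n_single, n_buckets, seed = 0) {
  candidates <- sprintf("tok%05d", seq_len(3000L))
  hb <- hash_bucket(candidates, n_buckets, seed = seed)
  key <- paste(hb$bucket, hb$sign)
  pair_key <- names(which(table(key) >= 2L))[1L]
  stopifnot(!is.na(pair_key))
  pair <- hb[key == pair_key, ][1:2, ]
  singles <- hb[hb$bucket != pair$bucket[1L] & !duplicated(hb$bucket), ]
  stopifnot(nrow(singles) >= n_single)
  c(pair$token, singles$token[seq_len(n_single)])
}

# Small synthetic corpus with a tokens column, for model-level tests.
small_synth <- function(n = 200L, separability = 0.8, seed = 1L,
                        shared = 100L, class_vocab = 30L) {
  tokenize_corpus(generate_corpus(corpus_spec(
    n_documents = n, separability = separability, seed = seed,
    vocab_size_shared = shared, vocab_size_class = class_vocab,
    doc_length_mean = 20
  )))
}
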