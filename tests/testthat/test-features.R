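test_that("vocabulary is the sorted distinct token set", {
  v <- fit_vocabulary(list(c("a", "b"), c("b", "c")))
  expect_equal(v$terms, c("a", "b", "c"))
  expect_equal(unname(v$index[v$terms]), 1:3)
  expect_error(fit_vocabulary(list()), "empty corpus")
  expect_warning(fit_vocabulary(list(character(0))), "empty")
})

test_that("worked-example corpus yields the 12-term vocabulary and exact BoW counts", {
  fx <- load_fixture("tables_5_6")
  v <- fit_vocabulary(fx$documents)
  expect_equal(v$terms,
               c("annoying", "do", "feel", "good", "internet", "it", "its",
                 "really", "so", "strangers", "swear", "when"))
  bw <- bow_transform(fx$documents, v)
  expect_equal(unname(as.matrix(bw)), unname(fx$expected_bow))
  expect_equal(provenance(bw), "bow")
})

test_that("bag-of-words counts tokens and ignores out-of-vocabulary terms", {
  v <- fit_vocabulary(list(c("a", "b")))
  m <- as.matrix(bow_transform(list(c("a", "a", "b", "zzz"), character(0)), v))
  expect_equal(unname(m), rbind(c(2, 1), c(0, 0)))
  # row sum equals the in-vocabulary token count
  expect_equal(unname(rowSums(m)), c(3, 0))
})

test_that("idf follows log(N / D_t)", {
  expect_equal(idf_weight(2, 1), log(2))
  expect_equal(idf_weight(4, 2), log(2))
  expect_equal(idf_weight(3, 3), 0)  # term in every document
  expect_equal(idf_weight(2, 1, variant = "smooth"), log(3 / 2) + 1)
})

test_that("worked-example TF-IDF weights are exact (1/sqrt(8) and 1/sqrt(4))", {
  fx <- load_fixture("tables_5_6")
  m <- as.matrix(tfidf(fx$documents))
  expect_identical(dim(m), c(2L, 12L))
  nz0 <- m[1, m[1, ] > 0]
  nz1 <- m[2, m[2, ] > 0]
  expect_equal(unname(nz0), rep(1 / sqrt(8), 8), tolerance = 1e-15)
  expect_equal(unname(nz1), rep(0.5, 4), tolerance = 1e-15)
  expect_equal(round(unname(m["0", "feel"]), 6), 0.353553)
  expect_equal(m, fx$expected_tfidf, ignore_attr = FALSE)
})

test_that("single-term documents get weight 1 after normalization", {
  m <- as.matrix(tfidf(list("alpha", c("beta", "beta"))))
  expect_equal(unname(m[1, "alpha"]), 1)
  expect_equal(unname(m[2, "beta"]), 1)
})

test_that("tfidf matches the brute-force oracle on random tiny corpora", {
  for (seed in 1:6) {
    corp <- random_tiny_corpus(n_docs = sample(2:5, 1), n_terms = 20, seed = seed)
    expect_equal(unname(as.matrix(tfidf(corp))),
                 unname(oracle_tfidf(corp)), tolerance = 1e-12)
    expect_equal(unname(as.matrix(tfidf(corp, norm = "none"))),
                 unname(oracle_tfidf(corp, norm = "none")), tolerance = 1e-12)
    expect_equal(unname(as.matrix(tfidf(corp, idf_variant = "smooth"))),
                 unname(oracle_tfidf(corp, variant = "smooth")), tolerance = 1e-12)
  }
})

test_that("non-empty TF-IDF and hashing rows have unit Euclidean norm", {
  corp <- random_tiny_corpus(5, 15, seed = 9)
  corp <- c(corp, list(character(0)))
  for (m in list(as.matrix(tfidf(corp)),
                 as.matrix(hashing_transform(corp, n_buckets = 32)))) {
    norms <- unname(sqrt(rowSums(m^2)))
    expect_equal(norms[1:5], rep(1, 5), tolerance = 1e-9)
    expect_equal(norms[6], 0)
  }
})

test_that("a fitted tfidf model transforms unseen documents with training idf", {
  train <- list(c("a", "b"), c("b", "c"))
  model <- fit_tfidf(train)
  m <- as.matrix(tfidf_transform(list(c("a", "c", "zzz")), model))
  raw <- c(a = log(2), b = 0, c = log(2))
  expect_equal(unname(m[1, ]), unname(raw / sqrt(sum(raw^2))), tolerance = 1e-12)
})

test_that("hashing reproduces the collision magnitude pattern", {
  # 8 tokens, one bucket holding a same-signed pair, six singleton buckets
  toks <- find_collision_tokens(n_single = 6, n_buckets = 12)
  m <- as.matrix(hashing_transform(list(toks), n_buckets = 12))
  mags <- sort(abs(m[1, m[1, ] != 0]), decreasing = TRUE)
  expect_equal(unname(mags), c(2, rep(1, 6)) / sqrt(10), tolerance = 1e-12)
  expect_equal(round(max(mags), 6), 0.632456)

  # 4 tokens over three buckets, one doubled
  toks2 <- find_collision_tokens(n_single = 2, n_buckets = 12)
  m2 <- as.matrix(hashing_transform(list(toks2), n_buckets = 12))
  mags2 <- sort(abs(m2[1, m2[1, ] != 0]), decreasing = TRUE)
  expect_equal(unname(mags2), c(2, 1, 1) / sqrt(6), tolerance = 1e-12)
  expect_equal(round(max(mags2), 6), 0.816497)
})

test_that("hashing needs no vocabulary and honours bucket count and seed", {
  corp <- random_tiny_corpus(4, 30, seed = 3)
  h1 <- hashing_transform(corp, n_buckets = 64, seed = 1)
  expect_equal(dim(h1), c(4L, 64L))
  expect_null(feature_names(h1))
  h1b <- hashing_transform(corp, n_buckets = 64, seed = 1)
  expect_identical(as.matrix(h1), as.matrix(h1b))
  h2 <- hashing_transform(corp, n_buckets = 64, seed = 2)
  expect_false(identical(as.matrix(h1), as.matrix(h2)))
  # unsigned mode: all contributions positive
  hu <- hashing_transform(corp, n_buckets = 64, signed = FALSE, norm = "none")
  expect_true(all(as.matrix(hu) >= 0))
})

test_that("feature matrices round-trip through MatrixMarket serialization", {
  fx <- load_fixture("tables_5_6")
  fm <- tfidf(fx$documents)
  prefix <- file.path(withr::local_tempdir(), "tf")
  write_feature_matrix(fm, prefix)
  back <- read_feature_matrix(prefix)
  expect_equal(as.matrix(back), as.matrix(fm), tolerance = 1e-12)
  expect_equal(provenance(back), "tfidf")
  expect_equal(feature_names(back), feature_names(fm))
})
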