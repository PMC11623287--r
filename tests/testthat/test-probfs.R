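make_probfs_inputs <- function(n = 150, separability = 0.8, seed = 2) {
  co <- small_synth(n = n, separability = separability, seed = seed)
  list(X = tfidf(co), y = co$label, corpus = co)
}

test_that("ProBFS is exactly four probability columns on the per-model simplex", {
  inp <- make_probfs_inputs()
  pf <- generate_probfs(inp$X, inp$y, seed = 1)
  expect_equal(names(pf), c("row_id", "P1", "P2", "P3", "P4"))
  expect_equal(nrow(pf), 150L)
  vals <- as.matrix(pf[, -1])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(abs(pf$P1 + pf$P2 - 1) <= 1e-6))
  expect_true(all(abs(pf$P3 + pf$P4 - 1) <= 1e-6))
  expect_equal(attr(pf, "mode"), "full_fit")
})

test_that("ProBFS is bit-for-bit reproducible under a fixed seed", {
  inp <- make_probfs_inputs(n = 100)
  a <- generate_probfs(inp$X, inp$y, seed = 9)
  b <- generate_probfs(inp$X, inp$y, seed = 9)
  expect_identical(a$P1, b$P1)
  expect_identical(a$P2, b$P2)
  expect_identical(a$P3, b$P3)
  expect_identical(a$P4, b$P4)
})

test_that("full-fit probabilities approach the vertices on separable data", {
  inp <- make_probfs_inputs(separability = 1, seed = 4)
  pf <- generate_probfs(inp$X, inp$y, seed = 1)
  expect_gt(mean(pmax(pf$P1, pf$P2) > 0.9), 0.5)
})

test_that("input contracts are enforced", {
  inp <- make_probfs_inputs(n = 60)
  expect_error(generate_probfs(inp$X, rep(c("a", "b", "c"), 20)),
               "two")
  bw <- bow_transform(inp$corpus, fit_vocabulary(inp$corpus))
  expect_warning(generate_probfs(bw, inp$y, seed = 1), "provenance")
  expect_error(generate_probfs(inp$X, rep("a", 60)), "two")
})

test_that("a full-fit bundle transforms the training corpus to the same values", {
  inp <- make_probfs_inputs(n = 80)
  pf <- generate_probfs(inp$X, inp$y, seed = 5)
  again <- probfs_transform(probfs_bundle(pf), inp$X)
  expect_equal(again$P1, pf$P1, tolerance = 1e-12)
  expect_equal(again$P4, pf$P4, tolerance = 1e-12)
})

test_that("transforming an empty corpus yields a 0 x 4 table", {
  inp <- make_probfs_inputs(n = 60)
  pf <- generate_probfs(inp$X, inp$y, seed = 5)
  empty <- probfs_transform(probfs_bundle(pf),
                            matrix(numeric(0), 0, ncol(inp$X$values)))
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), c("row_id", "P1", "P2", "P3", "P4"))
})

test_that("an all-out-of-vocabulary document scores as the zero vector", {
  inp <- make_probfs_inputs(n = 60)
  pf <- generate_probfs(inp$X, inp$y, seed = 5)
  bundle <- probfs_bundle(pf)
  model <- fit_tfidf(inp$corpus)
  oov <- tfidf_transform(list(c("qqq", "zzz")), model)
  got <- probfs_transform(bundle, oov)
  at_origin <- probfs_transform(bundle, matrix(0, 1, ncol(inp$X$values)))
  expect_equal(as.numeric(got[1, -1]), as.numeric(at_origin[1, -1]),
               tolerance = 1e-12)
})

test_that("out-of-fold ProBFS keeps the shape and simplex invariants", {
  inp <- make_probfs_inputs(n = 90)
  pf <- generate_probfs_oof(inp$X, inp$y, n_folds = 5, seed = 3)
  expect_equal(dim(pf), c(90L, 5L))
  expect_true(all(abs(pf$P1 + pf$P2 - 1) <= 1e-6))
  expect_true(all(abs(pf$P3 + pf$P4 - 1) <= 1e-6))
  expect_equal(attr(pf, "mode"), "out_of_fold")
  expect_error(probfs_bundle(pf), "no bundle")
  expect_error(generate_probfs_oof(inp$X, inp$y, n_folds = 1), "at least 2")
  expect_error(generate_probfs_oof(inp$X, inp$y, n_folds = 91), "exceeds")
})

test_that("the four columns carry at most two independent directions", {
  inp <- make_probfs_inputs(n = 100)
  pf <- generate_probfs(inp$X, inp$y, seed = 1)
  M <- cbind(1, as.matrix(pf[, c("P1", "P2", "P3", "P4")]))
  expect_lte(qr(M)$rank, 3L)  # P2 = 1 - P1 and P4 = 1 - P3
})

test_that("probfs tables serialize with metadata and convert to feature matrices", {
  inp <- make_probfs_inputs(n = 40)
  pf <- generate_probfs(inp$X, inp$y, seed = 2)
  fm <- probfs_features(pf)
  expect_equal(provenance(fm), "probfs")
  expect_equal(dim(fm), c(40L, 4L))
  path <- tempfile(fileext = ".csv")
  write_probfs(pf, path)
  back <- read.csv(path)
  expect_equal(back$P2, pf$P2, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$mode, "full_fit")
  expect_equal(meta$base_models$svm$kernel, "linear")
  unlink(c(path, paste0(path, ".json")))
})

test_that("per-fold and precomputed ProBFS cross-validation both run", {
  inp <- make_probfs_inputs(n = 90, separability = 1)
  cv1 <- probfs_cross_validate(inp$X, inp$y, model_config("KNN"),
                               n_folds = 3, seed = 1, regenerate = "per_fold")
  cv2 <- probfs_cross_validate(inp$X, inp$y, model_config("KNN"),
                               n_folds = 3, seed = 1, regenerate = "precomputed")
  expect_length(cv1$fold_scores, 3L)
  expect_length(cv2$fold_scores, 3L)
  expect_gte(cv2$mean, cv1$mean - 0.05)  # precomputed is the optimistic protocol
})
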