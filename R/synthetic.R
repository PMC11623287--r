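# Synthetic-corpus generator: binary-labeled short documents drawn from a
# token mixture of a shared vocabulary and two class-specific vocabularies,
# with tunable class separability. Emulates the scale of a balanced
# social-media corpus (two equal classes, mean document length 58 tokens)
# without any natural-language structure.

#' Specification of a synthetic corpus
#'
#' @param n_documents number of documents.
#' @param class_balance proportion of the positive (`"suicide"`) class in
#'   (0, 1); default 0.5 (balanced classes).
#' @param vocab_size_shared size of the class-neutral vocabulary.
#' @param vocab_size_class size of each class-specific vocabulary.
#' @param separability probability in `[0, 1]` that a token is drawn from
#'   the document's class-specific vocabulary rather than the shared one; 0
#'   makes the classes exchangeable, 1 gives them disjoint token support.
#' @param doc_length_mean mean document length in tokens (default 58).
#' @param doc_length_dispersion negative-binomial size parameter; smaller
#'   values give more length variation.
#' @param labels the two class names, sorted order defining the class order
#'   downstream.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_documents = 2000L, class_balance = 0.5,
                        vocab_size_shared = 800L, vocab_size_class = 150L,
                        separability = 0.6, doc_length_mean = 58,
                        doc_length_dispersion = 5,
                        labels = c("non-suicide", "suicide"), seed = 0L) {
  stopifnot(n_documents >= 2L, class_balance > 0, class_balance < 1,
            separability >= 0, separability <= 1,
            doc_length_mean >= 1, doc_length_dispersion > 0,
            length(labels) == 2L)
  if (vocab_size_shared < 1L || vocab_size_class < 1L) {
    abort("vocabulary sizes must be positive")
  }
  structure(
    list(n_documents = as.integer(n_documents), class_balance = class_balance,
         vocab_size_shared = as.integer(vocab_size_shared),
         vocab_size_class = as.integer(vocab_size_class),
         separability = separability, doc_length_mean = doc_length_mean,
         doc_length_dispersion = doc_length_dispersion,
         labels = sort(labels), seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat("<corpus_spec> ", x$n_documents, " documents (",
      paste(x$labels, collapse = "/"), ", balance ", x$class_balance,
      ")\n  separability ", x$separability, ", mean length ",
      x$doc_length_mean, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic labeled corpus
#'
#' Label counts match the specification exactly (positive count =
#' `round(n * class_balance)`). Document lengths are
#' `1 + NegBinomial(mean = doc_length_mean - 1, size = dispersion)`, so
#' every document has at least one token. Each token is drawn uniformly
#' from the document's class vocabulary with probability `separability`,
#' otherwise uniformly from the shared vocabulary.
#'
#' @param spec a [corpus_spec()].
#' @return a tibble with columns `id`, `text`, `label`; deterministic given
#'   `spec$seed`.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_documents
  n_pos <- round(n * spec$class_balance)
  shared <- sprintf("w%04d", seq_len(spec$vocab_size_shared))
  class_vocab <- list(
    sprintf("na%04d", seq_len(spec$vocab_size_class)),  # first sorted label
    sprintf("sb%04d", seq_len(spec$vocab_size_class))
  )
  .with_seed(spec$seed, {
    label <- sample(rep(c(spec$labels[2L], spec$labels[1L]), c(n_pos, n - n_pos)))
    lens <- 1L + rnbinom(n, size = spec$doc_length_dispersion,
                         mu = spec$doc_length_mean - 1)
    text <- vapply(seq_len(n), function(i) {
      cls <- match(label[i], spec$labels)
      from_class <- runif(lens[i]) < spec$separability
      tok <- character(lens[i])
      if (any(from_class)) {
        tok[from_class] <- sample(class_vocab[[cls]], sum(from_class),
                                  replace = TRUE)
      }
      if (any(!from_class)) {
        tok[!from_class] <- sample(shared, sum(!from_class), replace = TRUE)
      }
      paste(tok, collapse = " ")
    }, character(1L))
    tibble(id = seq_len(n), text = text, label = label)
  })
}

#' Tokenize a synthetic (already clean) corpus
#'
#' Synthetic documents contain only lowercase word tokens separated by
#' single spaces, so tokenization is plain whitespace splitting; no
#' cleaning steps are needed.
#'
#' @param data a corpus tibble with a `text` column.
#' @return the tibble with a `tokens` list-column added.
#' @export
tokenize_corpus <- function(data) {
  stopifnot(is.data.frame(data), "text" %in% names(data))
  out <- as_tibble(data)
  out$tokens <- strsplit(out$text, " ", fixed = TRUE)
  out
}
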