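# Cleaning pipeline: punctuation removal -> number removal -> lowercasing ->
# stop-word removal -> stemming, then whitespace tokenization.

# Unicode punctuation and symbols (covers the ASCII set plus typographic
# quotes and dashes common in social-media text).
.PUNCT_RE <- "[\\p{P}\\p{S}]+"

.PIPELINE_STEPS <- c("punctuation", "numbers", "lowercase", "stopwords", "stemming")

#' Strip punctuation from text
#'
#' Every maximal run of ASCII punctuation characters is replaced by a single
#' space. Replacement (rather than deletion) avoids fusing the words on
#' either side of the punctuation; already-fused words in the raw data are
#' left as they are.
#'
#' @param text character vector.
#' @return character vector of the same length, free of punctuation.
#' @examples
#' remove_punctuation("help!just help me")
#' @export
remove_punctuation <- function(text) {
  gsub(.PUNCT_RE, " ", text, perl = TRUE)
}

#' Strip digits from text
#'
#' Digits carry little class signal in short social-media posts and are
#' deleted outright (not replaced by a space).
#'
#' @param text character vector.
#' @return character vector with no digit characters.
#' @examples
#' remove_numbers("Finally 2020 is almost over")
#' @export
remove_numbers <- function(text) {
  gsub("[0-9]+", "", text, perl = TRUE)
}

#' Lowercase text
#'
#' @param text character vector.
#' @return lowercased text; idempotent.
#' @export
to_lowercase <- function(text) tolower(text)

#' The packaged English stop-word list
#'
#' A pinned copy of the standard Snowball English stop-word list, shipped
#' with the package so that results are reproducible independent of any
#' external resource.
#'
#' @return character vector of stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "probfs")
  readLines(path, encoding = "UTF-8")
}

#' Remove stop words from a token vector
#'
#' @param tokens character vector of tokens.
#' @param stopwords character vector; defaults to [default_stopwords()].
#' @return the surviving tokens, original order preserved.
#' @export
remove_stopwords <- function(tokens, stopwords = default_stopwords()) {
  tokens[!tokens %in% stopwords]
}

#' Stem a token vector
#'
#' @param tokens character vector of lowercase tokens.
#' @param stemmer `"porter"` (see [porter_stem()]) or `"none"`.
#' @return stemmed tokens, mapped independently.
#' @export
stem_tokens <- function(tokens, stemmer = "porter") {
  switch(stemmer,
    porter = vapply(tokens, porter_stem, character(1L), USE.NAMES = FALSE),
    none = tokens,
    abort(paste0("unknown stemmer: '", stemmer, "'"))
  )
}

#' Preprocessing configuration
#'
#' Describes which cleaning steps run. Steps are always executed in the
#' canonical order punctuation -> numbers -> lowercase -> stopwords ->
#' stemming regardless of the order given.
#'
#' @param steps character subset of
#'   `c("punctuation", "numbers", "lowercase", "stopwords", "stemming")`.
#' @param stopwords stop-word list used when the `stopwords` step is active.
#' @param stemmer stemming scheme, `"porter"` or `"none"`.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(steps = .PIPELINE_STEPS,
                              stopwords = default_stopwords(),
                              stemmer = "porter") {
  bad <- setdiff(steps, .PIPELINE_STEPS)
  if (length(bad) > 0L) {
    abort(paste0("unknown preprocessing step(s): ", paste(bad, collapse = ", ")))
  }
  if (!stemmer %in% c("porter", "none")) {
    abort(paste0("unknown stemmer: '", stemmer, "'"))
  }
  structure(
    list(
      steps = intersect(.PIPELINE_STEPS, steps),  # canonical order
      stopwords = stopwords,
      stemmer = stemmer
    ),
    class = "preprocess_config"
  )
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat("<preprocess_config>\n")
  cat("  steps:   ", paste(x$steps, collapse = " -> "), "\n", sep = "")
  cat("  stopwords: ", length(x$stopwords), " words\n", sep = "")
  cat("  stemmer: ", x$stemmer, "\n", sep = "")
  invisible(x)
}

#' Clean one text into a token vector
#'
#' Applies the configured steps in canonical order to a single string, then
#' tokenizes on whitespace. Deterministic: the same input always yields the
#' same tokens. Input is normalized to Unicode NFC before cleaning.
#'
#' @param text length-one character vector (may be empty).
#' @param config a [preprocess_config()].
#' @return character vector of tokens (possibly empty).
#' @export
preprocess_text <- function(text, config = preprocess_config()) {
  stopifnot(length(text) == 1L)
  if (is.na(text)) text <- ""
  text <- enc2utf8(text)
  nfc <- tryCatch(stringi::stri_trans_nfc(text), error = function(e) text)
  text <- nfc
  if ("punctuation" %in% config$steps) text <- remove_punctuation(text)
  if ("numbers" %in% config$steps) text <- remove_numbers(text)
  if ("lowercase" %in% config$steps) text <- to_lowercase(text)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if ("stopwords" %in% config$steps) {
    tokens <- remove_stopwords(tokens, config$stopwords)
  }
  if ("stemming" %in% config$steps) tokens <- stem_tokens(tokens, config$stemmer)
  tokens
}

#' Preprocess a corpus
#'
#' Cleans every document of a corpus tibble and adds a `tokens` list-column
#' plus a `clean_text` column (tokens re-joined with single spaces). Row
#' order is preserved.
#'
#' @param data a data frame with one row per document.
#' @param text_col name of the raw-text column (default `"text"`).
#' @param config a [preprocess_config()].
#' @return the input as a tibble with `tokens` and `clean_text` columns.
#' @examples
#' corpus <- tibble::tibble(id = 1, text = "I need helpjust help me im crying so hard")
#' preprocess_corpus(corpus)$tokens[[1]]
#' @export
preprocess_corpus <- function(data, config = preprocess_config(),
                              text_col = "text") {
  stopifnot(is.data.frame(data), text_col %in% names(data))
  out <- as_tibble(data)
  out$tokens <- lapply(out[[text_col]], preprocess_text, config = config)
  out$clean_text <- vapply(out$tokens, paste, character(1L), collapse = " ")
  out
}
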