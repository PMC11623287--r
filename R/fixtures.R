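# Worked-example fixtures: the two-document sample corpus whose BoW and
# TF-IDF matrices are known in closed form, and four raw example posts.

.FIXTURE_56_TOKENS <- list(
  c("do", "feel", "good", "internet", "it", "really", "strangers", "when"),
  c("annoying", "its", "so", "swear")
)

.FIXTURE_4_POSTS <- tibble::tibble(
  id = 1:4,
  text = c(
    paste("Ex Wife Threatening SuicideRecently I left my wife for good",
          "because she has cheated on me twice and lied to me so much that I",
          "have decided to refuse to go back to her."),
    paste("Am I weird I don't get affected by compliments if it's coming",
          "from someone I know irl but I feel really good when internet",
          "strangers do it"),
    paste("Finally 2020 is almost over... So I can never hear “2020 has",
          "been a bad year” ever again. I swear to fucking God it's so",
          "annoying"),
    "I need helpjust help me im crying so hard"
  ),
  label = c("suicide", "non-suicide", "non-suicide", "suicide")
)

#' Load a worked-example fixture
#'
#' Two fixtures are registered:
#' \describe{
#'   \item{`"tables_5_6"`}{The two-document sample corpus with disjoint
#'     token sets of sizes 8 and 4 (each token once per document). Returns
#'     the documents plus the expected bag-of-words count matrix and the
#'     expected L2-normalized TF-IDF matrix over the sorted 12-term
#'     vocabulary: every nonzero TF-IDF weight is `1/sqrt(8)` = 0.353553 in
#'     document 0 and `1/sqrt(4)` = 0.5 in document 1, because all terms
#'     share the same idf. Stop-word removal is bypassed for this fixture
#'     (its token sets retain conventional stop words such as "do", "it",
#'     "when").}
#'   \item{`"table_4_posts"`}{Four raw example posts with their
#'     suicide/non-suicide labels, for exercising the cleaning pipeline.}
#' }
#'
#' @param name fixture name.
#' @return a list with elements `name`, `documents` (tibble) and, for
#'   `"tables_5_6"`, `vocabulary`, `expected_bow` and `expected_tfidf`.
#' @export
load_fixture <- function(name) {
  if (identical(name, "tables_5_6")) {
    tokens <- .FIXTURE_56_TOKENS
    terms <- sort(unlist(tokens))
    bow <- t(vapply(tokens, function(tk) as.numeric(terms %in% tk),
                    numeric(length(terms))))
    tfidf <- bow / sqrt(rowSums(bow))
    dimnames(bow) <- dimnames(tfidf) <- list(c("0", "1"), terms)
    docs <- tibble(
      id = c(0L, 1L),
      text = vapply(tokens, paste, character(1L), collapse = " "),
      tokens = tokens
    )
    return(list(name = name, documents = docs, vocabulary = terms,
                expected_bow = bow, expected_tfidf = tfidf))
  }
  if (identical(name, "table_4_posts")) {
    return(list(name = name, documents = .FIXTURE_4_POSTS))
  }
  abort(paste0("unknown fixture: '", name, "'"))
}
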