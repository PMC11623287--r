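# Porter stemmer (the classic 1980 suffix-stripping algorithm), implemented
# directly because no stemming library ships with the supported stack.
# Operates on single lowercase tokens; tokens shorter than 3 characters and
# tokens containing non-alphabetic characters are returned unchanged.

# Classify each character as consonant ("c") or vowel ("v").  "y" is a vowel
# exactly when preceded by a consonant (and a consonant at word start).
.porter_types <- function(chars) {
  n <- length(chars)
  types <- character(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      types[i] <- "v"
    } else if (ch == "y" && i > 1L && types[i - 1L] == "c") {
      types[i] <- "v"
    } else {
      types[i] <- "c"
    }
  }
  types
}

# The measure m of a stem: number of vowel-run/consonant-run alternations,
# i.e. m in the canonical form [C](VC)^m[V].
.porter_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  runs <- rle(.porter_types(strsplit(stem, "", fixed = TRUE)[[1L]]))$values
  sum(runs == "v" & c(runs[-1L], "x") == "c")
}

.porter_has_vowel <- function(stem) {
  nzchar(stem) && any(.porter_types(strsplit(stem, "", fixed = TRUE)[[1L]]) == "v")
}

# *d: ends with a double consonant.
.porter_double_c <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  a == b && utils::tail(.porter_types(strsplit(word, "", fixed = TRUE)[[1L]]), 1L) == "c"
}

# *o: ends consonant-vowel-consonant where the final consonant is not w, x, y.
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  types <- .porter_types(strsplit(word, "", fixed = TRUE)[[1L]])
  last <- substr(word, n, n)
  types[n - 2L] == "c" && types[n - 1L] == "v" && types[n] == "c" &&
    !(last %in% c("w", "x", "y"))
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# Apply the longest matching rule of a step.  rules is a data.frame-like list
# of (suffix, replacement, min_m); returns the word, changed or not.
.porter_rule_step <- function(word, suffixes, replacements, min_m) {
  ord <- order(-nchar(suffixes))
  for (j in ord) {
    suf <- suffixes[j]
    if (endsWith(word, suf)) {
      stem <- .chop(word, nchar(suf))
      if (.porter_m(stem) > min_m[j]) {
        return(paste0(stem, replacements[j]))
      }
      return(word)  # longest match decides; condition failed => no change
    }
  }
  word
}

.porter_step1a <- function(word) {
  if (endsWith(word, "sses")) return(paste0(.chop(word, 4L), "ss"))
  if (endsWith(word, "ies"))  return(paste0(.chop(word, 3L), "i"))
  if (endsWith(word, "ss"))   return(word)
  if (endsWith(word, "s"))    return(.chop(word, 1L))
  word
}

.porter_step1b <- function(word) {
  if (endsWith(word, "eed")) {
    stem <- .chop(word, 3L)
    if (.porter_m(stem) > 0L) return(paste0(stem, "ee"))
    return(word)
  }
  fired <- FALSE
  if (endsWith(word, "ed")) {
    stem <- .chop(word, 2L)
    if (.porter_has_vowel(stem)) { word <- stem; fired <- TRUE }
  } else if (endsWith(word, "ing")) {
    stem <- .chop(word, 3L)
    if (.porter_has_vowel(stem)) { word <- stem; fired <- TRUE }
  }
  if (fired) {
    if (endsWith(word, "at") || endsWith(word, "bl") || endsWith(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_double_c(word) &&
               !endsWith(word, "l") && !endsWith(word, "s") && !endsWith(word, "z")) {
      word <- .chop(word, 1L)
    } else if (.porter_m(word) == 1L && .porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }
  word
}

.porter_step1c <- function(word) {
  if (endsWith(word, "y") && .porter_has_vowel(.chop(word, 1L))) {
    word <- paste0(.chop(word, 1L), "i")
  }
  word
}

.step2_suf <- c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
                "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
                "iveness", "fulness", "ousness", "aliti", "iviti", "biliti")
.step2_rep <- c("ate", "tion", "ence", "ance", "ize", "able", "al",
                "ent", "e", "ous", "ize", "ate", "ate", "al",
                "ive", "ful", "ous", "al", "ive", "ble")

.step3_suf <- c("icate", "ative", "alize", "iciti", "ical", "ful", "ness")
.step3_rep <- c("ic", "", "al", "ic", "ic", "", "")

.step4_suf <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                "ous", "ive", "ize")

.porter_step4 <- function(word) {
  ord <- order(-nchar(.step4_suf))
  for (j in ord) {
    suf <- .step4_suf[j]
    if (endsWith(word, suf)) {
      stem <- .chop(word, nchar(suf))
      ok <- .porter_m(stem) > 1L
      if (suf == "ion") ok <- ok && (endsWith(stem, "s") || endsWith(stem, "t"))
      if (ok) return(stem)
      return(word)
    }
  }
  word
}

.porter_step5 <- function(word) {
  if (endsWith(word, "e")) {
    stem <- .chop(word, 1L)
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) word <- stem
  }
  if (.porter_m(word) > 1L && .porter_double_c(word) && endsWith(word, "l")) {
    word <- .chop(word, 1L)
  }
  word
}

#' Stem a single word with the Porter algorithm
#'
#' The classic five-step suffix-stripping scheme for English. Input is
#' expected to be a single lowercase token; tokens of fewer than three
#' characters or containing non-alphabetic characters pass through unchanged.
#'
#' @param word a length-one character vector.
#' @return the stemmed word.
#' @examples
#' porter_stem("crying")      # "cry"
#' porter_stem("relational")  # "relat"
#' @export
porter_stem <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (nchar(word) < 3L || grepl("[^a-z]", word)) return(word)
  word <- .porter_step1a(word)
  word <- .porter_step1b(word)
  word <- .porter_step1c(word)
  word <- .porter_rule_step(word, .step2_suf, .step2_rep, rep(0L, length(.step2_suf)))
  word <- .porter_rule_step(word, .step3_suf, .step3_rep, rep(0L, length(.step3_suf)))
  word <- .porter_step4(word)
  .porter_step5(word)
}
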