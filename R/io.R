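# Corpus I/O in the two-column delimited schema (No., Text, Class).

#' Read a labeled corpus from CSV
#'
#' Expects the conventional schema with an id column, a free-text column and
#' a binary class column; column names are configurable.
#'
#' @param path CSV file.
#' @param id_col,text_col,class_col column names in the file.
#' @return a tibble with columns `id`, `text`, `label`.
#' @export
read_corpus <- function(path, id_col = "No.", text_col = "Text",
                        class_col = "Class") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 encoding = "UTF-8")
  missing <- setdiff(c(id_col, text_col, class_col), names(df))
  if (length(missing) > 0L) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  tibble(id = df[[id_col]], text = as.character(df[[text_col]]),
         label = as.character(df[[class_col]]))
}

#' Write a corpus to CSV in the No./Text/Class schema
#'
#' @param data tibble with `id`, `text` and (optionally) `label` columns.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(data, path) {
  stopifnot(all(c("id", "text") %in% names(data)))
  out <- data.frame(
    `No.` = data$id, Text = data$text,
    Class = if ("label" %in% names(data)) data$label else NA,
    check.names = FALSE
  )
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write cleaned text alongside a corpus
#'
#' Writes one row per document with the preprocessed text (tokens joined by
#' single spaces) in place of the raw text, preserving row order.
#'
#' @param data a [preprocess_corpus()] result (has `clean_text`).
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_clean_corpus <- function(data, path) {
  stopifnot("clean_text" %in% names(data))
  out <- data
  out$text <- out$clean_text
  write_corpus(out[, setdiff(names(out), c("tokens", "clean_text"))], path)
}

#' Serialize an evaluation report
#'
#' JSON with the four metrics, the confusion counts and timings.
#'
#' @param report an `eval_report`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(
      model = report$model, averaging = report$averaging,
      n_test = report$n_test,
      accuracy = report$accuracy, precision = report$precision,
      recall = report$recall, f1 = report$f1,
      confusion = as.vector(report$confusion),
      confusion_order = "actual-major, sorted class order",
      fit_time = report$fit_time, predict_time = report$predict_time
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
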