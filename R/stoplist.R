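# Stopword lists: frequent, low-information words removed before counting.
#
# The list contents are data, not method: the package ships a standard
# English list under inst/extdata/ and accepts arbitrary user lists; study-
# specific amalgamations (e.g. a list augmented with the most frequent words
# of some large reference transcript) are supplied as extra files.

#' Construct a stoplist
#'
#' @param words Character vector; lowercased and deduplicated. Entries must
#'   contain no internal whitespace.
#' @param source_files Provenance paths the words came from.
#' @return An object of class `stoplist` with set-valued `words`.
#' @export
stoplist <- function(words = character(), source_files = character()) {
  words <- tolower(as.character(words))
  words <- words[nzchar(words)]
  if (any(grepl("\\s", words))) {
    rl_value_error("stoplist entries must not contain whitespace")
  }
  structure(list(words = unique(words), source_files = source_files),
            class = "stoplist")
}

#' @export
print.stoplist <- function(x, ...) {
  cat(sprintf("<stoplist> %d words from %d file(s)\n",
              length(x$words), length(x$source_files)))
  invisible(x)
}

#' An explicitly empty stoplist
#'
#' Running the pipeline with no stopword removal must be requested
#' explicitly; this sentinel is how. (Then every comment with at least one
#' word counts as complete.)
#' @return A `stoplist` with zero words.
#' @export
empty_stoplist <- function() stoplist(character(), character())

#' Load and merge stopword files
#'
#' Each file is UTF-8 plain text, one word per line; lines starting with
#' `#` are comments. The result is the lowercased, deduplicated union of all
#' files. An empty union is a configuration error — use [empty_stoplist()]
#' to opt out of stopword removal on purpose.
#'
#' @param paths Character vector of file paths (at least one).
#' @return A [stoplist()].
#' @export
load_stoplist <- function(paths) {
  if (length(paths) == 0) {
    rl_config_error(
      "no stopword files given; use empty_stoplist() to run without one")
  }
  words <- unlist(lapply(paths, function(p) {
    if (!file.exists(p)) rl_io_error(sprintf("no such stopword file: '%s'", p))
    lines <- readLines(p, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    unlist(strsplit(lines, "\\s+"))
  }))
  if (length(words) == 0) {
    rl_config_error(
      "stopword files contained no words; use empty_stoplist() to opt out")
  }
  stoplist(words, source_files = as.character(paths))
}

#' The bundled English stopword list
#'
#' A standard general-English list (articles, pronouns, auxiliaries,
#' prepositions, common adverbs) shipped with the package.
#' @return A [stoplist()].
#' @export
default_stoplist <- function() {
  load_stoplist(system.file("extdata", "stopwords_en.txt",
                            package = "reflexlens", mustWork = TRUE))
}
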