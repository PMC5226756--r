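# Unigram/bigram frequency tables and per-category top-k vocabularies.
#
# Bigrams are formed from adjacent content lemmas within one comment only —
# never across comment boundaries — and incomplete comments contribute
# nothing. Rank ties are broken lexicographically so every downstream
# quantity (in particular Jaccard similarity between top-k sets) is
# deterministic.

.as_lemma_list <- function(comments) {
  if (is.data.frame(comments)) {
    return(comments$content_lemmas[comments$complete])
  }
  if (inherits(comments, "processed_comment")) comments <- list(comments)
  lapply(comments, function(cm) {
    if (inherits(cm, "processed_comment")) {
      if (!cm$complete) character() else cm$content_lemmas
    } else {
      as.character(cm)
    }
  })
}

#' Count n-grams over processed comments
#'
#' @param comments A list of [preprocess_comment()] results (or bare lemma
#'   vectors), or a [preprocess_corpus()] data.frame (only its complete
#'   rows are counted).
#' @param n N-gram order, 1 or 2. Bigram keys join the two lemmas with a
#'   single space.
#' @return An object of class `frequency_table`: list with `n`, `counts`
#'   (named integer vector, every count >= 1) and `total = sum(counts)`.
#' @export
#' @examples
#' pc <- preprocess_comment("loss of consciousness", default_stoplist())
#' count_ngrams(list(pc), n = 2)$counts
count_ngrams <- function(comments, n) {
  if (!is_count(n, 1) || !n %in% c(1, 2)) {
    rl_value_error("`n` must be 1 or 2")
  }
  lem <- .as_lemma_list(comments)
  lem <- lem[lengths(lem) > 0]
  grams <- if (n == 1) {
    unlist(lem, use.names = FALSE)
  } else {
    unlist(lapply(lem, function(v) {
      if (length(v) < 2) return(character())
      paste(v[-length(v)], v[-1])
    }), use.names = FALSE)
  }
  counts <- if (length(grams) == 0) {
    integer()
  } else {
    tab <- table(grams)
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    cnt[order(-cnt, names(cnt), method = "radix")]
  }
  structure(list(n = as.integer(n), counts = counts,
                 total = sum(counts)),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> n=%d, %d distinct, total %d\n",
              x$n, length(x$counts), x$total))
  invisible(x)
}

#' Top-k n-grams of a frequency table
#'
#' Descending by count, ties broken lexicographically on the n-gram;
#' returns `min(k, distinct keys)` n-grams.
#'
#' @param table A `frequency_table`.
#' @param k Non-negative integer.
#' @return Character vector of ranked n-grams.
#' @export
top_k <- function(table, k) {
  if (!inherits(table, "frequency_table")) {
    rl_value_error("`table` must be a frequency_table")
  }
  if (!is_count(k, 0)) rl_value_error("`k` must be a non-negative integer")
  utils::head(names(table$counts), k)
}

#' Top-k vocabulary of one RIME category
#'
#' Pools the content lemmas of all completed comments whose shift rating is
#' exactly the given single base category — hybrid-rated shifts are
#' excluded — and takes the set of top-k unigrams.
#'
#' @param x A [corpus()] or a [preprocess_corpus()] data.frame (passing the
#'   latter avoids re-preprocessing when profiling several categories).
#' @param category A base RIME category name.
#' @param k Vocabulary size (required; pairwise Jaccard values depend on it).
#' @param stoplist A [stoplist()]; required when `x` is a corpus.
#' @return An object of class `vocab_set`: list with `category`, `k`,
#'   `lemmas` (character set of size `min(k, available)`) and `tie_note`
#'   describing any tie broken at rank k.
#' @export
category_vocabulary <- function(x, category, k, stoplist = NULL) {
  if (!is_string(category) || !category %in% rime_base_categories()) {
    rl_value_error(sprintf("'%s' is not a base RIME category", category))
  }
  if (!is_count(k, 1)) rl_value_error("`k` must be a positive integer")
  processed <- if (is.data.frame(x)) x else {
    if (is.null(stoplist)) rl_value_error("`stoplist` required for a corpus")
    preprocess_corpus(x, stoplist)
  }
  eligible <- processed$complete & !is.na(processed$category) &
    processed$category == category
  if (!any(eligible)) {
    rl_empty_category_error(sprintf(
      "no completed single-category comments rated '%s'", category))
  }
  tab <- count_ngrams(processed[eligible, , drop = FALSE], n = 1)
  lemmas <- top_k(tab, k)
  tie_note <- "no distinct n-grams"
  if (length(tab$counts) > 0) {
    if (length(tab$counts) <= k) {
      tie_note <- "all distinct unigrams included; no truncation at rank k"
    } else if (tab$counts[[k]] == tab$counts[[k + 1]]) {
      tied <- names(tab$counts)[tab$counts == tab$counts[[k]]]
      tie_note <- sprintf(
        "count %d tied at rank %d among {%s}; lexicographic order decided",
        tab$counts[[k]], k, paste(tied, collapse = ", "))
    } else {
      tie_note <- "no tie at rank k"
    }
  }
  structure(list(category = category, k = as.integer(k),
                 lemmas = lemmas, tie_note = tie_note),
            class = "vocab_set")
}

#' @export
print.vocab_set <- function(x, ...) {
  cat(sprintf("<vocab_set> %s: %d lemmas (k=%d)\n",
              x$category, length(x$lemmas), x$k))
  invisible(x)
}

#' Export a frequency table as TSV
#'
#' Two columns, `ngram` and `count`, descending by count (ties
#' lexicographic).
#'
#' @param table A `frequency_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_tsv <- function(table, path) {
  if (dir.exists(path)) rl_io_error(sprintf("'%s' is a directory", path))
  df <- data.frame(ngram = names(table$counts),
                   count = unname(table$counts))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
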