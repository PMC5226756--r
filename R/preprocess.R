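# The four-step text normalisation and the comment-completion predicate:
#   1. lowercase  2. tokenize  3. remove stopwords  4. lemmatize
#
# Stopword removal happens on surface tokens, before lemmatization, so an
# inflected variant of a stopword that is not itself listed survives; an
# optional post-lemmatization second pass (off by default) removes lemmas
# that are themselves stopwords. A comment is "complete" when at least one
# word survives stopword removal.

#' Preprocess one comment
#'
#' @param raw Raw comment text (may be empty).
#' @param stoplist A [stoplist()] (use [empty_stoplist()] to skip removal).
#' @param engine Lemmatizer engine, see [lemmatize()].
#' @param post_lemma_stopwords If `TRUE`, run a second stopword pass on the
#'   lemmas (default `FALSE`).
#' @return An object of class `processed_comment`: list with `raw_text`,
#'   `tokens` (all lowercase word tokens), `content_lemmas` (lemmas of the
#'   tokens surviving stopword removal, order preserved) and `complete`
#'   (`TRUE` iff at least one content lemma remains).
#' @export
#' @examples
#' pc <- preprocess_comment("Loss of consciousness.", default_stoplist())
#' pc$content_lemmas
#' pc$complete
preprocess_comment <- function(raw, stoplist, engine = c("morphy", "stem"),
                               post_lemma_stopwords = FALSE) {
  engine <- match.arg(engine)
  if (!inherits(stoplist, "stoplist")) {
    rl_value_error("`stoplist` must be a stoplist object")
  }
  batch <- preprocess_comments(raw, stoplist, engine = engine,
                               post_lemma_stopwords = post_lemma_stopwords)
  structure(
    list(raw_text = raw, tokens = batch$tokens[[1]],
         content_lemmas = batch$content_lemmas[[1]],
         complete = batch$complete[[1]]),
    class = "processed_comment"
  )
}

#' @export
print.processed_comment <- function(x, ...) {
  cat(sprintf("<processed_comment> %d tokens, %d content lemmas, complete=%s\n",
              length(x$tokens), length(x$content_lemmas), x$complete))
  invisible(x)
}

#' Preprocess many comments at once
#'
#' Vectorised batch path used throughout the package. Tagging context (the
#' previous token) is taken within each comment after stopword removal,
#' matching the scalar pipeline order.
#'
#' @param texts Character vector of raw comments.
#' @inheritParams preprocess_comment
#' @return A list with parallel elements `tokens` (list), `content_lemmas`
#'   (list), `n_tokens` (integer) and `complete` (logical).
#' @export
preprocess_comments <- function(texts, stoplist, engine = "morphy",
                                post_lemma_stopwords = FALSE) {
  if (!inherits(stoplist, "stoplist")) {
    rl_value_error("`stoplist` must be a stoplist object")
  }
  toks <- tokenize_many(texts)
  lens <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  if (is.null(flat)) flat <- character()
  cid <- rep.int(seq_along(toks), lens)

  keep <- !(flat %in% stoplist$words)
  flat2 <- flat[keep]
  cid2 <- cid[keep]
  if (length(flat2) > 0) {
    prev <- c("", flat2[-length(flat2)])
    prev[!duplicated(cid2)] <- "" # comment starts have no context
    pos <- .pos_tag_vec(flat2, prev)
    lem <- lemmatize_vec(flat2, pos, engine = engine)
    if (post_lemma_stopwords) {
      keep2 <- !(lem %in% stoplist$words)
      lem <- lem[keep2]
      cid2 <- cid2[keep2]
    }
  } else {
    lem <- character()
  }
  f <- factor(cid2, levels = seq_along(toks))
  content <- split(lem, f)
  names(content) <- NULL
  list(tokens = toks,
       content_lemmas = content,
       n_tokens = as.integer(lens),
       complete = lengths(content) >= 1L)
}

#' Preprocess every shift of a corpus
#'
#' @param x A [corpus()].
#' @inheritParams preprocess_comment
#' @return A data.frame with one row per shift: `student_id`, `shift_index`,
#'   `final_grade`, `rating` (canonical label or `NA`), `hybrid` (logical,
#'   `NA` when unrated), `category` (the single base category for
#'   non-hybrid ratings, else `NA`), `n_tokens`, `complete`, and the list
#'   column `content_lemmas`.
#' @export
preprocess_corpus <- function(x, stoplist, engine = "morphy",
                              post_lemma_stopwords = FALSE) {
  df <- corpus_shifts(x)
  batch <- preprocess_comments(df$comment, stoplist, engine = engine,
                               post_lemma_stopwords = post_lemma_stopwords)
  rated <- nzchar(df$rating)
  hybrid <- ifelse(rated, grepl("-", df$rating, fixed = TRUE), NA)
  out <- data.frame(
    student_id = df$student_id,
    shift_index = df$shift_index,
    final_grade = df$final_grade,
    rating = ifelse(rated, df$rating, NA_character_),
    hybrid = hybrid,
    category = ifelse(rated & !vapply(hybrid, isTRUE, logical(1)),
                      df$rating, NA_character_),
    n_tokens = batch$n_tokens,
    complete = batch$complete,
    stringsAsFactors = FALSE
  )
  out$content_lemmas <- batch$content_lemmas
  out
}
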