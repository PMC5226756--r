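# Tokenization: lowercase first, then split into word-character runs.
#
# Deterministic regular-expression tokenizer (not a learned model): suited
# to transcribed free text without emoticons or heavy contraction use.
# Punctuation-only material is discarded and intra-word separators split
# the token, so "c/o" -> c, o and "s/p" -> s, p.

#' Tokenize a comment
#'
#' Lowercases the text and extracts maximal runs of word characters
#' (`[a-z0-9_]`). The empty string yields an empty token vector.
#'
#' @param text A single string.
#' @return Character vector of lowercase tokens, in order.
#' @export
#' @examples
#' tokenize("Loss of Consciousness.")
#' tokenize("chest pain, s/p fall")
tokenize <- function(text) {
  if (!is.character(text) || length(text) != 1) {
    rl_value_error("`text` must be a single string")
  }
  tokenize_many(text)[[1]]
}

#' @rdname tokenize
#' @param texts Character vector of comments.
#' @return `tokenize_many()`: a list of token vectors, one per input.
#' @export
tokenize_many <- function(texts) {
  texts <- as.character(texts)
  texts[is.na(texts)] <- ""
  m <- gregexpr("[a-z0-9_]+", tolower(texts), perl = TRUE)
  regmatches(tolower(texts), m)
}
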