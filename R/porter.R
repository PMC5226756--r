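# Porter stemmer: the opt-in derivational backend for lemmatization.
#
# Classic five-step suffix-stripping algorithm over the measure
# [C](VC)^m[V] of a word. Unlike the inflectional default engine it also
# removes derivational suffixes, so infection/infections/infected/infect
# all reduce to "infect".

.p_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1) return(TRUE)
    return(!.p_is_cons(chars, i - 1)) # y after a consonant acts as a vowel
  }
  TRUE
}

.p_cons_mask <- function(word) {
  chars <- strsplit(word, "")[[1]]
  vapply(seq_along(chars), function(i) .p_is_cons(chars, i), logical(1))
}

.p_measure <- function(word) {
  if (!nzchar(word)) return(0L)
  m <- .p_cons_mask(word)
  # count VC transitions
  sum(!m[-length(m)] & m[-1])
}

.p_has_vowel <- function(word) {
  if (!nzchar(word)) return(FALSE)
  any(!.p_cons_mask(word))
}

.p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1)
  b <- substr(word, n, n)
  a == b && .p_cons_mask(word)[n]
}

.p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  m <- .p_cons_mask(word)
  last <- substr(word, n, n)
  m[n] && !m[n - 1] && m[n - 2] && !last %in% c("w", "x", "y")
}

.p_ends <- function(word, suffix) {
  nchar(word) > nchar(suffix) && endsWith(word, suffix)
}

.p_stem_of <- function(word, suffix) substr(word, 1, nchar(word) - nchar(suffix))

# replace the first matching suffix whose stem satisfies m > thresh
.p_rule_set <- function(word, rules, thresh) {
  for (i in seq(1, length(rules), by = 2)) {
    suf <- rules[[i]]
    if (.p_ends(word, suf)) {
      stem <- .p_stem_of(word, suf)
      if (.p_measure(stem) > thresh) return(paste0(stem, rules[[i + 1]]))
      return(word) # longest match found; condition failed, stop
    }
  }
  word
}

#' Porter stem of a word
#'
#' @param word A single lowercase token.
#' @return The stemmed token.
#' @export
#' @examples
#' porter_stem("infections")
porter_stem <- function(word) {
  if (!is_string(word)) rl_value_error("`word` must be a single string")
  if (nchar(word) <= 2 || grepl("[^a-z]", word)) return(word)

  # step 1a
  w <- word
  if (endsWith(w, "sses")) w <- substr(w, 1, nchar(w) - 2)
  else if (endsWith(w, "ies")) w <- paste0(substr(w, 1, nchar(w) - 3), "i")
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- substr(w, 1, nchar(w) - 1)

  # step 1b
  cleanup <- FALSE
  if (.p_ends(w, "eed")) {
    if (.p_measure(.p_stem_of(w, "eed")) > 0) w <- substr(w, 1, nchar(w) - 1)
  } else if (.p_ends(w, "ed") && .p_has_vowel(.p_stem_of(w, "ed"))) {
    w <- .p_stem_of(w, "ed"); cleanup <- TRUE
  } else if (.p_ends(w, "ing") && .p_has_vowel(.p_stem_of(w, "ing"))) {
    w <- .p_stem_of(w, "ing"); cleanup <- TRUE
  }
  if (cleanup) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1, nchar(w) - 1)
    } else if (.p_measure(w) == 1 && .p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (.p_ends(w, "y") && .p_has_vowel(.p_stem_of(w, "y"))) {
    w <- paste0(substr(w, 1, nchar(w) - 1), "i")
  }

  # step 2 (m > 0)
  w <- .p_rule_set(w, list(
    "ational", "ate", "tional", "tion", "enci", "ence", "anci", "ance",
    "izer", "ize", "abli", "able", "alli", "al", "entli", "ent", "eli", "e",
    "ousli", "ous", "ization", "ize", "ation", "ate", "ator", "ate",
    "alism", "al", "iveness", "ive", "fulness", "ful", "ousness", "ous",
    "aliti", "al", "iviti", "ive", "biliti", "ble"), 0)

  # step 3 (m > 0)
  w <- .p_rule_set(w, list(
    "icate", "ic", "ative", "", "alize", "al", "iciti", "ic", "ical", "ic",
    "ful", "", "ness", ""), 0)

  # step 4 (m > 1); "ion" only after s/t
  matched <- FALSE
  for (suf in c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
                "al", "er", "ic", "ou")) {
    if (.p_ends(w, suf)) {
      stem <- .p_stem_of(w, suf)
      ok <- .p_measure(stem) > 1 &&
        (suf != "ion" || substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))
      if (ok) w <- stem
      matched <- TRUE
      break
    }
  }

  # step 5a
  if (endsWith(w, "e")) {
    stem <- substr(w, 1, nchar(w) - 1)
    m <- .p_measure(stem)
    if (m > 1 || (m == 1 && !.p_cvc(stem))) w <- stem
  }
  # step 5b
  if (.p_measure(w) > 1 && .p_double_cons(w) && endsWith(w, "l")) {
    w <- substr(w, 1, nchar(w) - 1)
  }
  w
}
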