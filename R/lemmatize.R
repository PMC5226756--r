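# Lemmatization: map inflected forms to a base form.
#
# The default engine is a self-contained morphy-style inflectional
# lemmatizer: per-POS suffix-detachment rules plus exception tables, with
# guard heuristics (don't strip -s after -ss/-us/-is, undouble a doubled
# final consonant, restore a dropped final -e after soft consonants)
# standing in for dictionary validation. Tokens no rule or exception
# matches pass through unchanged, so out-of-lexicon symbols are stable.
# Inflectional lemmatization keeps "infection" distinct from "infect";
# collapsing derivational morphology like that needs the opt-in Porter
# stemmer engine ("stem").

.noun_exceptions <- c(
  men = "man", women = "woman", children = "child", feet = "foot",
  teeth = "tooth", mice = "mouse", people = "person", lives = "life",
  criteria = "criterion", diagnoses = "diagnosis", crises = "crisis",
  analyses = "analysis", series = "series", species = "species",
  news = "news", staff = "staff"
)

.verb_exceptions <- c(
  was = "be", were = "be", is = "be", are = "be", am = "be", been = "be",
  being = "be", has = "have", had = "have", did = "do", done = "do",
  went = "go", gone = "go", saw = "see", seen = "see", felt = "feel",
  ran = "run", took = "take", taken = "take", thought = "think",
  taught = "teach", said = "say", made = "make", got = "get",
  gotten = "get", gave = "give", given = "give", came = "come",
  knew = "know", known = "know", found = "find", told = "tell",
  kept = "keep", learnt = "learn", met = "meet", spoke = "speak",
  spoken = "speak", wrote = "write", written = "write", began = "begin",
  begun = "begin", wore = "wear", worn = "wear"
)

.adjective_exceptions <- c(better = "good", best = "good", worse = "bad",
                           worst = "bad", less = "less", least = "less")

.vowels <- c("a", "e", "i", "o", "u")

# after stripping -ed/-ing/-er/-est: undouble a doubled final consonant
# (except ll/ss/zz/ff), else restore -e after a soft consonant preceded by
# a vowel (manag -> manage, notic -> notice, us -> use).
.fix_stripped_stem <- function(stem) {
  n <- nchar(stem)
  if (n >= 3) {
    last <- substr(stem, n, n)
    prev <- substr(stem, n - 1, n - 1)
    if (last == prev && !last %in% .vowels && !last %in% c("l", "s", "z", "f")) {
      return(substr(stem, 1, n - 1))
    }
  }
  if (n >= 2) {
    last <- substr(stem, n, n)
    prev <- substr(stem, n - 1, n - 1)
    if (last %in% c("c", "g", "s", "v", "z", "u") && prev %in% .vowels) {
      return(paste0(stem, "e"))
    }
  }
  stem
}

.lemmatize_noun <- function(w) {
  hit <- .noun_exceptions[w]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(w)
  if (n > 3 && endsWith(w, "sses")) return(substr(w, 1, n - 2))
  if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
  if (n > 3 && (endsWith(w, "xes") || endsWith(w, "zes") ||
                endsWith(w, "ches") || endsWith(w, "shes"))) {
    return(substr(w, 1, n - 2))
  }
  if (n > 3 && endsWith(w, "ses")) return(substr(w, 1, n - 1))
  if (n > 2 && endsWith(w, "s") &&
      !endsWith(w, "ss") && !endsWith(w, "us") && !endsWith(w, "is")) {
    return(substr(w, 1, n - 1))
  }
  w
}

.lemmatize_verb <- function(w) {
  hit <- .verb_exceptions[w]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(w)
  if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
  if (n > 3 && (endsWith(w, "xes") || endsWith(w, "zes") ||
                endsWith(w, "ches") || endsWith(w, "shes") ||
                endsWith(w, "sses"))) {
    return(substr(w, 1, n - 2))
  }
  if (n > 2 && endsWith(w, "s") && !endsWith(w, "ss") &&
      !endsWith(w, "us") && !endsWith(w, "is")) {
    return(substr(w, 1, n - 1))
  }
  if (n > 3 && endsWith(w, "ed")) {
    if (substr(w, n - 2, n - 2) == "e") return(substr(w, 1, n - 1)) # -eed, agreed
    return(.fix_stripped_stem(substr(w, 1, n - 2)))
  }
  if (n > 4 && endsWith(w, "ing")) {
    return(.fix_stripped_stem(substr(w, 1, n - 3)))
  }
  w
}

.lemmatize_adjective <- function(w) {
  hit <- .adjective_exceptions[w]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(w)
  if (n > 4 && endsWith(w, "iest")) return(paste0(substr(w, 1, n - 4), "y"))
  if (n > 3 && endsWith(w, "ier")) return(paste0(substr(w, 1, n - 3), "y"))
  if (n > 4 && endsWith(w, "est")) return(.fix_stripped_stem(substr(w, 1, n - 3)))
  if (n > 3 && endsWith(w, "er")) return(.fix_stripped_stem(substr(w, 1, n - 2)))
  w
}

.lemmatize_word <- function(token, pos) {
  switch(pos,
         noun = .lemmatize_noun(token),
         verb = .lemmatize_verb(token),
         adjective = .lemmatize_adjective(token),
         token)
}

#' Lemmatize POS-tagged tokens
#'
#' @param tagged A data.frame with columns `token` and `pos`, as produced by
#'   [pos_tag()].
#' @param engine `"morphy"` (default): inflectional suffix-detachment
#'   lemmatizer keyed by the coarse POS; `"stem"`: the Porter stemmer
#'   (ignores POS), which additionally collapses derivational morphology
#'   such as infection -> infect.
#' @return Character vector of lemmas, in token order.
#' @export
#' @examples
#' lemmatize(pos_tag(c("patients")))
#' lemmatize(data.frame(token = "infections", pos = "noun"), engine = "stem")
lemmatize <- function(tagged, engine = c("morphy", "stem")) {
  engine <- match.arg(engine)
  if (!is.data.frame(tagged) || !all(c("token", "pos") %in% names(tagged))) {
    rl_value_error("`tagged` must be a data.frame with columns token, pos")
  }
  lemmatize_vec(tagged$token, tagged$pos, engine)
}

# Vectorised path with a unique-(token, pos) cache.
lemmatize_vec <- function(tokens, pos, engine = "morphy") {
  if (length(tokens) == 0) return(character())
  key <- paste(tokens, pos, sep = "\r")
  uk <- !duplicated(key)
  lem <- if (engine == "stem") {
    vapply(tokens[uk], porter_stem, character(1), USE.NAMES = FALSE)
  } else {
    mapply(.lemmatize_word, tokens[uk], pos[uk], USE.NAMES = FALSE)
  }
  lem[match(key, key[uk])]
}
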