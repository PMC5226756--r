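# Coarse part-of-speech tagging.
#
# A compact rule-plus-lexicon tagger over the five coarse classes the
# lemmatizer distinguishes: noun, verb, adjective, adverb, other. Closed-
# class words (determiners, pronouns, prepositions, auxiliaries, numbers)
# tag as "other"; small open-class lexicons catch frequent clinical and
# educational words; suffix rules and one contextual rule (a word in -ing
# right after an auxiliary is a verb) cover the rest; unknown words default
# to noun, the safest class for lemmatization ("patient"/"patients" only
# collapse when "patient" is a noun). The tagger's outputs on the test
# fixtures are frozen in the test suite so any rule change is caught.

.rl_closed_class <- c(
  "a", "an", "the", "this", "that", "these", "those", "some", "any", "no",
  "each", "every", "either", "neither", "both", "all", "few", "many", "much",
  "more", "most", "other", "another", "such", "own", "same",
  "i", "me", "my", "mine", "myself", "we", "us", "our", "ours", "ourselves",
  "you", "your", "yours", "yourself", "he", "him", "his", "she", "her",
  "hers", "it", "its", "they", "them", "their", "theirs", "themselves",
  "who", "whom", "whose", "what", "which", "when", "where", "why", "how",
  "and", "or", "but", "nor", "so", "yet", "if", "because", "although",
  "though", "while", "whereas", "unless", "since", "until", "than", "as",
  "of", "in", "on", "at", "by", "for", "with", "without", "about", "against",
  "between", "among", "into", "onto", "through", "during", "before", "after",
  "above", "below", "under", "over", "up", "down", "out", "off", "to",
  "from", "toward", "towards", "upon", "per", "via",
  "am", "is", "are", "was", "were", "be", "been", "being",
  "do", "does", "did", "done", "have", "has", "had", "having",
  "will", "would", "shall", "should", "may", "might", "must", "can", "could",
  "not", "nt", "there", "here", "also", "too", "then", "now", "just",
  "one", "two", "three", "four", "five", "six", "seven", "eight", "nine",
  "ten", "first", "second", "third"
)

.rl_aux <- c("am", "is", "are", "was", "were", "be", "been", "being",
             "have", "has", "had", "having", "will", "would", "shall",
             "should", "may", "might", "must", "can", "could", "not")

.rl_verb_lexicon <- c(
  "learn", "learned", "learns", "learnt", "feel", "feels", "felt", "see",
  "sees", "saw", "seen", "think", "thinks", "thought", "know", "knows",
  "knew", "known", "manage", "managed", "manages", "treat", "treated",
  "treats", "present", "presented", "presents", "examine", "examined",
  "examines", "order", "ordered", "admit", "admitted", "admits",
  "discharge", "discharged", "ask", "asked", "asks", "help", "helped",
  "helps", "work", "worked", "works", "write", "wrote", "written", "read",
  "take", "takes", "took", "taken", "go", "goes", "went", "gone", "make",
  "makes", "made", "get", "gets", "got", "gotten", "give", "gives", "gave",
  "given", "come", "comes", "came", "say", "says", "said", "tell", "tells",
  "told", "teach", "teaches", "taught", "find", "finds", "found", "keep",
  "keeps", "kept", "use", "used", "uses", "need", "needed", "needs",
  "want", "wanted", "wants", "try", "tried", "tries", "run", "runs", "ran",
  "expect", "expected", "reflect", "reflected", "reflects", "improve",
  "improved", "improves", "perform", "performed", "performs", "diagnose",
  "diagnosed", "suture", "sutured", "intubate", "intubated", "infect",
  "infected", "infects"
)

.rl_adjective_lexicon <- c(
  "good", "great", "bad", "new", "old", "young", "high", "low", "long",
  "short", "big", "small", "difficult", "easy", "hard", "busy", "sick",
  "stable", "unstable", "acute", "chronic", "severe", "mild", "challenging",
  "interesting", "unexpected", "important", "useful", "helpful", "clinical",
  "medical", "abdominal", "cardiac", "respiratory", "legible", "illegible"
)

.rl_adverb_lexicon <- c(
  "very", "well", "never", "always", "often", "sometimes", "again", "soon",
  "later", "early", "late", "quite", "rather", "almost", "enough", "still"
)

# words in -ly that are not adverbs
.rl_ly_exceptions <- c("family", "apply", "reply", "supply", "rely", "fly",
                       "belly", "likely", "only", "early")

# words in -ed that are not verb forms
.rl_ed_exceptions <- c("bed", "red", "hundred", "sacred", "wicked", "med")

#' Coarse part-of-speech tagging
#'
#' Tags every token with one of `noun`, `verb`, `adjective`, `adverb`,
#' `other`; unknown words default to noun. The one contextual rule uses the
#' previous token in the sequence: a word ending in `-ing` or `-ed` directly
#' after an auxiliary is tagged verb ("patients were running").
#'
#' @param tokens Character vector of lowercase tokens (one comment, in
#'   order).
#' @return A data.frame with columns `token` and `pos`.
#' @export
#' @examples
#' pos_tag(tokenize("patients were running"))
pos_tag <- function(tokens) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0) {
    return(data.frame(token = character(), pos = character(),
                      stringsAsFactors = FALSE))
  }
  prev <- c("", tokens[-length(tokens)])
  data.frame(token = tokens, pos = .pos_tag_vec(tokens, prev),
             stringsAsFactors = FALSE)
}

# Vectorised rule engine; `prev` is the preceding token within the same
# comment ("" at a comment start).
.pos_tag_vec <- function(tokens, prev) {
  pos <- rep("noun", length(tokens))
  n <- nchar(tokens)

  pos[endsWith(tokens, "ly") & n > 3 & !(tokens %in% .rl_ly_exceptions)] <- "adverb"
  pos[endsWith(tokens, "ed") & n > 3 & !(tokens %in% .rl_ed_exceptions)] <- "verb"
  ing <- endsWith(tokens, "ing") & n > 4
  pos[ing & prev %in% .rl_aux] <- "verb"

  pos[tokens %in% .rl_adverb_lexicon] <- "adverb"
  pos[tokens %in% .rl_adjective_lexicon] <- "adjective"
  pos[tokens %in% .rl_verb_lexicon] <- "verb"
  pos[tokens %in% .rl_closed_class] <- "other"
  pos[grepl("^[0-9]", tokens)] <- "other"
  pos
}
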