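# Normalisation pipeline: stoplists, tokenization, tagging, lemmatization,
# and the completion predicate.

test_that("load_stoplist unions, lowercases and deduplicates files", {
  f1 <- tempfile(); writeLines(c("the", "of"), f1)
  f2 <- tempfile(); writeLines(c("# a comment", "of", "And"), f2)
  sl <- load_stoplist(c(f1, f2))
  expect_setequal(sl$words, c("the", "of", "and"))
  expect_length(sl$source_files, 2)
})

test_that("an accidental empty stoplist is a configuration error", {
  expect_error(load_stoplist(character()), class = "rl_config_error")
  empty <- tempfile(); writeLines("# only comments", empty)
  expect_error(load_stoplist(empty), class = "rl_config_error")
  # the explicit opt-out sentinel works
  pc <- preprocess_comment("the of", empty_stoplist())
  expect_true(pc$complete)
})

test_that("tokenize lowercases, strips punctuation and splits word runs", {
  expect_equal(tokenize("Loss of Consciousness."),
               c("loss", "of", "consciousness"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("..."), character())
  # intra-word separators split: the word-character-run rule
  expect_equal(tokenize("chest pain, s/p fall"),
               c("chest", "pain", "s", "p", "fall"))
  expect_equal(tokenize("c/o headache x3 days"),
               c("c", "o", "headache", "x3", "days"))
})

test_that("coarse POS tagging follows its frozen rules", {
  expect_equal(pos_tag("patient")$pos, "noun")
  expect_equal(nrow(pos_tag(character())), 0)
  # frozen tagger output on the fixed context phrase
  tagged <- pos_tag(tokenize("patients were running"))
  expect_equal(tagged$pos, c("noun", "other", "verb"))
  # unknown words default to noun
  expect_equal(pos_tag("xyzzy")$pos, "noun")
  expect_equal(pos_tag(c("quickly", "difficult", "the", "felt"))$pos,
               c("adverb", "adjective", "other", "verb"))
})

test_that("lemmatization removes inflectional suffixes by POS", {
  expect_equal(lemmatize(data.frame(token = "patients", pos = "noun")),
               "patient")
  expect_equal(lemmatize(data.frame(token = "infected", pos = "verb")),
               "infect")
  # out-of-lexicon passthrough
  expect_equal(lemmatize(data.frame(token = "xyzzy", pos = "noun")),
               "xyzzy")
  # guards: -ss and -us nouns are not plural
  expect_equal(lemmatize(data.frame(token = c("loss", "consciousness",
                                              "status"),
                                    pos = "noun")),
               c("loss", "consciousness", "status"))
  expect_equal(lemmatize(data.frame(token = c("injuries", "boxes", "was"),
                                    pos = c("noun", "noun", "verb"))),
               c("injury", "box", "be"))
  expect_equal(lemmatize(data.frame(token = c("running", "managed"),
                                    pos = "verb")),
               c("run", "manage"))
})

test_that("the Porter backend collapses derivational morphology", {
  tagged <- data.frame(token = c("infection", "infections", "infected",
                                 "infect"), pos = "noun")
  expect_equal(unique(lemmatize(tagged, engine = "stem")), "infect")
  # classic reference pairs
  expect_equal(porter_stem("caresses"), "caress")
  expect_equal(porter_stem("ponies"), "poni")
  expect_equal(porter_stem("relational"), "relat")
  expect_equal(porter_stem("hopeful"), "hope")
  expect_equal(porter_stem("w00042"), "w00042") # symbols pass through
})

test_that("preprocess_comment applies the four steps in order", {
  sl <- mini_stoplist()
  pc <- preprocess_comment("loss of consciousness", sl)
  expect_equal(pc$content_lemmas, c("loss", "consciousness"))
  expect_true(pc$complete)
  expect_equal(pc$tokens, c("loss", "of", "consciousness"))

  expect_false(preprocess_comment("", sl)$complete)
  # all stopwords -> incomplete even though tokens exist
  all_stop <- preprocess_comment("the and of", stoplist(c("the", "and", "of")))
  expect_equal(all_stop$content_lemmas, character())
  expect_false(all_stop$complete)
})

test_that("every content lemma derives from a non-stopword token", {
  sl <- default_stoplist()
  texts <- c("The patients were running to the resus bay",
             "Saw a c/o chest pain and felt unsure of the plan",
             "loss of consciousness", "", "the the the")
  for (txt in texts) {
    pc <- preprocess_comment(txt, sl)
    kept <- pc$tokens[!(pc$tokens %in% sl$words)]
    expect_length(pc$content_lemmas, length(kept))
  }
})

test_that("re-preprocessing the content lemmas never grows the lemma count", {
  sl <- default_stoplist()
  set.seed(31)
  vocab <- c("patient", "patients", "chest", "pain", "the", "of", "felt",
             "learning", "manage", "managed", "w0007")
  for (i in 1:25) {
    txt <- paste(sample(vocab, sample(0:8, 1), replace = TRUE),
                 collapse = " ")
    pc <- preprocess_comment(txt, sl)
    again <- preprocess_comment(paste(pc$content_lemmas, collapse = " "), sl)
    expect_lte(length(again$content_lemmas), length(pc$content_lemmas))
  }
})

test_that("completion is monotone in appended non-stopwords", {
  sl <- default_stoplist()
  texts <- c("", "the of", "chest pain", "the patient")
  for (txt in texts) {
    before <- preprocess_comment(txt, sl)$complete
    after <- preprocess_comment(paste(txt, "triage"), sl)$complete
    expect_true(after >= before)
    expect_true(after) # a non-stopword always completes the comment
  }
})

test_that("the optional post-lemma stopword pass removes inflected variants", {
  # "patients" is not listed, so it survives the surface pass, but its
  # lemma "patient" is a stopword
  sl <- stoplist(c("patient"))
  keep <- preprocess_comment("patients", sl)
  expect_equal(keep$content_lemmas, "patient") # default: surface match only
  second <- preprocess_comment("patients", sl, post_lemma_stopwords = TRUE)
  expect_equal(second$content_lemmas, character())
  expect_false(second$complete)
})
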