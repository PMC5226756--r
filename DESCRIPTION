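Package: reflexlens
Title: Reflective-Writing Corpus Analysis for Clinical Clerkships
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing short post-shift reflective comments written
    by medical students during a clinical clerkship. Provides a corpus data
    model with readers and writers for CSV/JSONL shift records, a
    deterministic text-normalisation pipeline (lowercasing, regular-expression
    tokenization, stopword removal, part-of-speech-aware lemmatization with an
    optional Porter-stemmer backend), unigram/bigram frequency profiling by
    RIME evaluation category, Jaccard similarity between category vocabularies
    with an empirical label-resampling null, statistics linking reflection
    effort to final grade (Pearson correlation with t-test,
    Kolmogorov-Smirnov group comparison, notched-boxplot summaries), a
    multinomial naive Bayes bag-of-words classifier with stratified
    cross-validation, and a seeded synthetic-corpus generator carrying planted
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
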