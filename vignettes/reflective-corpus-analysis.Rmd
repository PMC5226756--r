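---
title: "Analysing reflective-writing corpora from clinical clerkships"
author: "reflexlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing reflective-writing corpora from clinical clerkships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexlens)
```

## The problem

During an emergency-medicine clerkship, students are asked to write a few
sentences of reflection after every shift, and an attending rates each shift
on the RIME ladder (Reporter < Interpreter < Manager < Educator, with
"Inadequate" below it; some evaluation forms relabel Educator as
"Superior"). Two questions follow naturally from such a corpus:

1. Does the *habit* of reflecting — how often a student writes anything
   substantive — track the final clerkship grade?
2. Do students at different RIME levels *talk differently* about their
   shifts, i.e. do the characteristic vocabularies of the rating categories
   differ more than chance relabelling would predict?

reflexlens implements the full analysis pipeline for both questions, plus a
bag-of-words classifier for predicting the rating from the comment, and a
synthetic-corpus generator that plants known structure so that every stage
can be validated end to end without any real (and necessarily private)
student data.

## Text normalisation

Each comment passes through four steps, in this order:

1. **Lowercasing.**
2. **Tokenization** — a deterministic regular-expression tokenizer takes
   maximal runs of word characters, so punctuation vanishes and intra-word
   separators split ("s/p" becomes `s`, `p`). A learned tokenizer would add
   nothing for transcribed prose without emoticons or heavy contractions,
   and would cost reproducibility.
3. **Stopword removal** on surface tokens. The bundled list is a standard
   general-English one; study-specific lists load from plain-text files and
   merge by union. Running with no stoplist at all must be requested
   explicitly via `empty_stoplist()` — an accidentally empty list is almost
   always a configuration bug, so it errors.
4. **Lemmatization**, keyed by a coarse part-of-speech tag. The tagger is a
   compact rule-plus-lexicon affair (closed-class words, small open-class
   lexicons, suffix rules, and one contextual rule: `-ing`/`-ed` directly
   after an auxiliary is a verb). Its outputs on the test fixtures are
   frozen in the test suite, so a rule change cannot slip through silently.
   The lemmatizer itself is a self-contained morphy-style suffix detacher
   with per-POS exception tables and guard heuristics (never strip `-s`
   after `-ss`/`-us`/`-is`, undouble doubled consonants, restore a dropped
   `-e` after soft consonants). Tokens no rule matches pass through
   unchanged, which keeps synthetic symbols like `w00042` stable.

A comment is **complete** when at least one token survives stopword
removal. Note two consequences of the step order: an inflected variant of a
stopword that is not itself listed survives (an optional post-lemmatization
second pass, `post_lemma_stopwords = TRUE`, removes such lemmas and is off
by default); and completion is judged before lemmatization can merge
anything away.

Inflectional lemmatization deliberately keeps *infection* distinct from
*infect*: collapsing derivational morphology is a stemmer's job, and an
opt-in Porter stemmer backend (`engine = "stem"`) is provided for analyses
that want `infection`, `infected` and `infect` pooled.

```{r}
preprocess_comment("Loss of Consciousness.", default_stoplist())$content_lemmas
lemmatize(data.frame(token = "infections", pos = "noun"))            # morphy
lemmatize(data.frame(token = "infections", pos = "noun"), "stem")    # Porter
```

## Vocabulary profiles and their similarity

Unigram and bigram tables pool the content lemmas of complete comments;
bigrams never cross a comment boundary. Ranking ties are broken
lexicographically — the paper-of-record for this kind of analysis rarely
states its tie rule, but silent nondeterminism would make every downstream
Jaccard value irreproducible, so the rule is explicit and the `tie_note`
field of a vocabulary records what happened at rank *k*.

A category's vocabulary is the top-*k* unigram set over the complete
comments rated *exactly* that single category: hybrid ratings (an attending
circled two adjacent categories) are excluded, as is "Inadequate" by
default in category-level analyses (typically far too few comments).
Because every similarity below depends on *k*, the similarity functions
have **no default k** — it must be chosen and reported.

For two categories A and B the observed similarity is the Jaccard index
`J = |V_A ∩ V_B| / |V_A ∪ V_B|`. Its significance comes from a resampling
null: pool the two categories' eligible comments, reassign them to two
groups of the original sizes without replacement, recompute both top-*k*
vocabularies and their Jaccard, repeat `B` times. Three design choices
deserve a word:

* **Resampling unit = comment**, not word token. Words within one comment
  are strongly dependent (one patient, one scenario); exchanging comments
  respects that dependence, exchanging tokens would destroy it.
* **Left tail.** The scientific question is whether vocabularies are *more
  distinct* than label exchange predicts, so small `p_left` flags low
  similarity: `p_left = (1 + #{J_null ≤ J_obs}) / (B + 1)`.
* **The +1/(B+1) correction** makes `p_left` a valid permutation p-value
  with resolution floor `1/(B+1)` and no exact zeros.

`pairwise_jaccard_matrix()` derives each pair's child seed from the master
seed and the *sorted* pair names, so the category order cannot affect any
result. Per-pair p-values are reported raw by default (matching how such
matrices are usually printed), with Holm adjustment behind a flag. `B`
defaults to 1,000.

## Reflection effort and the final grade

Per student: the completion fraction (complete comments over *all* shifts —
an empty row still counts in the denominator, because the rotation length,
not the writing habit, fixes it) and the mean comment length. Length counts
raw word tokens before stopword removal by default ("words as written");
the content-lemma convention is available via `length_basis = "content"`.

The association report contains, for both effort measures, the Pearson
correlation with the least-squares line and the t-test
`t = r·sqrt(n−2)/sqrt(1−r²)` on `n−2` df (two-tailed); the split into
completers (completion fraction **strictly** greater than 0.5 — "more than
half", so a student at exactly one half is a non-completer) and
non-completers; notched-boxplot summaries of the two grade distributions;
and a two-sample Kolmogorov–Smirnov comparison (exact p when both groups
have ≤ 25 students, asymptotic otherwise, via `stats::ks.test`).

All quantile-derived numbers use the linear-interpolation convention
(R type 7) and say so in the output. The notch is the standard
`median ± 1.57·IQR/√n` approximate 95% interval for the median; whiskers
sit at the 2nd and 97th percentiles.

## The classifier

`train_nb()` is a multinomial naive Bayes over content-lemma counts with
additive smoothing (α = 1 by default), trained on the same eligible set as
the category profiles (complete, single-category, Inadequate excluded).
`cv_evaluate()` runs stratified k-fold cross-validation, deterministic
given its seed. A class with fewer comments than folds raises a *typed*
stratification error — precisely the "insufficient data" condition such
studies report — and the pipeline downgrades it to a warning so every other
stage still completes.

## The synthetic generator

`generate_corpus()` emulates the study design: `n_students` × 14 shifts;
per-student completion propensity `Beta(a, b)`; each completed shift gets a
rating and a comment of Poisson-many tokens, a `stopword_fill` fraction of
which are stopwords and the rest Zipf-distributed words from the rating
category's pool. Every shift is rated (attendings evaluate regardless of
whether the student wrote), so rated-but-empty rows — a real transcription
outcome — are always exercised. Hybrid ratings appear at a configurable
rate (10% by default) so the exclusion paths always run.

Defaults were chosen once to echo the scale of the motivating study
design: 116 students, grades centred in the low 80s with a ~4-point gap
between completers and non-completers, completion-grade correlation near
0.3, Beta(2, 2) propensities (mean 0.5, wide spread across the completer
threshold), 9-token comments with half stopwords.

Vocabulary overlap: a scalar `overlap` makes that fraction of each
category pool a block common to *all* categories (1 = identical pools,
0 = disjoint); a matrix plants a dedicated shared block per category pair,
which is how a similarity *gradient* (e.g. Manager↔Educator high,
Reporter↔others low) is planted. Zipf rank assignment within a pool is a
seeded permutation derived from the pool's *content*, so identical pools
get identical sampling distributions — that is what makes the
`calibration` fixture's two categories genuinely exchangeable.

Grades are `clamp(intercept + slope·fraction + N(0, σ), 0, 100)`. Clamping
attenuates correlations, so when `target_corr` is requested the slope is
found by 1-D search on a 50,000-draw simulated population *after*
clamping; the planted value stays honest. A target the clamped scale
cannot reach raises an error rather than silently planting less.

What the generator does **not** emulate: real clinical language (words are
synthetic symbols), spelling noise, per-site or seasonal grade effects,
serial correlation between a student's shifts, or any dependence of the
rating on the comment text beyond the planted vocabulary. Passing tests on
synthetic corpora therefore validate the *machinery* — recovery of planted
correlations, overlaps and separability — not any claim about real
students.

```{r}
fx <- make_fixture("tiny")
fx$corpus
corpus_effort(fx$corpus, default_stoplist())[, c(1, 4, 6)]
```

## Numerical choices and degenerate inputs

* Ties at rank *k*: lexicographic, recorded in `tie_note`.
* Jaccard of two empty sets, zero-variance correlations, empty student
  lists, single-class training sets: typed errors, never NaN.
* `|r| = 1` in the correlation t-test returns an infinite-t sentinel with
  p = 0 instead of dividing by zero.
* Grades are stored as reals and never rounded at ingest; the generator
  rounds to 3 decimals only so that CSV round-trips are bit-exact.
* Child seeds derive from a 31-bit hash of (master seed, stage label), so
  all stages are reproducible from one `--seed` and unordered pairs hash
  order-independently.

## Scale of the validation suite

The test suite validates calibration and recovery at sizes chosen to give
tight binomial/sampling bounds while staying desk-sized: 200 replicate
corpora (B = 500) for null calibration of the similarity test, 100
replicates each of n = 300 students for correlation recovery at
ρ ∈ {0, 0.3, 0.5}, n = 400 students for the separability and
identical-pool extremes, and 1,000 fuzz cases per closed-form oracle.

One recovery caveat worth stating precisely: the sampling standard
deviation of a Pearson correlation is ≈ (1 − ρ²)/√n, i.e. 0.058 at ρ = 0
and n = 300, so even a perfectly calibrated generator puts only ~92% of
replicates within ±0.1 of the planted value there; a ±0.1 band with 95%
coverage needs n ≳ 385. Validation bands for r̂ at n = 300 should be read
with that floor in mind.

## Known limitations

* The tagger and lemmatizer are compact rule systems, not
  dictionary-backed NLP models; they are exact on the bundled fixtures and
  deliberately conservative elsewhere (unknown words pass through). Real
  clinical free text with heavy abbreviation would deserve a medical
  lexicon upstream; abbreviation expansion is out of scope (in the
  emulated workflow it is a human transcription step).
* The grade association is bivariate by design: no adjustment for site,
  season or specialty interest.
* The observed comments are not independent across shifts of one student;
  the similarity null exchanges comments, not students, and inherits that
  caveat when within-student dependence is strong.
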