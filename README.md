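# reflexlens

Analysis toolkit for **reflective-writing corpora from clinical
clerkships**: short free-text comments students write after each shift,
paired with per-shift RIME ratings (Reporter–Interpreter–Manager–Educator,
"Superior" accepted as an alias for Educator) and a final 0–100 clerkship
grade. It is written for medical-education researchers who want the whole
chain — text normalisation, vocabulary profiling, similarity testing,
grade association, classification — reproducible from one seed, and
testable end to end on synthetic corpora with planted ground truth.

## What it computes

* **Normalisation** — lowercase → regular-expression tokenization →
  stopword removal → POS-aware lemmatization (opt-in Porter stemmer
  backend). A comment is *complete* if at least one non-stopword survives.
* **Vocabulary profiles** — unigram/bigram tables (bigrams within a
  comment only) and top-*k* vocabularies per RIME category, hybrid ratings
  excluded, ties broken lexicographically and documented.
* **Vocabulary similarity** — Jaccard index
  `J(A, B) = |V_A ∩ V_B| / |V_A ∪ V_B|` between category vocabularies,
  with an empirical null built by reassigning the pooled comments to the
  two categories without replacement (preserving group sizes) and a
  left-tailed permutation p-value
  `p = (1 + #{J_null ≤ J_obs}) / (B + 1)` — small p means the categories'
  vocabularies are more distinct than label exchange predicts.
* **Grade association** — per-student completion fraction and mean comment
  length; Pearson `r` with `t = r√(n−2)/√(1−r²)`; completer
  (fraction > 1/2) vs non-completer split with notched-boxplot summaries
  (`median ± 1.57·IQR/√n`, whiskers at the 2nd/97th percentiles) and a
  two-sample Kolmogorov–Smirnov test `D = sup|F̂_a − F̂_b|`.
* **Classification** — multinomial naive Bayes on content-lemma counts
  with Laplace smoothing and stratified k-fold cross-validation; a class
  rarer than the fold count raises a typed "insufficient data" error.
* **Synthetic corpora** — `generate_corpus()` plants per-student completion
  propensities, a target completion–grade correlation (calibrated after
  grade clamping), category vocabularies with configurable pairwise
  overlap, Zipf word frequencies and stopword fill; `make_fixture()` ships
  frozen named designs (`tiny`, `calibration`, `separable`, `null`,
  `twin`).

Corpora load from CSV/TSV or JSONL (`student_id`, `shift_index`,
`comment`, `rating`, `final_grade`); `run_all()` writes a single JSON
report plus TSV tables. A thin CLI lives at `inst/cli/reflexlens.R`.

## Worked example

```r
library(reflexlens)

synth <- generate_corpus(synthetic_config(n_students = 60,
                                          target_corr = 0.32, seed = 7))
sl        <- default_stoplist()
processed <- preprocess_corpus(synth$corpus, sl)

assoc <- grade_association(processed)
round(c(r = assoc$r_completion, t = assoc$t_completion,
        p = assoc$p_completion), 4)
#>      r      t      p
#> 0.3680 3.0142 0.0038
```

Students who reflected on more of their shifts got higher grades: the
sample correlation between completion fraction and final grade is 0.37
(here the generator planted 0.32), and its t-test rejects at any usual
level. The completer/non-completer medians and the KS comparison of the
two grade distributions:

```r
round(c(completers = assoc$group_split$completers$median,
        noncompleters = assoc$group_split$noncompleters$median), 3)
#>    completers noncompleters
#>        85.014        81.292
round(c(D = assoc$ks_D, p = assoc$ks_p), 4)
#>      D      p
#> 0.3290 0.0927
```

Vocabulary distinctness between two rating categories (k must be chosen
explicitly; B resamples of the comment-exchange null):

```r
jaccard_test(processed, "Interpreter", "Manager", k = 50, B = 1000,
             seed = 11)
#> <jaccard_result> Interpreter-Manager: J = 0.3158, p_left = 0.000999 (k=50, B=1000)
```

The two top-50 vocabularies share fewer words than almost every null
reassignment (p at the 1/(B+1) floor): Interpreter- and Manager-rated
comments use genuinely different words, beyond what their shared core
vocabulary explains. Finally, the cross-validated naive Bayes recovers the
planted category separation:

```r
cv_evaluate(processed, folds = 5, seed = 3)$mean_accuracy
#> [1] 0.951
```

The methods vignette
(`vignettes/reflective-corpus-analysis.Rmd`) documents the model choices,
parameter defaults, and what synthetic-corpus results do and do not say
about real data.

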