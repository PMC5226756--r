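# End-to-end pipeline: preprocess -> n-gram tables -> Jaccard matrix ->
# grade association -> classifier, with every seed recorded in the report.
# A classifier stratification failure (a class rarer than the fold count —
# the "insufficient data" condition) is a logged warning, not a fatal
# error: every other section is still produced.

#' Pipeline run configuration
#'
#' @param corpus_path Path to a corpus file readable by [read_corpus()]
#'   (exactly one of `corpus_path` / `synthetic` must be given).
#' @param synthetic A [synthetic_config()] to generate the corpus instead.
#' @param stoplist_paths Stopword file paths; `NULL` uses the bundled
#'   English list; `character(0)` is rejected — pass an explicit
#'   [empty_stoplist()] via `stoplist` to disable removal.
#' @param stoplist A ready [stoplist()] overriding `stoplist_paths`.
#' @param top_k_unigram,top_k_bigram Table sizes for the overall frequency
#'   tables (defaults 50 and 9).
#' @param category_k Vocabulary size per RIME category; also the Jaccard
#'   `k` unless `jaccard_k` is given.
#' @param jaccard_k Vocabulary size used by the similarity stage.
#' @param bootstrap_B Resamples per category pair (default 1000).
#' @param split_threshold Completion split point (default 0.5).
#' @param folds,alpha Classifier cross-validation settings.
#' @param p_adjust Jaccard matrix p-value adjustment, `"none"` or `"holm"`.
#' @param length_basis See [student_effort()].
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for the JSON report and TSV tables;
#'   `NULL` computes everything in memory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(corpus_path = NULL, synthetic = NULL,
                       stoplist_paths = NULL, stoplist = NULL,
                       top_k_unigram = 50, top_k_bigram = 9,
                       category_k = 50, jaccard_k = NULL,
                       bootstrap_B = 1000, split_threshold = 0.5,
                       folds = 5, alpha = 1,
                       p_adjust = "none", length_basis = "raw",
                       seed = 1, out_dir = NULL) {
  if (is.null(corpus_path) == is.null(synthetic)) {
    rl_config_error("give exactly one of `corpus_path` or `synthetic`")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    rl_config_error("`synthetic` must come from synthetic_config()")
  }
  structure(
    list(corpus_path = corpus_path, synthetic = synthetic,
         stoplist_paths = stoplist_paths, stoplist = stoplist,
         top_k_unigram = top_k_unigram, top_k_bigram = top_k_bigram,
         category_k = category_k, jaccard_k = jaccard_k %||% category_k,
         bootstrap_B = bootstrap_B, split_threshold = split_threshold,
         folds = folds, alpha = alpha, p_adjust = p_adjust,
         length_basis = length_basis, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

.config_echo <- function(config) {
  keep <- setdiff(names(config), c("synthetic", "stoplist"))
  echo <- config[keep]
  if (!is.null(config$synthetic)) {
    sc <- unclass(config$synthetic)
    sc$category_probs <- as.list(sc$category_probs)
    if (is.matrix(sc$vocab$overlap)) {
      sc$vocab$overlap <- as.data.frame(sc$vocab$overlap)
    }
    echo$synthetic <- sc
  }
  echo
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured corpus and assembles the JSON
#' report (see [write_report()] for the schema). When `out_dir` is set the
#' report plus TSV exports (frequency tables, Jaccard matrix, per-student
#' effort) are written there. Identical configurations produce identical
#' reports apart from the timestamp.
#'
#' @param config A [run_config()].
#' @return The report list, invisibly when written to disk.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) {
    rl_value_error("`config` must come from run_config()")
  }
  stoplist <- config$stoplist %||% (
    if (is.null(config$stoplist_paths)) default_stoplist()
    else load_stoplist(config$stoplist_paths))

  corp <- if (!is.null(config$corpus_path)) {
    read_corpus(config$corpus_path)
  } else {
    generate_corpus(config$synthetic)$corpus
  }

  processed <- preprocess_corpus(corp, stoplist)
  eff <- corpus_effort(processed, length_basis = config$length_basis)

  preprocessing_summary <- list(
    n_students = nrow(eff),
    n_shifts = nrow(processed),
    n_complete = sum(processed$complete),
    completion_rate = mean(processed$complete),
    n_rated = sum(!is.na(processed$rating)),
    n_hybrid = sum(processed$hybrid %in% TRUE),
    stoplist_words = length(stoplist$words),
    total_tokens = sum(processed$n_tokens),
    total_content_lemmas = sum(lengths(processed$content_lemmas))
  )

  uni <- count_ngrams(processed, 1)
  bi <- count_ngrams(processed, 2)
  ngram_tables <- list(
    unigrams = .table_entries(uni, config$top_k_unigram),
    bigrams = .table_entries(bi, config$top_k_bigram)
  )

  cats_present <- intersect(rime_ladder(),
                            unique(stats::na.omit(
                              processed$category[processed$complete])))
  jaccard_section <- if (length(cats_present) >= 2) {
    jm <- pairwise_jaccard_matrix(
      processed, cats_present, k = config$jaccard_k, B = config$bootstrap_B,
      seed = derive_seed(config$seed, "jaccard"),
      p_adjust = config$p_adjust)
    list(k = jm$k, B = jm$B, seed = jm$seed,
         pairs = lapply(jm$results, function(r) {
           list(pair = paste(r$pair, collapse = "-"), J_obs = r$J_obs,
                p_left = r$p_left)
         }))
  } else {
    list(skipped = TRUE,
         reason = "fewer than 2 ladder categories with completed comments")
  }

  assoc <- grade_association(processed, threshold = config$split_threshold,
                             length_basis = config$length_basis)

  classifier_seed <- derive_seed(config$seed, "classifier")
  classifier <- tryCatch({
    cv <- cv_evaluate(processed, folds = config$folds,
                      seed = classifier_seed, alpha = config$alpha)
    list(folds = cv$folds, alpha = cv$alpha, seed = cv$seed, n = cv$n,
         fold_accuracy = cv$fold_accuracy,
         mean_accuracy = cv$mean_accuracy,
         confusion = .confusion_entries(cv$confusion))
  }, rl_stratification_error = function(e) {
    warning(sprintf("classifier skipped: %s", conditionMessage(e)),
            call. = FALSE)
    list(skipped = TRUE, reason = conditionMessage(e),
         seed = classifier_seed)
  })

  report <- list(
    preprocessing_summary = preprocessing_summary,
    ngram_tables = ngram_tables,
    jaccard_matrix = jaccard_section,
    grade_association = assoc,
    classifier = classifier,
    metadata = list(
      package = "reflexlens",
      version = as.character(utils::packageVersion("reflexlens")),
      seed = config$seed,
      config = .config_echo(config),
      generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$out_dir, "report.json"))
    write_frequency_tsv(uni, file.path(config$out_dir, "unigrams.tsv"))
    write_frequency_tsv(bi, file.path(config$out_dir, "bigrams.tsv"))
    utils::write.table(eff, file.path(config$out_dir, "student_effort.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (is.null(jaccard_section$skipped)) {
      jm <- do.call(rbind, lapply(jaccard_section$pairs, as.data.frame))
      utils::write.table(jm, file.path(config$out_dir, "jaccard_matrix.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    return(invisible(report))
  }
  report
}

.table_entries <- function(table, k) {
  grams <- top_k(table, k)
  list(k = k, total = table$total,
       entries = lapply(grams, function(g) {
         list(ngram = g, count = unname(table$counts[[g]]))
       }))
}

.confusion_entries <- function(confusion) {
  lapply(rownames(confusion), function(tr) {
    row <- as.list(confusion[tr, ])
    c(list(true = tr), row)
  })
}
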