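# Jaccard similarity between category vocabularies and its empirical
# significance under a label-resampling null.
#
# The resampling unit is the comment: the two categories' eligible comments
# are pooled and repeatedly reassigned to two groups of the original sizes
# without replacement, the top-k vocabularies and their Jaccard similarity
# recomputed each time. The p-value is left-tailed — a small p means the
# observed vocabularies are MORE DISTINCT (lower J) than label exchange
# predicts — with the +1/(B+1) correction that makes it a valid permutation
# p-value and keeps it away from zero.

#' Jaccard similarity of two sets
#'
#' `|A ∩ B| / |A ∪ B|`; symmetric; defined only when at least one set is
#' non-empty.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    rl_value_error("jaccard undefined for two empty sets")
  }
  length(intersect(a, b)) / length(union(a, b))
}

# top-k words of a count vector (parallel to `words`), count-desc then
# lexicographic; words with zero count are not part of the vocabulary.
.topk_counts <- function(counts, words, k) {
  present <- counts > 0
  w <- words[present]
  cnt <- counts[present]
  ord <- order(-cnt, w, method = "radix")
  w[ord[seq_len(min(k, length(w)))]]
}

.eligible_category_rows <- function(processed, category) {
  which(processed$complete & !is.na(processed$category) &
          processed$category == category)
}

#' Jaccard similarity test between two category vocabularies
#'
#' Computes the observed Jaccard similarity of the two categories' top-`k`
#' vocabularies (via [category_vocabulary()] on the real labels) and an
#' empirical null of `B` label-resamples; see the module notes above for
#' the null construction and tail direction.
#'
#' @param x A [corpus()] or [preprocess_corpus()] data.frame.
#' @param cat_a,cat_b Two distinct base RIME categories.
#' @param k Vocabulary size (required, never defaulted: J depends on it).
#' @param B Number of resamples, >= 1.
#' @param seed Integer seed; the result is fully reproducible from it.
#' @param stoplist A [stoplist()]; required when `x` is a corpus.
#' @return An object of class `jaccard_result`: list with `pair`, `J_obs`,
#'   `k`, `B`, `null_J` (length-`B` numeric), `p_left` and `seed`, where
#'   `p_left = (1 + #\{null_J <= J_obs\}) / (B + 1)`.
#' @export
jaccard_test <- function(x, cat_a, cat_b, k, B, seed, stoplist = NULL) {
  if (!is_count(B, 1)) rl_value_error("`B` must be an integer >= 1")
  if (!is_count(k, 1)) rl_value_error("`k` must be a positive integer")
  if (identical(cat_a, cat_b)) {
    rl_value_error("the two categories must differ")
  }
  processed <- if (is.data.frame(x)) x else {
    if (is.null(stoplist)) rl_value_error("`stoplist` required for a corpus")
    preprocess_corpus(x, stoplist)
  }

  vocab_a <- category_vocabulary(processed, cat_a, k)
  vocab_b <- category_vocabulary(processed, cat_b, k)
  j_obs <- jaccard(vocab_a$lemmas, vocab_b$lemmas)

  ia <- .eligible_category_rows(processed, cat_a)
  ib <- .eligible_category_rows(processed, cat_b)
  pool <- processed$content_lemmas[c(ia, ib)]
  n_a <- length(ia)
  n <- length(pool)

  # comment-by-word count matrix over the pooled vocabulary
  words <- sort(unique(unlist(pool, use.names = FALSE)))
  flat <- unlist(pool, use.names = FALSE)
  ci <- rep.int(seq_len(n), lengths(pool))
  M <- Matrix::sparseMatrix(i = ci, j = match(flat, words), x = 1,
                            dims = c(n, length(words)))
  tot <- Matrix::colSums(M)

  null_j <- with_seed(seed, {
    idx <- vapply(seq_len(B), function(b) sample.int(n, n_a),
                  integer(n_a))
    Z <- Matrix::sparseMatrix(i = as.vector(idx),
                              j = rep(seq_len(B), each = n_a),
                              x = 1, dims = c(n, B))
    CA <- as.matrix(Matrix::crossprod(M, Z)) # words x B
    vapply(seq_len(B), function(b) {
      ca <- CA[, b]
      jaccard(.topk_counts(ca, words, k), .topk_counts(tot - ca, words, k))
    }, numeric(1))
  })

  structure(
    list(pair = c(cat_a, cat_b), J_obs = j_obs, k = as.integer(k),
         B = as.integer(B), null_J = null_j,
         p_left = (1 + sum(null_j <= j_obs)) / (B + 1),
         seed = as.integer(seed)),
    class = "jaccard_result"
  )
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat(sprintf("<jaccard_result> %s-%s: J = %.4f, p_left = %.4g (k=%d, B=%d)\n",
              x$pair[1], x$pair[2], x$J_obs, x$p_left, x$k, x$B))
  invisible(x)
}

#' Pairwise Jaccard matrix over categories
#'
#' One [jaccard_test()] per unordered category pair. Each pair's child seed
#' is derived from the master seed and the pair's sorted names, so
#' permuting the input category order permutes but never changes the
#' results.
#'
#' @inheritParams jaccard_test
#' @param categories Character vector of >= 2 base categories.
#' @param p_adjust `"none"` (default: raw per-pair p-values) or `"holm"`.
#' @return An object of class `jaccard_matrix`: list of `jaccard_result`s
#'   plus the comparison metadata; `as.data.frame()` gives the flat table
#'   (pair, J_obs, p_left, and `p_adj` when adjusted).
#' @export
pairwise_jaccard_matrix <- function(x, categories, k, B, seed,
                                    stoplist = NULL,
                                    p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  categories <- unique(as.character(categories))
  if (length(categories) < 2) {
    rl_value_error("need at least 2 categories")
  }
  processed <- if (is.data.frame(x)) x else {
    if (is.null(stoplist)) rl_value_error("`stoplist` required for a corpus")
    preprocess_corpus(x, stoplist)
  }
  pairs <- utils::combn(categories, 2, simplify = FALSE)
  results <- lapply(pairs, function(p) {
    p <- sort(p)
    jaccard_test(processed, p[1], p[2], k = k, B = B,
                 seed = derive_seed(seed, c("jaccard", p)))
  })
  p_adj <- if (p_adjust == "holm") {
    stats::p.adjust(vapply(results, `[[`, numeric(1), "p_left"),
                    method = "holm")
  }
  structure(list(results = results, k = as.integer(k), B = as.integer(B),
                 seed = as.integer(seed), p_adjust = p_adjust,
                 p_adj = p_adj),
            class = "jaccard_matrix")
}

#' @export
as.data.frame.jaccard_matrix <- function(x, ...) {
  df <- do.call(rbind, lapply(x$results, function(r) {
    data.frame(pair = paste(r$pair, collapse = "-"), J_obs = r$J_obs,
               p_left = r$p_left, B = r$B, k = r$k, seed = r$seed,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(x$p_adj)) df$p_adj <- x$p_adj
  df
}

#' @export
print.jaccard_matrix <- function(x, ...) {
  cat(sprintf("<jaccard_matrix> %d pairs (k=%d, B=%d)\n",
              length(x$results), x$k, x$B))
  print(as.data.frame(x))
  invisible(x)
}

#' Export a Jaccard matrix as TSV
#'
#' @param x A `jaccard_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaccard_tsv <- function(x, path) {
  if (dir.exists(path)) rl_io_error(sprintf("'%s' is a directory", path))
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
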