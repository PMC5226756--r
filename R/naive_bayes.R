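# Multinomial naive Bayes over comment bags-of-words, with stratified
# cross-validation. This is the classifier the emulated study design calls
# for but could not power; a class rarer than the number of folds surfaces
# as a typed stratification error rather than a silent degradation.

#' Train a multinomial naive Bayes model
#'
#' Counts content lemmas per class with additive (Laplace) smoothing
#' `alpha`; fully deterministic.
#'
#' @param comments List of [preprocess_comment()] results or bare lemma
#'   vectors (incomplete comments contribute nothing, but at least one
#'   lemma must survive overall).
#' @param labels Character vector of class labels aligned with `comments`;
#'   at least two distinct classes.
#' @param alpha Smoothing weight, > 0 (default 1).
#' @return An object of class `bow_nb`: list with `classes`, `log_priors`,
#'   `log_likelihoods` (classes x vocabulary matrix; rows exponentiate and
#'   sum to 1), `vocabulary` and `alpha`.
#' @export
train_nb <- function(comments, labels, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0) {
    rl_value_error("`alpha` must be a positive number")
  }
  lem <- .as_lemma_list(comments)
  labels <- as.character(labels)
  if (length(lem) != length(labels)) {
    rl_value_error("`comments` and `labels` differ in length")
  }
  keep <- lengths(lem) > 0
  lem <- lem[keep]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    rl_value_error("need at least 2 classes with completed comments")
  }
  vocabulary <- sort(unique(unlist(lem, use.names = FALSE)))
  if (length(vocabulary) == 0) rl_value_error("empty vocabulary")

  flat <- unlist(lem, use.names = FALSE)
  cls <- rep.int(labels, lengths(lem))
  counts <- matrix(0, nrow = length(classes), ncol = length(vocabulary),
                   dimnames = list(classes, vocabulary))
  tab <- table(factor(cls, levels = classes),
               factor(flat, levels = vocabulary))
  counts[] <- as.numeric(tab)

  totals <- rowSums(counts)
  log_lik <- log(counts + alpha) -
    log(totals + alpha * length(vocabulary))
  prior <- table(factor(labels, levels = classes))
  structure(
    list(classes = classes,
         log_priors = log(as.numeric(prior) / length(labels)),
         log_likelihoods = log_lik,
         vocabulary = vocabulary,
         alpha = alpha),
    class = "bow_nb"
  )
}

#' @export
print.bow_nb <- function(x, ...) {
  cat(sprintf("<bow_nb> %d classes, vocabulary %d, alpha=%g\n",
              length(x$classes), length(x$vocabulary), x$alpha))
  invisible(x)
}

#' Posterior log-scores and predictions
#'
#' Words outside the training vocabulary are ignored. Ties break on the
#' first class in sorted order, so prediction is deterministic.
#'
#' @param object A `bow_nb` model.
#' @param newdata List of processed comments or lemma vectors.
#' @param type `"class"` (default) or `"logposterior"` (unnormalised
#'   matrix of class scores).
#' @param ... Unused.
#' @return Character vector of predicted classes, or a score matrix.
#' @export
predict.bow_nb <- function(object, newdata, type = c("class", "logposterior"),
                           ...) {
  type <- match.arg(type)
  lem <- .as_lemma_list(newdata)
  n <- length(lem)
  flat <- unlist(lem, use.names = FALSE)
  ci <- rep.int(seq_len(n), lengths(lem))
  j <- match(flat, object$vocabulary)
  keep <- !is.na(j)
  X <- Matrix::sparseMatrix(i = ci[keep], j = j[keep], x = 1,
                            dims = c(n, length(object$vocabulary)))
  scores <- as.matrix(X %*% t(object$log_likelihoods))
  scores <- sweep(scores, 2, object$log_priors, `+`)
  colnames(scores) <- object$classes
  if (type == "logposterior") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Stratified cross-validated naive Bayes evaluation
#'
#' Eligible comments are the completed, single-category ones, with
#' "Inadequate" excluded by default (mirroring the category analyses).
#' Folds are stratified within class and deterministic given `seed`.
#'
#' @param x A [corpus()] or [preprocess_corpus()] data.frame.
#' @param folds Number of folds, >= 2; every class must have at least
#'   `folds` comments, else a stratification error names the offending
#'   class — the "insufficient data" condition.
#' @param seed Integer seed for the fold assignment.
#' @param alpha Smoothing weight, see [train_nb()].
#' @param stoplist A [stoplist()]; required when `x` is a corpus.
#' @param include_inadequate Include the Inadequate class (default `FALSE`).
#' @return List with `fold_accuracy`, `mean_accuracy`, `confusion`
#'   (true x predicted matrix over all folds), `n`, `folds`, `alpha`,
#'   `seed`.
#' @export
cv_evaluate <- function(x, folds, seed, alpha = 1, stoplist = NULL,
                        include_inadequate = FALSE) {
  if (!is_count(folds, 2)) rl_value_error("`folds` must be an integer >= 2")
  processed <- if (is.data.frame(x)) x else {
    if (is.null(stoplist)) rl_value_error("`stoplist` required for a corpus")
    preprocess_corpus(x, stoplist)
  }
  eligible <- processed$complete & !is.na(processed$category)
  if (!include_inadequate) {
    eligible <- eligible & processed$category != "Inadequate"
  }
  lem <- processed$content_lemmas[eligible]
  labels <- processed$category[eligible]
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    rl_value_error("need at least 2 classes with completed comments")
  }
  sizes <- table(labels)
  small <- names(sizes)[sizes < folds]
  if (length(small) > 0) {
    rl_stratification_error(sprintf(
      "class '%s' has %d comments, fewer than %d folds (insufficient data)",
      small[[1]], sizes[[small[[1]]]], folds))
  }

  fold_id <- with_seed(seed, {
    fid <- integer(length(labels))
    for (cl in classes) {
      ii <- which(labels == cl)
      fid[ii] <- rep_len(seq_len(folds), length(ii))[sample.int(length(ii))]
    }
    fid
  })

  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    model <- train_nb(lem[!test], labels[!test], alpha = alpha)
    pred <- predict(model, lem[test])
    truth <- labels[test]
    acc[f] <- mean(pred == truth)
    tab <- table(factor(truth, levels = classes),
                 factor(pred, levels = classes))
    confusion <- confusion + as.matrix(tab)
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc), confusion = confusion,
       n = length(labels), folds = as.integer(folds), alpha = alpha,
       seed = as.integer(seed))
}
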