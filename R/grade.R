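# Reflection-effort statistics per student and their association with the
# final clerkship grade.
#
# A comment counts as completed when at least one word survives stopword
# removal; the completion denominator is the number of shifts, not the
# number of non-empty rows. Mean comment length counts raw word tokens
# before stopword removal by default ("words as written"), with the
# content-lemma convention available behind `length_basis`. All quantile-
# based summaries use the linear-interpolation convention (R type 7) and
# say so in their output.

#' Per-student reflection effort
#'
#' @param x A [student()].
#' @param stoplist A [stoplist()].
#' @param length_basis `"raw"` (default): mean raw token count per shift,
#'   empty shifts contributing 0; `"content"`: mean surviving content-lemma
#'   count.
#' @return An object of class `student_effort`: list with `student_id`,
#'   `n_shifts`, `n_complete`, `completion_fraction` and `mean_length`.
#' @export
student_effort <- function(x, stoplist, length_basis = c("raw", "content")) {
  length_basis <- match.arg(length_basis)
  if (!inherits(x, "student")) rl_value_error("`x` must be a student")
  if (length(x$shifts) == 0) {
    rl_value_error(sprintf("student '%s' has no shifts", x$student_id))
  }
  texts <- vapply(x$shifts, function(s) s$raw_text, character(1))
  batch <- preprocess_comments(texts, stoplist)
  n_shifts <- length(texts)
  n_complete <- sum(batch$complete)
  lens <- if (length_basis == "raw") batch$n_tokens else
    lengths(batch$content_lemmas)
  structure(
    list(student_id = x$student_id, n_shifts = n_shifts,
         n_complete = n_complete,
         completion_fraction = n_complete / n_shifts,
         mean_length = mean(lens)),
    class = "student_effort"
  )
}

#' Per-student effort table for a whole corpus
#'
#' @param x A [corpus()] or [preprocess_corpus()] data.frame.
#' @param stoplist A [stoplist()]; required when `x` is a corpus.
#' @inheritParams student_effort
#' @return A data.frame with one row per student: `student_id`, `n_shifts`,
#'   `n_complete`, `completion_fraction`, `mean_length`, `final_grade`.
#' @export
corpus_effort <- function(x, stoplist = NULL,
                          length_basis = c("raw", "content")) {
  length_basis <- match.arg(length_basis)
  processed <- if (is.data.frame(x)) x else {
    if (is.null(stoplist)) rl_value_error("`stoplist` required for a corpus")
    preprocess_corpus(x, stoplist)
  }
  lens <- if (length_basis == "raw") processed$n_tokens else
    lengths(processed$content_lemmas)
  ids <- unique(processed$student_id)
  sp <- split(seq_len(nrow(processed)), processed$student_id)[ids]
  out <- data.frame(
    student_id = ids,
    n_shifts = vapply(sp, length, integer(1)),
    n_complete = vapply(sp, function(ii) sum(processed$complete[ii]),
                        integer(1)),
    mean_length = vapply(sp, function(ii) mean(lens[ii]), numeric(1)),
    final_grade = vapply(sp, function(ii) processed$final_grade[ii[[1]]],
                         numeric(1)),
    stringsAsFactors = FALSE
  )
  out$completion_fraction <- out$n_complete / out$n_shifts
  rownames(out) <- NULL
  out[, c("student_id", "n_shifts", "n_complete", "completion_fraction",
          "mean_length", "final_grade")]
}

#' Pearson correlation with the least-squares line
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return List with `r`, and `slope`, `intercept`, `r_squared` of the
#'   least-squares regression of `y` on `x`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) rl_value_error("`x` and `y` differ in length")
  if (length(x) < 3) rl_value_error("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) rl_value_error("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rl_degenerate_error("zero variance in `x` or `y`")
  }
  r <- stats::cor(x, y)
  slope <- r * stats::sd(y) / stats::sd(x)
  list(r = r, slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = r^2)
}

#' t-test that a Pearson correlation differs from zero
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' two-tailed.
#'
#' @param r Sample correlation, `|r| <= 1`.
#' @param n Number of paired observations, >= 3.
#' @return List with `t`, `p` and `df`. `|r| = 1` gives an infinite-t
#'   sentinel with `p = 0`.
#' @export
#' @examples
#' corr_t_test(0.5, 27)
corr_t_test <- function(r, n) {
  if (!is_count(n, 0) || n < 3) rl_value_error("`n` must be an integer >= 3")
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || abs(r) > 1) {
    rl_value_error("`r` must be a correlation in [-1, 1]")
  }
  df <- n - 2
  if (abs(r) == 1) {
    return(list(t = sign(r) * Inf, p = 0, df = df))
  }
  t <- r * sqrt(df) / sqrt(1 - r^2)
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Split students into completers and non-completers
#'
#' Completers wrote reflections on strictly more than `threshold` of their
#' shifts ("more than half"); a student exactly at the threshold is a
#' non-completer.
#'
#' @param efforts A [corpus_effort()] data.frame (columns
#'   `completion_fraction` and `final_grade`).
#' @param threshold Completion-fraction cut point, default 0.5.
#' @return List with data.frames `completers` and `noncompleters`.
#' @export
split_by_completion <- function(efforts, threshold = 0.5) {
  if (!is.data.frame(efforts) ||
      !all(c("completion_fraction", "final_grade") %in% names(efforts))) {
    rl_value_error(
      "`efforts` must have columns completion_fraction and final_grade")
  }
  if (nrow(efforts) == 0) rl_value_error("empty effort table")
  up <- efforts$completion_fraction > threshold
  list(completers = efforts[up, , drop = FALSE],
       noncompleters = efforts[!up, , drop = FALSE])
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with a two-sided p-value: exact when both
#' samples have at most 25 observations, asymptotic otherwise.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `D` and `p`.
#' @export
ks_2sample <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    rl_value_error("both samples must be non-empty")
  }
  exact <- length(a) <= 25 && length(b) <= 25
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Notched-boxplot summary of one group
#'
#' Median and IQR via linear-interpolation quantiles; the notch is the
#' standard approximate 95% interval for the median,
#' `median +/- 1.57 * IQR / sqrt(n)`; whiskers sit at the 2nd and 97th
#' percentiles.
#'
#' @param values Non-empty numeric vector.
#' @return An object of class `group_summary`: list with `n`, `median`,
#'   `iqr`, `notch_ci` (low, high), `whiskers` (2nd, 97th percentile) and
#'   `quantile_convention`.
#' @export
group_summary <- function(values) {
  if (length(values) < 1 || anyNA(values)) {
    rl_value_error("`values` must be non-empty with no missing values")
  }
  q <- unname(stats::quantile(values, c(0.02, 0.25, 0.5, 0.75, 0.97),
                              type = 7))
  med <- q[3]
  iqr <- q[4] - q[2]
  half <- 1.57 * iqr / sqrt(length(values))
  structure(
    list(n = length(values), median = med, iqr = iqr,
         notch_ci = c(med - half, med + half),
         whiskers = c(q[1], q[5]),
         quantile_convention = "linear interpolation (type 7)"),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "<group_summary> n=%d median=%.4g IQR=%.4g notch=(%.4g, %.4g)\n",
    x$n, x$median, x$iqr, x$notch_ci[1], x$notch_ci[2]))
  invisible(x)
}

#' Full reflection-grade association report
#'
#' Assembles the grade-association analysis: Pearson correlation (with
#' regression line and t-test) of final grade against completion fraction
#' and against mean comment length, the completer/non-completer split with
#' notched-boxplot summaries, and the two-sample Kolmogorov-Smirnov
#' comparison of the two grade distributions.
#'
#' @param x A [corpus()] or [preprocess_corpus()] data.frame.
#' @param stoplist A [stoplist()]; required when `x` is a corpus.
#' @param threshold Completion split threshold, default 0.5.
#' @inheritParams student_effort
#' @return A named list (`r_completion`, `t_completion`, `p_completion`,
#'   `regression_completion`, `r_length`, `t_length`, `p_length`,
#'   `regression_length`, `n`, `group_split`, `ks_D`, `ks_p`, ...). The KS
#'   entries are `NA` when either group is empty.
#' @export
grade_association <- function(x, stoplist = NULL, threshold = 0.5,
                              length_basis = c("raw", "content")) {
  length_basis <- match.arg(length_basis)
  eff <- corpus_effort(x, stoplist, length_basis = length_basis)
  if (nrow(eff) < 3) rl_value_error("need at least 3 students")
  pc <- pearson_r(eff$completion_fraction, eff$final_grade)
  tc <- corr_t_test(pc$r, nrow(eff))
  pl <- pearson_r(eff$mean_length, eff$final_grade)
  tl <- corr_t_test(pl$r, nrow(eff))
  sp <- split_by_completion(eff, threshold)
  has_both <- nrow(sp$completers) > 0 && nrow(sp$noncompleters) > 0
  ks <- if (has_both) {
    ks_2sample(sp$completers$final_grade, sp$noncompleters$final_grade)
  } else {
    list(D = NA_real_, p = NA_real_)
  }
  list(
    n = nrow(eff),
    r_completion = pc$r, t_completion = tc$t, p_completion = tc$p,
    regression_completion = pc[c("slope", "intercept", "r_squared")],
    r_length = pl$r, t_length = tl$t, p_length = tl$p,
    regression_length = pl[c("slope", "intercept", "r_squared")],
    split_threshold = threshold,
    length_basis = length_basis,
    group_split = list(
      completers = if (nrow(sp$completers) > 0)
        unclass(group_summary(sp$completers$final_grade)),
      noncompleters = if (nrow(sp$noncompleters) > 0)
        unclass(group_summary(sp$noncompleters$final_grade))
    ),
    ks_D = ks$D, ks_p = ks$p,
    quantile_convention = "linear interpolation (type 7)"
  )
}
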