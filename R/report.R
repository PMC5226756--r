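# JSON analysis report: one document holding every stage's output.

.report_sections <- c("preprocessing_summary", "ngram_tables",
                      "jaccard_matrix", "grade_association", "classifier")

#' Write the assembled analysis report as JSON
#'
#' The report is a single JSON document with the five fixed top-level
#' sections `preprocessing_summary`, `ngram_tables`, `jaccard_matrix`,
#' `grade_association` and `classifier`, written in that stable order, plus
#' an optional `metadata` section. It round-trips through [read_report()].
#'
#' @param results Named list containing all five sections (a section whose
#'   stage was skipped still appears, e.g. as a list with a `skipped` flag).
#' @param path Output file path (must not be a directory).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (!is.list(results)) rl_value_error("`results` must be a named list")
  missing_sections <- setdiff(.report_sections, names(results))
  if (length(missing_sections) > 0) {
    rl_value_error(sprintf("report is missing section '%s'",
                           missing_sections[[1]]))
  }
  if (dir.exists(path)) rl_io_error(sprintf("'%s' is a directory", path))
  if (!dir.exists(dirname(path))) {
    rl_io_error(sprintf("no such directory: '%s'", dirname(path)))
  }
  keep <- c(.report_sections, setdiff(names(results), .report_sections))
  jsonlite::write_json(results[keep], path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) rl_io_error(sprintf("no such file: '%s'", path))
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
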