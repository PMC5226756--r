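# Corpus data model and bit-exact readers/writers.
#
# One Student holds the 14 (in the emulated study design) per-shift records
# of a clerkship rotation: the raw reflective comment exactly as transcribed
# (possibly empty — a shift row with an empty comment is preserved, because
# the completion denominator is the number of shifts, not the number of rows
# with text) plus the attending's RIME rating when one was recorded.

#' Construct a shift record
#'
#' @param shift_index Integer >= 1, position of the shift in the rotation.
#' @param raw_text The comment text verbatim; `""` means no legible
#'   reflection was written. Never normalised at ingest.
#' @param rating A [rime_rating()], a rating label string, or `NULL` when no
#'   evaluation was recorded.
#' @return An object of class `shift_record`.
#' @export
shift_record <- function(shift_index, raw_text = "", rating = NULL) {
  if (!is_count(shift_index, min = 1)) {
    rl_value_error("`shift_index` must be an integer >= 1")
  }
  if (!is.character(raw_text) || length(raw_text) != 1) {
    rl_value_error("`raw_text` must be a single string")
  }
  if (is.na(raw_text)) raw_text <- ""
  if (!is.null(rating) && !is_rime_rating(rating)) {
    rating <- parse_rime_label(rating)
  }
  structure(
    list(shift_index = as.integer(shift_index), raw_text = raw_text,
         rating = rating),
    class = "shift_record"
  )
}

#' Construct a student
#'
#' @param student_id Opaque identifier, unique within a corpus.
#' @param final_grade Final clerkship grade on the 0-100 scale, stored as a
#'   real (grades like 83.675 are never rounded at ingest).
#' @param shifts List of [shift_record()]s with unique `shift_index` values.
#' @return An object of class `student`.
#' @export
student <- function(student_id, final_grade, shifts = list()) {
  if (!is_string(student_id) || !nzchar(student_id)) {
    rl_value_error("`student_id` must be a non-empty string")
  }
  if (!is.numeric(final_grade) || length(final_grade) != 1 || is.na(final_grade)) {
    rl_value_error(sprintf("grade for student '%s' is not a number", student_id))
  }
  if (final_grade < 0 || final_grade > 100) {
    rl_value_error(sprintf("grade %s for student '%s' outside [0, 100]",
                           format(final_grade), student_id))
  }
  idx <- vapply(shifts, function(s) s$shift_index, integer(1))
  if (anyDuplicated(idx)) {
    rl_integrity_error(sprintf(
      "duplicate shift_index %d for student '%s'", idx[duplicated(idx)][[1]],
      student_id))
  }
  structure(
    list(student_id = student_id, final_grade = as.numeric(final_grade),
         shifts = shifts[order(idx)]),
    class = "student"
  )
}

#' Construct a corpus
#'
#' @param students List of [student()]s; ids must be unique.
#' @param metadata Free-form named list of provenance keys.
#' @return An object of class `corpus`.
#' @export
corpus <- function(students = list(), metadata = list()) {
  ids <- vapply(students, function(s) s$student_id, character(1))
  if (anyDuplicated(ids)) {
    rl_integrity_error(sprintf("duplicate student_id '%s'",
                               ids[duplicated(ids)][[1]]))
  }
  structure(list(students = students, metadata = metadata), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  ns <- length(x$students)
  nshift <- sum(vapply(x$students, function(s) length(s$shifts), integer(1)))
  cat(sprintf("<corpus> %d students, %d shift records\n", ns, nshift))
  invisible(x)
}

n_students <- function(x) length(x$students)

#' Flatten a corpus to one row per shift
#'
#' @param x A [corpus()].
#' @return A data.frame with columns `student_id`, `shift_index`, `comment`,
#'   `rating` (canonical label or `""`), `final_grade` — the same layout the
#'   CSV dialect uses on disk.
#' @export
corpus_shifts <- function(x) {
  stopifnot(inherits(x, "corpus"))
  rows <- lapply(x$students, function(s) {
    if (length(s$shifts) == 0) return(NULL)
    data.frame(
      student_id = s$student_id,
      shift_index = vapply(s$shifts, function(sh) sh$shift_index, integer(1)),
      comment = vapply(s$shifts, function(sh) sh$raw_text, character(1)),
      rating = vapply(s$shifts, function(sh) {
        if (is.null(sh$rating)) "" else format(sh$rating)
      }, character(1)),
      final_grade = s$final_grade,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(student_id = character(), shift_index = integer(),
                      comment = character(), rating = character(),
                      final_grade = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

.required_columns <- c("student_id", "shift_index", "comment", "rating",
                       "final_grade")

# Assemble a corpus from a flat shift table; shared by the CSV/JSONL readers.
.corpus_from_flat <- function(df, metadata = list()) {
  key <- paste(df$student_id, df$shift_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    rl_integrity_error(sprintf(
      "duplicate (student_id, shift_index) = ('%s', %s)",
      d$student_id, d$shift_index))
  }
  grades <- suppressWarnings(as.numeric(df$final_grade))
  bad <- which(is.na(grades))
  if (length(bad) > 0) {
    rl_value_error(sprintf("unparseable final_grade '%s' at row %d",
                           df$final_grade[bad[[1]]], bad[[1]]))
  }
  sidx <- suppressWarnings(as.integer(df$shift_index))
  bad <- which(is.na(sidx))
  if (length(bad) > 0) {
    rl_value_error(sprintf("unparseable shift_index '%s' at row %d",
                           df$shift_index[bad[[1]]], bad[[1]]))
  }
  students <- lapply(split(seq_len(nrow(df)), df$student_id), function(ii) {
    g <- unique(grades[ii])
    if (length(g) > 1) {
      rl_integrity_error(sprintf(
        "student '%s' has conflicting final grades: %s",
        df$student_id[ii[[1]]], paste(format(g), collapse = ", ")))
    }
    shifts <- lapply(ii, function(i) {
      lab <- df$rating[i]
      rating <- if (is.na(lab) || !nzchar(trimws(lab))) NULL else
        parse_rime_label(lab)
      txt <- df$comment[i]
      if (is.na(txt)) txt <- ""
      shift_record(sidx[i], txt, rating)
    })
    student(df$student_id[ii[[1]]], g, shifts)
  })
  # preserve first-appearance order of students
  ord <- match(unique(df$student_id), names(students))
  corpus(unname(students[ord]), metadata)
}

#' Read a corpus from CSV/TSV or JSONL
#'
#' The CSV dialect is UTF-8 with a header row and columns `student_id`,
#' `shift_index`, `comment`, `rating`, `final_grade`; quoted fields are
#' allowed and a `.tsv` extension switches the separator to tab. JSONL holds
#' one object per shift record with the same field names, the student's grade
#' repeated on every line. Empty comment cells become empty `raw_text`
#' (preserved — see [shift_record()]); rating cells go through
#' [parse_rime_label()].
#'
#' @param path Path to an existing file.
#' @param format `"csv"` or `"jsonl"`; `NULL` guesses from the extension.
#' @return A [corpus()] with one [student()] per distinct `student_id`.
#' @export
read_corpus <- function(path, format = NULL) {
  if (!file.exists(path)) rl_io_error(sprintf("no such file: '%s'", path))
  if (is.null(format)) {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  format <- match.arg(format, c("csv", "jsonl"))
  df <- if (format == "csv") {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      encoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    as.data.frame(
      do.call(rbind, lapply(recs, function(r) {
        vapply(.required_columns, function(col) {
          v <- r[[col]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))
      })),
      stringsAsFactors = FALSE
    )
  }
  missing_cols <- setdiff(.required_columns, names(df))
  if (length(missing_cols) > 0) {
    rl_format_error(sprintf("missing required column '%s'", missing_cols[[1]]))
  }
  .corpus_from_flat(df, metadata = list(source = path, format = format))
}

#' Write a corpus in the package's CSV dialect
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p))` restores
#' every field (comments verbatim, ratings in canonical hyphenated form).
#'
#' @param x A [corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  df <- corpus_shifts(x)
  if (dir.exists(path)) rl_io_error(sprintf("'%s' is a directory", path))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
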