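# Shared helpers: small in-code fixtures and independent brute-force
# oracles used across test files.

# stoplist with just the function words the tiny examples need
mini_stoplist <- function() {
  stoplist(c("the", "of", "and", "a", "to", "was", "i"))
}

# write a corpus CSV from a data.frame of rows and return the path
write_corpus_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

flat_rows <- function(student_id, shift_index, comment, rating,
                      final_grade) {
  data.frame(student_id = student_id, shift_index = shift_index,
             comment = comment, rating = rating, final_grade = final_grade,
             stringsAsFactors = FALSE)
}

# hand-buildable corpus: each element of `comments` is one student's
# character vector of shift comments; ratings parallel lists of labels
build_corpus <- function(comments, ratings = NULL, grades = NULL) {
  students <- lapply(seq_along(comments), function(i) {
    txts <- comments[[i]]
    shifts <- lapply(seq_along(txts), function(s) {
      r <- if (!is.null(ratings)) ratings[[i]][[s]]
      if (!is.null(r) && is.character(r) && !nzchar(r)) r <- NULL
      shift_record(s, txts[[s]], r)
    })
    student(sprintf("stu%02d", i),
            if (is.null(grades)) 80 else grades[[i]], shifts)
  })
  corpus(students)
}

# brute-force Jaccard: double-loop membership count
oracle_jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  inter <- 0
  for (x in a) for (y in b) if (identical(x, y)) inter <- inter + 1
  inter / (length(a) + length(b) - inter)
}

# brute-force two-sample KS D: sweep the ECDF difference over all points
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# strip the timestamp so reports can be compared for determinism
strip_timestamp <- function(report) {
  report$metadata$generated_at <- NULL
  report
}
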