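# Corpus data model, RIME label parsing, file round-trips.

test_that("RIME labels parse case-insensitively with alias and hybrids", {
  r <- parse_rime_label("Superior")
  expect_equal(r$categories, "Educator")
  expect_false(r$hybrid)

  h <- parse_rime_label("reporter-interpreter")
  expect_equal(h$categories, c("Reporter", "Interpreter"))
  expect_true(h$hybrid)
  # slash separator and reversed order canonicalize identically
  expect_equal(format(parse_rime_label("Interpreter/Reporter")),
               "Reporter-Interpreter")
  expect_equal(format(parse_rime_label("  manager ")), "Manager")
})

test_that("RIME parsing rejects unknown tokens and bad hybrids", {
  expect_error(parse_rime_label("Observer"), class = "rl_value_error")
  expect_error(parse_rime_label("Observer"), "Observer")
  expect_error(parse_rime_label("Reporter-Manager"), "non-adjacent",
               class = "rl_value_error")
  expect_error(parse_rime_label("Inadequate-Reporter"),
               class = "rl_value_error")
  expect_error(parse_rime_label(""), class = "rl_value_error")
  expect_error(rime_rating(c("Reporter", "Interpreter", "Manager")),
               class = "rl_value_error")
})

test_that("parse_rime_label is idempotent on its canonical output", {
  labels <- c("Superior", "manager/educator", "REPORTER", "inadequate",
              "Interpreter-Manager")
  for (lab in labels) {
    once <- parse_rime_label(lab)
    twice <- parse_rime_label(format(once))
    expect_identical(once, twice)
  }
})

test_that("read_corpus maps CSV rows to students and shifts", {
  path <- write_corpus_csv(flat_rows(
    student_id = rep("a1", 3), shift_index = 1:3,
    comment = c("saw patients", "", "chest pain"),
    rating = c("Reporter", "Reporter-Interpreter", ""),
    final_grade = rep("83.0", 3)))
  corp <- read_corpus(path)
  expect_length(corp$students, 1)
  stu <- corp$students[[1]]
  expect_length(stu$shifts, 3)
  expect_equal(stu$final_grade, 83.0)
  # empty comment cell preserved as empty raw_text, not dropped
  expect_identical(stu$shifts[[2]]$raw_text, "")
  # hyphenated rating cell parsed as a hybrid
  expect_true(stu$shifts[[2]]$rating$hybrid)
  expect_equal(stu$shifts[[2]]$rating$categories,
               c("Reporter", "Interpreter"))
  # absent rating preserved as NULL
  expect_null(stu$shifts[[3]]$rating)
})

test_that("read_corpus enforces its contract", {
  no_comment <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(student_id = "a", shift_index = 1,
                              rating = "", final_grade = "80"),
                   no_comment, row.names = FALSE)
  expect_error(read_corpus(no_comment), "comment",
               class = "rl_format_error")

  dup <- write_corpus_csv(flat_rows(c("a", "a"), c(1, 1), c("x", "y"),
                                    c("", ""), c("80", "80")))
  expect_error(read_corpus(dup), class = "rl_integrity_error")

  badgrade <- write_corpus_csv(flat_rows("a", 1, "x", "", "eighty"))
  err <- tryCatch(read_corpus(badgrade), error = identity)
  expect_s3_class(err, "rl_value_error")
  expect_match(conditionMessage(err), "row 1")

  expect_error(read_corpus(tempfile()), class = "rl_io_error")
})

test_that("JSONL reading matches CSV reading of the same records", {
  df <- flat_rows(c("a", "a", "b"), c(1, 2, 1),
                  c("felt unsure", "", "ran the code"),
                  c("Interpreter", "", "Superior"),
                  c("77.25", "77.25", "91.5"))
  csv <- write_corpus_csv(df)
  jsonl <- tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)
  }, character(1)), jsonl)
  from_csv <- read_corpus(csv)
  from_jsonl <- read_corpus(jsonl)
  from_csv$metadata <- from_jsonl$metadata <- NULL
  expect_identical(from_csv, from_jsonl)
})

test_that("write_corpus / read_corpus round-trips a synthetic corpus", {
  corp <- make_fixture("tiny")$corpus
  path <- tempfile(fileext = ".csv")
  write_corpus(corp, path)
  back <- read_corpus(path)
  back$metadata <- corp$metadata <- NULL
  expect_identical(back, corp)
})

test_that("grades outside [0, 100] are rejected at ingest", {
  path <- write_corpus_csv(flat_rows("a", 1, "x", "", "105"))
  expect_error(read_corpus(path), class = "rl_value_error")
})

test_that("write_report emits the five sections and round-trips", {
  minimal <- list(preprocessing_summary = list(n_students = 1),
                  ngram_tables = list(), jaccard_matrix = list(),
                  grade_association = list(), classifier = list(skipped = TRUE))
  path <- tempfile(fileext = ".json")
  write_report(minimal, path)
  back <- read_report(path)
  expect_true(all(c("preprocessing_summary", "ngram_tables",
                    "jaccard_matrix", "grade_association",
                    "classifier") %in% names(back)))
  # read-back writes identically: structure is stable
  path2 <- tempfile(fileext = ".json")
  write_report(back, path2)
  expect_identical(read_report(path2), back)

  expect_error(write_report(minimal["ngram_tables"], tempfile()),
               class = "rl_value_error")
  expect_error(write_report(minimal, tempdir()), class = "rl_io_error")
})
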