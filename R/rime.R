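# RIME evaluation ratings: parsing, validation, canonical formatting.
#
# The RIME scheme rates a trainee's clinical functioning on the ladder
# Reporter < Interpreter < Manager < Educator; "Inadequate" sits below it.
# Some evaluation forms relabel Educator as "Superior". An attending may
# circle two adjacent ladder categories, giving a hybrid rating printed with
# a hyphen (e.g. "Reporter-Interpreter").

#' RIME category names
#'
#' @return `rime_base_categories()`: the five base categories, Inadequate
#'   first. `rime_ladder()`: the four ordered ladder categories that can form
#'   adjacent hybrids.
#' @export
rime_base_categories <- function() {
  c("Inadequate", "Reporter", "Interpreter", "Manager", "Educator")
}

#' @rdname rime_base_categories
#' @export
rime_ladder <- function() c("Reporter", "Interpreter", "Manager", "Educator")

#' Construct a RIME rating
#'
#' @param categories Character vector of one or two base categories. Two
#'   categories form a hybrid and must be adjacent on the RIME ladder;
#'   "Inadequate" cannot take part in a hybrid.
#' @return An object of class `rime_rating`: a list with `categories`
#'   (ordered by ladder position) and `hybrid` (logical).
#' @export
#' @examples
#' rime_rating("Educator")
#' rime_rating(c("Interpreter", "Reporter")) # reordered to ladder order
rime_rating <- function(categories) {
  categories <- unique(as.character(categories))
  base <- rime_base_categories()
  unknown <- setdiff(categories, base)
  if (length(unknown) > 0) {
    rl_value_error(sprintf("unknown RIME category: '%s'", unknown[[1]]))
  }
  if (length(categories) < 1 || length(categories) > 2) {
    rl_value_error("a RIME rating has one or two categories")
  }
  hybrid <- length(categories) == 2
  if (hybrid) {
    if ("Inadequate" %in% categories) {
      rl_value_error("'Inadequate' cannot be part of a hybrid rating")
    }
    pos <- match(categories, rime_ladder())
    if (abs(diff(sort(pos))) != 1) {
      rl_value_error(sprintf(
        "non-adjacent hybrid rating: '%s'",
        paste(categories, collapse = "-")
      ))
    }
    categories <- rime_ladder()[sort(pos)]
  }
  structure(list(categories = categories, hybrid = hybrid),
            class = "rime_rating")
}

#' Parse a free-text RIME rating label
#'
#' Case-insensitive; surrounding whitespace ignored. "Superior" is an alias
#' for Educator (the relabelling used on some evaluation tools). A hyphen or
#' slash separates the two halves of a hybrid rating.
#'
#' @param label Non-empty string, e.g. `"Superior"`, `"reporter-interpreter"`.
#' @return A [rime_rating()].
#' @export
#' @examples
#' parse_rime_label("Superior")
#' parse_rime_label("reporter/interpreter")
parse_rime_label <- function(label) {
  if (!is_string(label) || !nzchar(trimws(label))) {
    rl_value_error("rating label must be a non-empty string")
  }
  parts <- strsplit(trimws(label), "[-/]")[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  canon <- vapply(parts, function(p) {
    p <- tolower(p)
    hit <- match(p, tolower(rime_base_categories()))
    if (!is.na(hit)) return(rime_base_categories()[hit])
    if (p == "superior") return("Educator")
    rl_value_error(sprintf("unknown RIME category token: '%s'", parts[match(p, tolower(parts))]))
  }, character(1))
  rime_rating(canon)
}

#' @export
format.rime_rating <- function(x, ...) paste(x$categories, collapse = "-")

#' @export
print.rime_rating <- function(x, ...) {
  cat("<rime_rating> ", format(x),
      if (x$hybrid) " (hybrid)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.rime_rating <- function(x, ...) format(x)

is_rime_rating <- function(x) inherits(x, "rime_rating")
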