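# Synthetic annotated-corpus generator.
#
# Emulates the study design the analysis assumes: each student completes a
# fixed number of shifts (14); a per-student completion propensity drawn
# from a Beta distribution decides which shifts get a written reflection;
# the final grade is a clamped linear function of the realized completion
# fraction plus Gaussian noise (or is calibrated to a planted target
# correlation); every shift carries a RIME rating drawn from a category
# distribution that includes adjacent hybrids; completed shifts get a short
# comment of Poisson-many tokens mixing stopwords with Zipf-distributed
# synthetic content words (w00001 ...) from category-specific pools that
# share words according to a configurable pairwise overlap. The generator
# returns the corpus together with its planted ground truth, which analysis
# code never consumes.

.default_category_probs <- function() {
  c(Inadequate = 0.02, Reporter = 0.20, Interpreter = 0.25, Manager = 0.25,
    Educator = 0.18, `Reporter-Interpreter` = 0.0333,
    `Interpreter-Manager` = 0.0333, `Manager-Educator` = 0.0334)
}

#' Configuration for the synthetic-corpus generator
#'
#' @param n_students Number of students.
#' @param shifts_per_student Shifts per rotation (default 14, the emulated
#'   study design).
#' @param completion_ab Length-2 Beta(a, b) parameters for the per-student
#'   completion propensity.
#' @param grade_model List `intercept`, `slope` (on the completion
#'   fraction), `noise_sd`, all on the 0-100 grade scale; grades are
#'   clamped to that scale after noise.
#' @param target_corr Optional planted population correlation between
#'   completion fraction and grade; when set, the slope is calibrated (by
#'   1-D search on a large simulated population, after clamping) and
#'   overrides `grade_model$slope`. Must satisfy `|rho| < 1`.
#' @param category_probs Named probability vector over rating labels (base
#'   categories and hyphenated adjacent hybrids); normalised. The default
#'   puts 10% mass on hybrids and 2% on Inadequate.
#' @param vocab List `core_size` (words shared by every category),
#'   `per_category_size`, `overlap` and `zipf_exponent` for the within-pool
#'   frequency law. A scalar `overlap` in \[0, 1\] makes that fraction of
#'   each category pool one block common to all categories (1 = identical
#'   pools); a symmetric matrix with category dimnames instead plants a
#'   dedicated shared block per category pair.
#' @param comment_len Poisson mean token count of a completed comment.
#' @param stopword_fill Fraction of tokens drawn from the stopword pool.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_students = 116,
                             shifts_per_student = 14,
                             completion_ab = c(2, 2),
                             grade_model = list(intercept = 79, slope = 6.5,
                                                noise_sd = 5),
                             target_corr = NULL,
                             category_probs = NULL,
                             vocab = list(core_size = 40,
                                          per_category_size = 50,
                                          overlap = 0.3,
                                          zipf_exponent = 1.1),
                             comment_len = 9,
                             stopword_fill = 0.5,
                             seed = 1) {
  if (!is_count(n_students, 1)) rl_value_error("`n_students` must be >= 1")
  if (!is_count(shifts_per_student, 1)) {
    rl_value_error("`shifts_per_student` must be >= 1")
  }
  if (length(completion_ab) != 2 || any(completion_ab <= 0)) {
    rl_value_error("`completion_ab` must be two positive Beta parameters")
  }
  if (!is.null(target_corr)) {
    if (!is.numeric(target_corr) || length(target_corr) != 1 ||
        is.na(target_corr) || abs(target_corr) >= 1) {
      rl_value_error("`target_corr` must satisfy |rho| < 1")
    }
  }
  if (is.null(category_probs)) category_probs <- .default_category_probs()
  if (is.null(names(category_probs)) || any(category_probs < 0) ||
      sum(category_probs) <= 0) {
    rl_value_error("`category_probs` must be a named non-negative vector")
  }
  lapply(names(category_probs), parse_rime_label) # validates labels
  category_probs <- category_probs / sum(category_probs)
  vocab$core_size <- vocab$core_size %||% 0
  vocab$zipf_exponent <- vocab$zipf_exponent %||% 1
  vocab$overlap <- vocab$overlap %||% 0
  if (!is_count(vocab$per_category_size, 1)) {
    rl_value_error("`vocab$per_category_size` must be >= 1")
  }
  if (is.matrix(vocab$overlap)) {
    if (any(vocab$overlap < 0 | vocab$overlap > 1)) {
      rl_value_error("`vocab$overlap` entries must lie in [0, 1]")
    }
  } else if (vocab$overlap < 0 || vocab$overlap > 1) {
    rl_value_error("`vocab$overlap` must lie in [0, 1]")
  }
  if (comment_len <= 0) rl_value_error("`comment_len` must be positive")
  if (stopword_fill < 0 || stopword_fill >= 1) {
    rl_value_error("`stopword_fill` must lie in [0, 1)")
  }
  structure(
    list(n_students = as.integer(n_students),
         shifts_per_student = as.integer(shifts_per_student),
         completion_ab = as.numeric(completion_ab),
         grade_model = grade_model, target_corr = target_corr,
         category_probs = category_probs, vocab = vocab,
         comment_len = comment_len, stopword_fill = stopword_fill,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# the stopword pool comments are padded with; a subset of the bundled list
.generator_stopwords <- c(
  "the", "of", "and", "a", "to", "in", "was", "i", "my", "that", "it",
  "with", "for", "on", "at", "this", "but", "be", "had", "we", "is",
  "were", "as", "from", "an", "me", "so", "not", "have", "very")

# probability a completed comment still has no content word: its Poisson
# token count may be 0 or every token may be a stopword
.p_no_content <- function(config) {
  exp(-config$comment_len * (1 - config$stopword_fill))
}

# base categories appearing (alone or in hybrids) in category_probs
.config_base_cats <- function(config) {
  cats <- unlist(strsplit(names(config$category_probs), "-", fixed = TRUE))
  base <- rime_base_categories()
  base[base %in% cats]
}

# Build per-category content-word pools with the requested pairwise
# overlap, and Zipf sampling weights over a pool-content-derived
# permutation (identical pools therefore get identical distributions).
.build_vocab <- function(config) {
  cats <- .config_base_cats(config)
  nc <- length(cats)
  size <- config$vocab$per_category_size
  O <- config$vocab$overlap
  if (!is.matrix(O)) {
    O <- matrix(O, nc, nc, dimnames = list(cats, cats))
  } else {
    if (!all(cats %in% rownames(O)) || !all(cats %in% colnames(O))) {
      rl_value_error("`vocab$overlap` matrix must name every category")
    }
    O <- O[cats, cats, drop = FALSE]
  }
  next_id <- 0L
  fresh <- function(n) {
    if (n <= 0) return(character())
    ids <- next_id + seq_len(n)
    next_id <<- next_id + n
    sprintf("w%05d", ids)
  }
  core <- fresh(config$vocab$core_size)
  pools <- if (!is.matrix(config$vocab$overlap)) {
    # scalar overlap: one block of round(overlap * size) words shared by
    # every category pool, the rest unique per category
    common <- fresh(round(config$vocab$overlap * size))
    lapply(seq_len(nc), function(i) {
      c(core, common, fresh(size - length(common)))
    })
  } else {
    # matrix overlap: a dedicated shared block per category pair
    shared <- list()
    if (nc >= 2) {
      for (i in seq_len(nc - 1)) {
        for (j in seq(i + 1, nc)) {
          s <- round(O[i, j] * size)
          shared[[paste(cats[i], cats[j], sep = "|")]] <- fresh(s)
        }
      }
    }
    lapply(seq_len(nc), function(i) {
      mine <- unlist(shared[grepl(paste0("(^|\\|)", cats[i], "($|\\|)"),
                                  names(shared))], use.names = FALSE)
      if (length(mine) > size) {
        rl_config_error(sprintf(
          "pairwise overlap blocks for '%s' exceed per_category_size",
          cats[i]))
      }
      c(core, mine, fresh(size - length(mine)))
    })
  }
  names(pools) <- cats
  weights <- lapply(pools, function(pool) {
    perm <- with_seed(derive_seed(config$seed, c("vocabperm", pool)),
                      sample.int(length(pool)))
    w <- 1 / seq_along(pool)^config$vocab$zipf_exponent
    w <- w[order(perm)] # rank assignment via the permutation
    w / sum(w)
  })
  list(categories = cats, pools = pools, weights = weights)
}

# Realized correlation between completion fraction and clamped grade for a
# candidate slope, on a large simulated population (deterministic seed).
.sim_corr <- function(slope, config, n_sim, seed) {
  gm <- config$grade_model
  with_seed(seed, {
    p <- stats::rbeta(n_sim, config$completion_ab[1], config$completion_ab[2])
    frac <- stats::rbinom(n_sim, config$shifts_per_student,
                          p * (1 - .p_no_content(config))) /
      config$shifts_per_student
    g <- gm$intercept + slope * frac + stats::rnorm(n_sim, 0, gm$noise_sd)
    g <- pmin(100, pmax(0, g))
    if (stats::sd(frac) == 0 || stats::sd(g) == 0) return(0)
    stats::cor(frac, g)
  })
}

# 1-D search for the slope that attains target_corr after clamping.
# Starts from the no-clamping closed form and expands the bracket
# geometrically; clamping attenuates the correlation, so a target the
# clamped model cannot reach raises a config error instead of silently
# planting a smaller one.
.calibrate_slope <- function(config, n_sim = 50000) {
  target <- config$target_corr
  if (target == 0) return(0)
  seed <- derive_seed(config$seed, "calibrate")
  f <- function(b) .sim_corr(b, config, n_sim, seed) - target

  sd_frac <- with_seed(seed, {
    p <- stats::rbeta(n_sim, config$completion_ab[1], config$completion_ab[2])
    stats::sd(stats::rbinom(n_sim, config$shifts_per_student,
                            p * (1 - .p_no_content(config))) /
                config$shifts_per_student)
  })
  if (sd_frac == 0) {
    rl_config_error("completion fractions are degenerate; cannot calibrate")
  }
  b0 <- target * config$grade_model$noise_sd / (sd_frac * sqrt(1 - target^2))
  hi <- 2 * b0
  sgn <- sign(target)
  tries <- 0
  while (sgn * f(hi) < 0 && tries < 8) {
    hi <- 2 * hi
    tries <- tries + 1
  }
  if (sgn * f(hi) < 0) {
    rl_config_error(sprintf(
      "target_corr %.3f unattainable under grade clamping", target))
  }
  stats::uniroot(f, sort(c(0, hi)), tol = 1e-3)$root
}

#' Generate a synthetic corpus with planted ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with `corpus` (a [corpus()]) and `truth`: the per-student
#'   completion propensities, the planted correlation (`planted_corr`) and
#'   slope actually used, the expected pairwise vocabulary overlap
#'   (Jaccard of the content pools), and a scalar class-separability index
#'   (1 - mean off-diagonal pool overlap). Ground truth is carried for
#'   testing only; analysis functions never read it.
#' @export
#' @examples
#' out <- generate_corpus(synthetic_config(n_students = 5, seed = 42))
#' out$corpus
generate_corpus <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    rl_value_error("`config` must come from synthetic_config()")
  }
  voc <- .build_vocab(config)
  gm <- config$grade_model
  slope <- if (!is.null(config$target_corr)) .calibrate_slope(config)
           else gm$slope
  labels <- names(config$category_probs)
  label_ratings <- lapply(labels, parse_rime_label)
  names(label_ratings) <- labels

  n <- config$n_students
  S <- config$shifts_per_student
  ids <- sprintf("S%04d", seq_len(n))

  gen <- with_seed(derive_seed(config$seed, "corpus"), {
    propensity <- stats::rbeta(n, config$completion_ab[1],
                               config$completion_ab[2])
    completed <- stats::rbinom(n * S, 1, rep(propensity, each = S)) == 1
    shift_label <- sample(labels, n * S, replace = TRUE,
                          prob = config$category_probs)
    nC <- sum(completed)
    len <- stats::rpois(nC, config$comment_len)
    total <- sum(len)
    shift_of_tok <- rep.int(which(completed), len)
    is_stop <- stats::runif(total) < config$stopword_fill
    words <- character(total)
    words[is_stop] <- sample(.generator_stopwords, sum(is_stop),
                             replace = TRUE)
    # content tokens draw from the base pool of their shift's rating;
    # hybrid-rated shifts mix their two categories' pools token by token
    content_idx <- which(!is_stop)
    if (length(content_idx) > 0) {
      lab <- shift_label[shift_of_tok[content_idx]]
      halves <- strsplit(lab, "-", fixed = TRUE)
      pick <- stats::runif(length(content_idx))
      tok_cat <- vapply(seq_along(content_idx), function(i) {
        h <- halves[[i]]
        if (length(h) == 1) h else h[1 + (pick[i] > 0.5)]
      }, character(1))
      for (cat in voc$categories) {
        ii <- content_idx[tok_cat == cat]
        if (length(ii) > 0) {
          words[ii] <- sample(voc$pools[[cat]], length(ii), replace = TRUE,
                              prob = voc$weights[[cat]])
        }
      }
    }
    texts <- character(n * S)
    texts[completed] <- vapply(
      split(words, factor(shift_of_tok, levels = which(completed))),
      paste, character(1), collapse = " ")
    has_content <- logical(n * S)
    if (total > 0) {
      tab <- tapply(!is_stop, shift_of_tok, any)
      has_content[as.integer(names(tab))] <- as.logical(tab)
    }
    frac <- tapply(has_content,
                   factor(rep(seq_len(n), each = S), levels = seq_len(n)),
                   mean)
    grade <- gm$intercept + slope * as.numeric(frac) +
      stats::rnorm(n, 0, gm$noise_sd)
    grade <- round(pmin(100, pmax(0, grade)), 3)
    list(propensity = propensity, shift_label = shift_label,
         texts = texts, grade = grade)
  })

  students <- lapply(seq_len(n), function(i) {
    rows <- (i - 1) * S + seq_len(S)
    shifts <- lapply(seq_len(S), function(s) {
      shift_record(s, gen$texts[rows[s]],
                   label_ratings[[gen$shift_label[rows[s]]]])
    })
    student(ids[i], gen$grade[i], shifts)
  })

  pools <- voc$pools
  nc <- length(pools)
  expected_overlap <- matrix(1, nc, nc,
                             dimnames = list(voc$categories, voc$categories))
  if (nc >= 2) {
    for (i in seq_len(nc - 1)) for (j in seq(i + 1, nc)) {
      expected_overlap[i, j] <- expected_overlap[j, i] <-
        jaccard(pools[[i]], pools[[j]])
    }
  }
  offdiag <- expected_overlap[upper.tri(expected_overlap)]
  planted_corr <- config$target_corr %||%
    .sim_corr(slope, config, 50000, derive_seed(config$seed, "calibrate"))

  list(
    corpus = corpus(students,
                    metadata = list(generator = "reflexlens synthetic",
                                    seed = config$seed)),
    truth = list(
      propensity = stats::setNames(gen$propensity, ids),
      pools = pools,
      planted_corr = planted_corr,
      slope_used = slope,
      expected_overlap = expected_overlap,
      class_separability = if (length(offdiag) > 0) 1 - mean(offdiag) else NA,
      config = config
    )
  )
}

#' Frozen named fixtures used by the test suite
#'
#' * `tiny` — 6 students x 14 shifts with a small vocabulary; every
#'   downstream statistic is hand-checkable.
#' * `calibration` — two categories (Reporter, Interpreter) drawing from one
#'   shared vocabulary distribution: labels are exchangeable, so
#'   resampling-null p-values should be uniform.
#' * `separable` — four ladder categories with fully disjoint vocabularies
#'   and no shared core.
#' * `null` — planted completion-grade correlation of exactly 0.
#' * `twin` — two categories whose content pools coincide entirely
#'   (pairwise overlap 1, no core), at n = 400.
#'
#' @param name Fixture name.
#' @param seed Optional seed override (each fixture has a frozen default).
#' @return As [generate_corpus()]: list with `corpus` and `truth`.
#' @export
make_fixture <- function(name, seed = NULL) {
  if (!is_string(name)) rl_value_error("`name` must be a string")
  two_cats <- c(Reporter = 0.5, Interpreter = 0.5)
  cfg <- switch(
    name,
    tiny = synthetic_config(
      n_students = 6, completion_ab = c(2, 2),
      vocab = list(core_size = 8, per_category_size = 10, overlap = 0.25,
                   zipf_exponent = 1),
      comment_len = 6, stopword_fill = 0.5, seed = seed %||% 101),
    calibration = synthetic_config(
      n_students = 24, category_probs = two_cats,
      grade_model = list(intercept = 80, slope = 0, noise_sd = 5),
      vocab = list(core_size = 20, per_category_size = 40, overlap = 1,
                   zipf_exponent = 1.1),
      comment_len = 8, stopword_fill = 0.4, seed = seed %||% 202),
    separable = synthetic_config(
      n_students = 400,
      category_probs = c(Reporter = 0.23, Interpreter = 0.23,
                         Manager = 0.23, Educator = 0.23,
                         `Reporter-Interpreter` = 0.027,
                         `Interpreter-Manager` = 0.027,
                         `Manager-Educator` = 0.026),
      vocab = list(core_size = 0, per_category_size = 50, overlap = 0,
                   zipf_exponent = 1.1),
      comment_len = 9, stopword_fill = 0.5, seed = seed %||% 303),
    null = synthetic_config(
      n_students = 300, target_corr = 0, seed = seed %||% 404),
    twin = synthetic_config(
      n_students = 400, category_probs = two_cats,
      vocab = list(core_size = 0, per_category_size = 50, overlap = 1,
                   zipf_exponent = 1.1),
      comment_len = 9, stopword_fill = 0.5, seed = seed %||% 505),
    rl_value_error(sprintf("unknown fixture '%s'", name))
  )
  generate_corpus(cfg)
}

#' Read a generator configuration from a JSON file
#'
#' Flat key/value JSON whose keys are the arguments of
#' [synthetic_config()] (nested objects for `grade_model` and `vocab`).
#'
#' @param path JSON file path.
#' @return A [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  if (!file.exists(path)) rl_io_error(sprintf("no such file: '%s'", path))
  args <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0) {
    rl_config_error(sprintf("unknown generator key '%s'", unknown[[1]]))
  }
  if (!is.null(args$category_probs)) {
    args$category_probs <- unlist(args$category_probs)
  }
  do.call(synthetic_config, args)
}
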