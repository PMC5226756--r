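# Jaccard similarity and its label-resampling null.

test_that("jaccard matches its definition on the worked examples", {
  expect_equal(jaccard(c("loss", "consciousness"),
                       c("loss", "consciousness")), 1.0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard("a", "b"), 0)
  expect_error(jaccard(character(), character()), class = "rl_value_error")
})

test_that("jaccard agrees with the brute-force double-loop oracle", {
  set.seed(99)
  universe <- paste0("w", 1:12)
  for (i in 1:300) {
    a <- sample(universe, sample(0:8, 1))
    b <- sample(universe, sample(0:8, 1))
    if (length(a) == 0 && length(b) == 0) next
    expect_identical(jaccard(a, b), oracle_jaccard(a, b))
  }
})

test_that("jaccard is symmetric, reflexive and monotone in shared elements", {
  set.seed(7)
  universe <- paste0("w", 1:15)
  for (i in 1:100) {
    a <- sample(universe, sample(1:10, 1))
    b <- sample(universe, sample(1:10, 1))
    expect_identical(jaccard(a, b), jaccard(b, a))
    expect_equal(jaccard(a, a), 1)
    shared <- setdiff(universe, union(a, b))
    if (length(shared) > 0) {
      s <- shared[[1]]
      expect_gte(jaccard(c(a, s), c(b, s)), jaccard(a, b))
    }
  }
})

test_that("jaccard_test is reproducible and satisfies the p-value identity", {
  fx <- make_fixture("calibration")
  sl <- default_stoplist()
  processed <- preprocess_corpus(fx$corpus, sl)
  r1 <- jaccard_test(processed, "Reporter", "Interpreter", k = 20, B = 99,
                     seed = 42)
  r2 <- jaccard_test(processed, "Reporter", "Interpreter", k = 20, B = 99,
                     seed = 42)
  expect_identical(r1, r2) # bit-for-bit determinism
  expect_length(r1$null_J, 99)
  expect_true(all(r1$null_J >= 0 & r1$null_J <= 1))
  expect_equal(r1$p_left, (1 + sum(r1$null_J <= r1$J_obs)) / 100)
  # different seed, different null
  r3 <- jaccard_test(processed, "Reporter", "Interpreter", k = 20, B = 99,
                     seed = 43)
  expect_false(identical(r1$null_J, r3$null_J))
})

test_that("jaccard_test validates its arguments", {
  fx <- make_fixture("tiny")
  sl <- default_stoplist()
  expect_error(jaccard_test(fx$corpus, "Reporter", "Interpreter", k = 5,
                            B = 0, seed = 1, stoplist = sl),
               class = "rl_value_error")
  expect_error(jaccard_test(fx$corpus, "Reporter", "Reporter", k = 5,
                            B = 10, seed = 1, stoplist = sl),
               class = "rl_value_error")
  only_hybrid <- build_corpus(list(c("alpha beta", "gamma delta")),
                              list(c("Reporter-Interpreter",
                                     "Reporter-Interpreter")))
  expect_error(jaccard_test(only_hybrid, "Reporter", "Interpreter", k = 5,
                            B = 10, seed = 1, stoplist = empty_stoplist()),
               class = "rl_empty_category_error")
})

test_that("the pairwise matrix covers all pairs order-independently", {
  fx <- make_fixture("separable")
  sl <- default_stoplist()
  processed <- preprocess_corpus(fx$corpus, sl)
  cats <- c("Reporter", "Interpreter", "Manager", "Educator")
  m1 <- pairwise_jaccard_matrix(processed, cats, k = 30, B = 19, seed = 5)
  expect_length(m1$results, 6)
  m2 <- pairwise_jaccard_matrix(processed, rev(cats), k = 30, B = 19,
                                seed = 5)
  df1 <- as.data.frame(m1)
  df2 <- as.data.frame(m2)
  df2 <- df2[match(df1$pair, df2$pair), ]
  rownames(df2) <- NULL
  expect_identical(df1, df2) # permuting categories only permutes rows

  holm <- pairwise_jaccard_matrix(processed, cats, k = 30, B = 19, seed = 5,
                                  p_adjust = "holm")
  expect_equal(as.data.frame(holm)$p_adj,
               stats::p.adjust(df1$p_left, "holm"))
})

test_that("a planted overlap gradient is recovered in J_obs order", {
  cats <- c("Reporter", "Manager", "Educator")
  O <- matrix(0, 3, 3, dimnames = list(cats, cats))
  O["Manager", "Educator"] <- O["Educator", "Manager"] <- 0.8
  O["Reporter", "Manager"] <- O["Manager", "Reporter"] <- 0.1
  O["Reporter", "Educator"] <- O["Educator", "Reporter"] <- 0.1
  cfg <- synthetic_config(
    n_students = 200,
    category_probs = c(Reporter = 1, Manager = 1, Educator = 1) / 3,
    vocab = list(core_size = 0, per_category_size = 40, overlap = O,
                 zipf_exponent = 1),
    comment_len = 9, stopword_fill = 0.4, seed = 77)
  out <- generate_corpus(cfg)
  processed <- preprocess_corpus(out$corpus, default_stoplist())
  m <- pairwise_jaccard_matrix(processed, cats, k = 40, B = 19, seed = 3)
  df <- as.data.frame(m)
  j <- setNames(df$J_obs, df$pair)
  expect_gt(j[["Educator-Manager"]], j[["Manager-Reporter"]])
  expect_gt(j[["Educator-Manager"]], j[["Educator-Reporter"]])
  # and the planted expected ordering matches the ground truth matrix
  expect_gt(out$truth$expected_overlap["Manager", "Educator"],
            out$truth$expected_overlap["Reporter", "Manager"])
})
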