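# Per-student effort statistics and grade-association tests.

test_that("student_effort computes completion fraction and mean length", {
  sl <- mini_stoplist()
  texts <- c(rep("chest pain", 7), rep("", 7))
  stu <- student("s1", 80, lapply(seq_along(texts), function(i) {
    shift_record(i, texts[[i]])
  }))
  eff <- student_effort(stu, sl)
  expect_equal(eff$n_shifts, 14)
  expect_equal(eff$n_complete, 7)
  expect_equal(eff$completion_fraction, 0.5)
  expect_equal(eff$mean_length, 1) # 7 shifts x 2 tokens / 14

  all_empty <- student("s2", 70, list(shift_record(1, ""), shift_record(2, "")))
  eff2 <- student_effort(all_empty, sl)
  expect_equal(eff2$completion_fraction, 0)
  expect_equal(eff2$mean_length, 0)

  # token counts [10, 0] -> mean 5; raw basis counts stopwords too
  ten <- paste(rep("the", 10), collapse = " ")
  stu3 <- student("s3", 75, list(shift_record(1, ten), shift_record(2, "")))
  expect_equal(student_effort(stu3, sl)$mean_length, 5)
  expect_equal(student_effort(stu3, sl, length_basis = "content")$mean_length, 0)

  expect_error(student_effort(student("s4", 80, list()), sl),
               class = "rl_value_error")
})

test_that("pearson_r matches an explicit sum-formula oracle", {
  x <- c(1, 2, 4, 5, 8)
  y <- c(3, 1, 5, 2, 7)
  n <- length(x)
  # independent arithmetic: raw-moment formula
  r_oracle <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  fit <- pearson_r(x, y)
  expect_equal(fit$r, r_oracle, tolerance = 1e-12)
  expect_equal(fit$r_squared, r_oracle^2, tolerance = 1e-12)
  # regression line through the centroid
  expect_equal(fit$intercept + fit$slope * mean(x), mean(y),
               tolerance = 1e-12)

  exact <- pearson_r(x, 2 * x + 1)
  expect_equal(exact$r, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  # orthogonal-after-centering construction
  xo <- c(-1, 0, 1, 0)
  yo <- c(0, 1, 0, -1)
  expect_equal(pearson_r(xo, yo)$r, 0)
})

test_that("pearson_r is invariant under positive affine transforms", {
  set.seed(5)
  x <- rnorm(30)
  y <- x + rnorm(30)
  base <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 10, y)$r, base, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.2 * y - 4)$r, base, tolerance = 1e-12)
})

test_that("pearson_r rejects degenerate input", {
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "rl_degenerate_error")
  expect_error(pearson_r(1:2, 1:2), class = "rl_value_error")
  expect_error(pearson_r(1:4, 1:3), class = "rl_value_error")
})

test_that("corr_t_test follows the closed form", {
  expect_equal(corr_t_test(0.5, 27)$t, 0.5 * 5 / sqrt(0.75),
               tolerance = 1e-12)
  z <- corr_t_test(0, 30)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  perfect <- corr_t_test(1, 10)
  expect_equal(perfect$t, Inf)
  expect_equal(perfect$p, 0)
  expect_error(corr_t_test(0.5, 2), class = "rl_value_error")
  expect_error(corr_t_test(1.2, 10), class = "rl_value_error")
  # p agrees with the t distribution
  tt <- corr_t_test(0.4, 20)
  expect_equal(tt$p, 2 * stats::pt(-abs(tt$t), 18))
})

test_that("completion split uses a strict threshold", {
  eff <- data.frame(completion_fraction = c(0.6, 0.5, 0.4),
                    final_grade = c(90, 85, 80))
  sp <- split_by_completion(eff)
  expect_equal(sp$completers$completion_fraction, 0.6)
  expect_equal(sp$noncompleters$completion_fraction, c(0.5, 0.4))

  all_up <- split_by_completion(eff, threshold = 0)
  expect_equal(nrow(all_up$completers), 3) # any completion counts
  none <- split_by_completion(eff, threshold = 1)
  expect_equal(nrow(none$completers), 0)
  expect_error(split_by_completion(eff[0, ]), class = "rl_value_error")
})

test_that("ks_2sample matches the brute-force ECDF sweep", {
  expect_equal(ks_2sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_2sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  expect_equal(ks_2sample(c(1, 2), c(1.5, 2.5))$D, 0.5)
  set.seed(12)
  for (i in 1:300) {
    a <- round(rnorm(sample(2:12, 1)), 1)
    b <- round(rnorm(sample(2:12, 1), mean = runif(1, -1, 1)), 1)
    expect_equal(ks_2sample(a, b)$D, oracle_ks_d(a, b), tolerance = 1e-12)
  }
  expect_error(ks_2sample(numeric(), 1:3), class = "rl_value_error")
})

test_that("group_summary uses linear-interpolation quantiles and the notch", {
  g <- group_summary(1:5)
  expect_equal(g$median, 3)
  expect_equal(g$iqr, 2)
  expect_equal(g$notch_ci, 3 + c(-1, 1) * 1.57 * 2 / sqrt(5))

  single <- group_summary(7)
  expect_equal(single$median, 7)
  expect_equal(single$iqr, 0)
  expect_equal(single$notch_ci, c(7, 7))

  sym <- group_summary(c(-3, -1, 0, 1, 3))
  expect_equal(mean(sym$notch_ci), sym$median) # symmetric about the median
  expect_true(g$notch_ci[1] <= g$median && g$median <= g$notch_ci[2])
  expect_equal(g$whiskers,
               unname(stats::quantile(1:5, c(0.02, 0.97), type = 7)))
})

test_that("grade_association assembles a coherent report", {
  out <- make_fixture("tiny")
  assoc <- grade_association(out$corpus, default_stoplist())
  expect_equal(assoc$n, 6)
  expect_true(abs(assoc$r_completion) <= 1)
  expect_equal(assoc$p_completion,
               corr_t_test(assoc$r_completion, assoc$n)$p)
  groups <- assoc$group_split
  total <- sum(c(groups$completers$n, groups$noncompleters$n))
  expect_equal(total, 6)
})
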