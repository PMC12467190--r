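test_that("score reconstruction inverts printed summaries", {
  expect_equal(reconstruct_scores(likert_summary("Qc", 5, 0, 5, 0, 6)),
               rep(5L, 6))
  q1 <- likert_summary("Q1", 4.5, 0.55, 4.5, 1, 6)
  expect_equal(sort(reconstruct_scores(q1)), c(4, 4, 4, 5, 5, 5))
  q9 <- likert_summary("Q9", 4.83, 0.41, 5, 0, 6)
  expect_equal(sort(reconstruct_scores(q9)), c(4, 5, 5, 5, 5, 5))
  # an impossible summary is flagged, not silently matched
  expect_error(reconstruct_scores(likert_summary("Qx", 4.9, 2.0, 1, 0, 6)),
               "no score multiset")
  # an ambiguous summary lists its candidates
  expect_error(reconstruct_scores(likert_summary("Qa", 3, 1.1, 3, 1.5, 6)),
               "ambiguous|no score")
})

test_that("reconstruction inverts summarization on every 6-score multiset", {
  counts <- ctdenoise:::likert_multisets(6)
  expect_equal(nrow(counts), choose(10, 4))   # 210 multisets
  n_ambiguous <- 0L
  for (i in seq_len(nrow(counts))) {
    sc <- ctdenoise:::counts_to_scores(counts[i, ])
    st <- ctdenoise:::summarize_scores(sc)
    summ <- likert_summary("q", st$mean, st$sd, st$median, st$iqr, 6)
    got <- tryCatch(reconstruct_scores(summ), error = function(e) e)
    if (inherits(got, "error")) {
      expect_match(conditionMessage(got), "ambiguous")
      n_ambiguous <- n_ambiguous + 1L
    } else {
      expect_equal(sort(got), sort(sc))
    }
  }
  # 2-d.p. rounding leaves at most a handful of colliding summaries
  expect_lt(n_ambiguous, 10)
})

test_that("t statistic, p-value and effect size match closed forms", {
  q1 <- c(4, 4, 4, 5, 5, 5)
  tt <- one_sample_t(q1, mu0 = 3)
  expect_equal(round(tt$t, 2), 6.71)
  expect_equal(tt$df, 5)
  # independent closed form
  expect_equal(tt$t, (mean(q1) - 3) / (sd(q1) / sqrt(6)))
  expect_equal(tt$p_raw, 2 * pt(-abs(tt$t), 5))
  expect_equal(round(cohens_d(q1), 2), 2.74)

  q9 <- c(4, 5, 5, 5, 5, 5)
  t9 <- one_sample_t(q9)
  expect_equal(round(t9$t, 2), 11.00)
  expect_equal(signif(t9$p_raw, 3), 0.000108)
  expect_equal(round(cohens_d(q9), 2), 4.49)

  # mean at the midpoint gives t = 0, p = 1
  t0 <- one_sample_t(c(2, 3, 4, 2, 3, 4))
  expect_equal(t0$t, 0)
  expect_equal(t0$p_raw, 1)
  expect_error(one_sample_t(rep(4, 6)), "degenerate")
  # t = d * sqrt(n) exactly
  for (s in list(q1, q9, c(1, 2, 3, 4, 5, 5))) {
    expect_equal(one_sample_t(s)$t, cohens_d(s) * sqrt(length(s)))
  }
})

test_that("holm adjustment matches hand computation in both variants", {
  p <- c(0.03, 0.001, 0.02)
  # by hand: sorted (0.001, 0.02, 0.03) x (3, 2, 1) = (0.003, 0.04, 0.03),
  # monotonicity lifts the last to 0.04
  expect_equal(holm_adjust(p), c(0.04, 0.003, 0.04))
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(rep(0.2, 4)), rep(0.8, 4))
  # never below raw, capped at 1
  p2 <- c(0.9, 0.5, 0.7)
  expect_true(all(holm_adjust(p2) >= p2))
  expect_true(all(holm_adjust(p2) <= 1))
  # tie-averaged variant: tied pair at ranks 1-2 gets mean(3, 2) = 2.5
  expect_equal(holm_adjust(c(0.01, 0.01, 0.5), ties = "average"),
               c(0.025, 0.025, 0.5))
  expect_error(holm_adjust(c(0.5, 0)), "0, 1")
})

test_that("confidence intervals match the printed-table convention", {
  q9 <- c(4, 5, 5, 5, 5, 5)
  ci <- ci95(q9)
  expect_equal(round(ci$width, 2), 0.43)
  expect_equal(ci$width, qt(0.975, 5) * sd(q9) / sqrt(6))
  expect_equal(ci$low, mean(q9) - ci$width)
  q4 <- c(3, 4, 5, 5, 5, 5)
  expect_equal(round(ci95(q4)$se, 2), 0.34)
  expect_equal(ci95(rep(3:4, 3))$width > 0, TRUE)
})

test_that("the full pipeline reproduces the nine-question table", {
  res <- analyze_reader_study(table5_summaries())
  expect_equal(round(res$t, 2),
               c(6.71, 6.71, 7.91, 4.39, 6.32, 6.32, 5.00, 2.71, 11.00))
  expect_equal(round(res$cohens_d, 2),
               c(2.74, 2.74, 3.23, 1.79, 2.58, 2.58, 2.04, 1.11, 4.49))
  expect_equal(round(res$se, 2),
               c(0.22, 0.22, 0.21, 0.34, 0.21, 0.21, 0.17, 0.31, 0.17))
  expect_equal(round(res$ci_width, 2),
               c(0.57, 0.57, 0.54, 0.88, 0.54, 0.54, 0.43, 0.79, 0.43))
  expect_equal(round(res$t_crit, 2), rep(2.57, 9))
  # raw and tie-averaged Holm p-values at the precision they are printed
  expect_equal(signif(res$p_raw[res$question_id == "Q9"], 3), 0.000108)
  expect_equal(signif(res$p_holm[res$question_id == "Q9"], 3), 0.000972)
  expect_equal(signif(res$p_holm[res$question_id == "Q1"], 2), 0.0072)
  expect_equal(signif(res$p_holm[res$question_id == "Q5"], 3), 0.00655)
  # a single question passes through unadjusted
  one <- analyze_reader_study(table5_summaries()[9, , drop = FALSE])
  expect_equal(one$p_holm, one$p_raw)
})

test_that("analysis results survive a csv export round trip", {
  res <- analyze_reader_study(table5_summaries())
  f <- tempfile(fileext = ".csv")
  write.csv(res[, setdiff(names(res), "scores")], f, row.names = FALSE)
  # re-analyze from the reconstructed raw scores written long-form
  long <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    data.frame(question_id = res$question_id[i],
               rater_id = 1:6,
               score = as.integer(strsplit(res$scores[i], ",")[[1]]))
  }))
  f2 <- tempfile(fileext = ".csv")
  write.csv(long, f2, row.names = FALSE)
  res2 <- analyze_reader_study(scores = read_reader_scores(f2))
  expect_equal(res2$t, res$t)
  expect_equal(res2$p_holm, res$p_holm)
  expect_equal(res2$cohens_d, res$cohens_d)
})
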