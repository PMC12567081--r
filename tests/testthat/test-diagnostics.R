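# Diagnostic metrics, grading, LOO classifier, printed-count verification.

test_that("se_sp_ac reproduces the published worked examples", {
  r <- se_sp_ac(confusion_counts(24, 2, 23, 3))
  expect_equal(r$se, 92.3)
  expect_equal(r$sp, 88.5)
  expect_equal(r$ac, 90.4)
  expect_true(r$balanced)
  perfect <- se_sp_ac(confusion_counts(26, 0, 26, 0))
  expect_equal(c(perfect$se, perfect$sp, perfect$ac), c(100, 100, 100))
  expect_error(se_sp_ac(confusion_counts(0, 0, 5, 1)), class = "jtez_invalid_argument")
})

test_that("half-up rounding matches the printed convention", {
  expect_equal(jtez:::.round_half_up(100*24/26), 92.3)
  expect_equal(jtez:::.round_half_up(100*41/52), 78.8)
  expect_equal(jtez:::.round_half_up(100*25/26), 96.2)
  expect_equal(jtez:::.round_half_up(0.25, 1), 0.3)  # half-up, not banker's
})

test_that("balanced accuracy identity holds when group sizes match", {
  set.seed(10)
  for (i in 1:50) {
    q <- sample(5:40, 1)
    n <- sample(0:q, 1); h <- sample(0:q, 1)
    r <- se_sp_ac(confusion_counts(q - n, n, q - h, h))
    expect_lt(abs(r$ac - (r$se + r$sp)/2), 0.1)  # equal up to rounding
  }
})

test_that("accuracy is monotone in the true-positive count", {
  acs <- vapply(0:26, function(N) {
    se_sp_ac(confusion_counts(N, 26 - N, 20, 6))$ac
  }, numeric(1))
  expect_true(all(diff(acs) >= 0))
})

test_that("grading maps accuracies onto the five labels with closed-above bounds", {
  expect_equal(accuracy_grade(96.2), "excellent")
  expect_equal(accuracy_grade(94.2), "very good")
  expect_equal(accuracy_grade(88.5), "good")
  expect_equal(accuracy_grade(82.7), "satisfactory")
  expect_equal(accuracy_grade(80.0), "unsatisfactory")
  expect_equal(accuracy_grade(c(85, 90, 95, 95.1)),
               c("satisfactory", "good", "very good", "excellent"))
  expect_error(accuracy_grade(101), class = "jtez_invalid_argument")
})

test_that("perfectly separated groups classify without error", {
  counts <- classify_loo(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(counts$n_tp, 2)
  expect_equal(counts$n_fn, 0)
  expect_equal(counts$h_tn, 2)
  expect_equal(counts$h_fp, 0)
  # polarity is inferred: separation in the other direction works too
  counts2 <- classify_loo(c(0.8, 0.9, 0.85), c(0.1, 0.2, 0.15))
  expect_equal(counts2$n_tp + counts2$h_tn, 6)
})

test_that("exchangeable groups classify at chance level", {
  set.seed(314)
  acs <- replicate(20, {
    x <- rnorm(26); y <- rnorm(26)
    se_sp_ac(classify_loo(x, y))$ac
  })
  # binomial 95% band around 50% for 52 draws is about +/- 13.6
  expect_gt(mean(acs), 50 - 15)
  expect_lt(mean(acs), 50 + 15)
  expect_true(all(acs > 20 & acs < 80))
})

test_that("degenerate separation warns but still returns counts", {
  expect_warning(counts <- classify_loo(rep(1, 5), rep(1, 5)),
                 "degenerate")
  expect_equal(counts$q_size, 5)
})

test_that("representativeness flags high fold deviation and passes boundaries", {
  r0 <- representativeness(rep(0.5, 10))
  expect_equal(r0$fold_sd, 0)
  expect_true(r0$pass)
  # construct a marker whose fold-mean deviation is exactly at the threshold:
  # fold sd of leave-one-out means is sd(x)/ (n-1) * sqrt((n-1)/n) ... use
  # calibration by scaling instead
  set.seed(1)
  x <- rnorm(10)
  base_sd <- representativeness(x)$fold_sd
  at <- representativeness(x*(0.025/base_sd))
  expect_true(at$pass)
  expect_equal(at$fold_sd, 0.025, tolerance = 1e-12)
  over <- representativeness(x*(0.03/base_sd))
  expect_false(over$pass)
  # data-frame input: one row per numeric column
  df <- data.frame(z3 = rnorm(8), z4 = rnorm(8), label = letters[1:8])
  rr <- representativeness(df)
  expect_equal(rr$marker, c("z3", "z4"))
})

test_that("bundled counts table satisfies its invariants", {
  tab <- reference_counts()
  expect_equal(nrow(tab), 24)
  expect_true(all(tab$n_tp + tab$n_fn == 26))
  expect_true(all(tab$h_tn + tab$h_fp == 26))
})

test_that("recomputed metrics match the printed table except one flagged cell", {
  v <- verify_printed_counts()
  expect_true(all(v$se_match))
  expect_true(all(v$ac_match))
  bad <- v[!v$sp_match, ]
  # exactly one printed specificity is internally inconsistent with its counts
  expect_equal(nrow(bad), 1)
  expect_equal(bad$method, "JT")
  expect_equal(bad$parameter, "LB")
  expect_equal(bad$comparison, "stage2")
  expect_equal(bad$sp, 92.3)        # 24/26 recomputed
  expect_equal(bad$sp_printed, 88.5)
  # the row's accuracy is consistent with the counts, which pins the typo to
  # the printed percentage, not the printed counts
  expect_true(bad$ac_match)
})

test_that("headline accuracies and grades recompute from their counts", {
  v <- verify_printed_counts()
  pick <- function(m, c, p) v[v$method == m & v$comparison == c & v$parameter == p, ]
  expect_equal(pick("JT", "stage1", "CB")$ac, 90.4)
  expect_equal(pick("JT", "stage2", "CB")$ac, 96.2)
  expect_equal(pick("JT", "stage2", "CB")$grade, "excellent")
  expect_equal(pick("JT", "stage2", "LB")$ac, 94.2)
  expect_equal(pick("JT", "stage2", "LB")$grade, "very good")
  expect_equal(pick("MMT", "stage1", "CB")$ac, 78.8)
  expect_equal(pick("MMT", "stage1", "CB")$grade, "unsatisfactory")
  expect_equal(pick("JT", "stage1", "LD")$ac, 82.7)
})

test_that("row-level invariant violations are reported without aborting", {
  tab <- data.frame(n_tp = c(24, -1), n_fn = c(2, 3), h_tn = c(23, 20), h_fp = c(3, 6))
  v <- verify_printed_counts(tab)
  expect_true(is.na(v$row_error[1]))
  expect_false(is.na(v$row_error[2]))
  expect_equal(v$ac[1], 90.4)
})

test_that("tidy and glance summarize a diagnostic result", {
  r <- se_sp_ac(confusion_counts(24, 2, 23, 3), marker_id = "Z2[CB]")
  td <- tidy(r)
  expect_equal(td$estimate, c(92.3, 88.5, 90.4))
  gl <- glance(r)
  expect_equal(gl$grade, "very good")
  expect_equal(gl$marker_id, "Z2[CB]")
})
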