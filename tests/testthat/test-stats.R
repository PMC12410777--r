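test_that("questionnaire change is the mean-item difference", {
  expect_equal(gad7_change(rep(0, 7), rep(3, 7)), 3)
  x <- runif(7, 0, 3)
  expect_equal(gad7_change(x, x), 0)
  expect_equal(gad7_change(rep(1, 7), rep(1.5, 7)), 0.5)
  expect_error(gad7_change(1:6, 1:7), "7 items")
})

test_that("median split assigns groups deterministically", {
  set.seed(61)
  chg <- setNames(sample(seq(0.1, 1.7, by = 0.1)), sprintf("P%02d", 1:17))
  g <- median_split(chg)
  expect_equal(sum(g$group == "anxious"), 9)
  expect_equal(sum(g$group == "non_anxious"), 8)
  # every anxious change score >= every non-anxious one
  expect_gte(min(chg[g$group == "anxious"]), max(chg[g$group == "non_anxious"]))

  g4 <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(sort(names(which(g4$group == "anxious"))), c("c", "d"))
  expect_equal(sort(names(which(g4$group == "non_anxious"))), c("a", "b"))

  # order invariance
  g_rev <- median_split(rev(chg))
  expect_equal(g_rev$group[names(chg)], g$group[names(chg)])

  expect_error(median_split(c(a = 1, b = 2, c = 2, d = 2, e = 3)), "tie")
  expect_error(median_split(c(a = 1, b = 2)), "at least 4")
})

test_that("median split sizes differ by at most one for random inputs", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(4:23, 1)
    chg <- rnorm(n)
    while (anyDuplicated(chg)) chg <- rnorm(n)
    g <- median_split(setNames(chg, seq_len(n)))
    expect_lte(abs(sum(g$group == "anxious") - sum(g$group == "non_anxious")), 1)
    expect_gte(min(chg[g$group == "anxious"]), max(chg[g$group == "non_anxious"]))
  }
})

test_that("rank-sum statistic and exact p match hand enumeration", {
  r <- ranksum_test(c(3, 4), c(1, 2))
  expect_equal(r$statistic, 7)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  r2 <- ranksum_test(c(1, 2), c(1, 2))
  expect_equal(r2$p_value, 1)

  expect_error(ranksum_test(1, c(1, 2)), "at least 2")
})

test_that("exact p equals exhaustive enumeration for all small group sizes", {
  set.seed(63)
  for (n1 in 2:8) {
    for (n2 in 2:(12 - n1)) {
      if (n2 < 2) next
      x <- rnorm(n1)
      y <- rnorm(n2)
      r <- ranksum_test(x, y)
      expect_equal(r$p_value, enumerate_ranksum_p(x, y), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("exact p at the study's group sizes matches enumeration and wilcox.test", {
  set.seed(64)
  for (i in 1:3) {
    x <- rnorm(9, mean = i * 0.3)
    y <- rnorm(8)
    r <- ranksum_test(x, y)
    expect_equal(r$p_value, enumerate_ranksum_p(x, y), tolerance = 1e-12)
    wt <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(r$p_value, unname(wt$p.value), tolerance = 1e-12)
    expect_equal(r$u, unname(wt$statistic))
  }
})

test_that("Cohen's d uses the pooled standard deviation", {
  set.seed(65)
  x <- rnorm(50); x <- (x - mean(x)) / sd(x) + 1
  y <- rnorm(50); y <- (y - mean(y)) / sd(y)
  expect_equal(cohens_d(x, y), 1, tolerance = 1e-9)
  expect_equal(cohens_d(y, y), 0)
  expect_warning(d0 <- cohens_d(rep(1, 5), rep(1, 4)), "undefined")
  expect_true(is.na(d0))
  # group summaries (means 79.445/66.75, SDs 13.424/7.184, n 9/8): hand value
  set.seed(66)
  mk <- function(n, m, s) { v <- rnorm(n); m + s * (v - mean(v)) / sd(v) }
  expect_equal(cohens_d(mk(9, 79.445, 13.424), mk(8, 66.75, 7.184)),
               1.158, tolerance = 1e-3)
})

test_that("Benjamini-Hochberg adjustment matches the step-up rule", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correct(0.2), 0.2)
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  set.seed(67)
  p <- runif(40)
  expect_equal(bh_correct(p), bh_by_hand(p))
  expect_true(all(bh_correct(p) >= p))
  expect_true(all(bh_correct(p) <= 1))
  expect_error(bh_correct(c(0.5, 0)), "0, 1")
  expect_error(bh_correct(c(0.5, 1.2)), "0, 1")
})

test_that("per-epoch tests produce masks of the right shape", {
  set.seed(68)
  mat <- matrix(rnorm(17 * 55), 17, 55, dimnames = list(sprintf("P%02d", 1:17), NULL))
  g <- median_split(setNames(seq(0.1, 1.7, 0.1), sprintf("P%02d", 1:17)))
  tc <- timecourse_tests(mat, g)
  expect_length(tc$p, 55)
  expect_length(tc$mask, 55)
  expect_true(all(tc$p > 0 & tc$p <= 1))
  one <- timecourse_tests(mat[, 1, drop = FALSE], g)
  expect_length(one$mask, 1)
  # strong separation -> mask almost everywhere
  sep <- mat
  sep[g$group[rownames(sep)] == "anxious", ] <-
    sep[g$group[rownames(sep)] == "anxious", ] + 3
  tc2 <- timecourse_tests(sep, g)
  expect_gt(mean(tc2$mask), 0.9)
})

test_that("per-epoch type-I error is near nominal under the null", {
  set.seed(69)
  hits <- 0; total <- 0
  for (i in 1:400) {
    mat <- matrix(rnorm(17 * 10), 17, 10, dimnames = list(sprintf("P%02d", 1:17), NULL))
    g <- median_split(setNames(rnorm(17), sprintf("P%02d", 1:17)))
    tc <- timecourse_tests(mat, g)
    hits <- hits + sum(tc$mask); total <- total + length(tc$mask)
  }
  expect_gt(hits / total, 0.03)
  expect_lt(hits / total, 0.07)
})

test_that("whole-task test reports descriptives and excludes empty participants", {
  set.seed(70)
  mat <- matrix(rnorm(17 * 55), 17, 55, dimnames = list(sprintf("P%02d", 1:17), NULL))
  g <- median_split(setNames(seq(0.1, 1.7, 0.1), sprintf("P%02d", 1:17)))
  anx_ids <- names(which(g$group == "anxious"))
  mat[anx_ids, ] <- mat[anx_ids, ] + 2
  ts <- whole_task_test(mat, g, measure = "X", units = "au")
  expect_equal(ts$n_anx, 9); expect_equal(ts$n_non, 8)
  expect_equal(ts$mean_anx, mean(rowMeans(mat[anx_ids, ])))
  expect_lt(ts$p_value, 0.01)
  expect_gt(ts$cohens_d, 1)
  expect_lte(ts$ci95_anx[1], ts$median_anx)
  expect_gte(ts$ci95_anx[2], ts$median_anx)

  mat["P01", ] <- NA
  expect_message(ts2 <- whole_task_test(mat, g), "P01")
  expect_equal(ts2$n_anx + ts2$n_non, 16)
})

test_that("PSD group comparison corrects across the right grid", {
  set.seed(71)
  n <- 17
  ids <- sprintf("P%02d", 1:n)
  g <- median_split(setNames(seq(0.1, 1.7, 0.1), ids))
  anx <- g$group[ids] == "anxious"
  freq <- 0:50
  # roll-like: single channel, power boosted in 5-50 Hz for the anxious group
  arr <- array(rexp(n * 1 * 51), dim = c(n, 1, 51), dimnames = list(ids, "roll", freq))
  arr[anx, 1, freq >= 5] <- arr[anx, 1, freq >= 5] + 6
  cmp <- psd_group_comparison(list(freq = freq, psd = arr), g, "per_bin")
  expect_gt(mean(cmp$mask_corrected[cmp$freq >= 5]), 0.85)
  expect_lt(mean(cmp$mask_corrected[cmp$freq < 5]), 0.5)
  expect_true(all(cmp$p_corrected >= cmp$p_raw))

  # single-cell grid: corrected equals raw
  arr1 <- arr[, , 10, drop = FALSE]
  cmp1 <- psd_group_comparison(list(freq = 9, psd = arr1), g, "per_bin", fmin = 0)
  expect_equal(cmp1$p_corrected, cmp1$p_raw)

  # EEG-like: channels x bands with an effect only in theta
  nch <- 5
  arr2 <- array(rexp(n * nch * 51), dim = c(n, nch, 51),
                dimnames = list(ids, paste0("ch", 1:nch), freq))
  arr2[anx, , freq >= 4 & freq < 8] <- arr2[anx, , freq >= 4 & freq < 8] + 8
  cmp2 <- psd_group_comparison(list(freq = freq, psd = arr2), g, "per_channel_band")
  expect_equal(dim(cmp2$p_raw), c(nch, 5L))
  expect_true(all(cmp2$mask_corrected[, "theta"]))
  expect_false(any(cmp2$mask_corrected[, "gamma"]))
})

test_that("corrected PSD maps make almost no discoveries under the null", {
  set.seed(72)
  ids <- sprintf("P%02d", 1:17)
  discoveries <- 0
  for (i in 1:150) {
    g <- median_split(setNames(rnorm(17), ids))
    arr <- array(rexp(17 * 1 * 30), dim = c(17, 1, 30),
                 dimnames = list(ids, "roll", 1:30))
    cmp <- psd_group_comparison(list(freq = 1:30, psd = arr), g, "per_bin")
    discoveries <- discoveries + sum(cmp$mask_corrected)
  }
  # mean corrected discoveries per cohort stays near zero (FDR control)
  expect_lt(discoveries / 150, 0.25)
})
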