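# Dice, precision/recall, per-case vs global aggregation, patient-level
# cross-validation, the paired t-test and repeated-run summaries.

test_that("dice coefficient: identity, disjoint, hand case, empty flag", {
  m <- matrix(c(1, 1, 0, 0, 2, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1), 4, 4)
  expect_equal(as.numeric(dice_coefficient(m, m, 1)), 1)

  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  expect_equal(as.numeric(dice_coefficient(a, b, 1)), 0)

  # |A| = 2, |B| = 3, |A intersect B| = 1 -> 0.4
  p <- matrix(0L, 4, 4); p[1, 1] <- 1L; p[2, 2] <- 1L
  t_ <- matrix(0L, 4, 4); t_[1, 1] <- 1L; t_[3, 3] <- 1L; t_[4, 4] <- 1L
  expect_equal(as.numeric(dice_coefficient(p, t_, 1)), 0.4)
  expect_equal(as.numeric(dice_coefficient(p, t_, 1)), oracle_dice(p, t_, 1))

  # class absent from both masks: defined as 1, flagged empty
  e <- dice_coefficient(a, b, 7)
  expect_equal(as.numeric(e), 1)
  expect_true(attr(e, "empty"))

  expect_error(dice_coefficient(matrix(0, 2, 2), matrix(0, 3, 3), 1),
               "different shapes")
})

test_that("dice is symmetric, bounded, and equals 2TP/(2TP+FP+FN)", {
  set.seed(40)
  for (rep in 1:20) {
    p <- rand_mask(8, 8, 4)
    t_ <- rand_mask(8, 8, 4)
    for (cls in 0:3) {
      d1 <- as.numeric(dice_coefficient(p, t_, cls))
      d2 <- as.numeric(dice_coefficient(t_, p, cls))
      expect_identical(d1, d2)
      expect_true(d1 >= 0 && d1 <= 1)
      cc <- confusion_counts(p, t_, cls)
      denom <- 2 * cc$tp + cc$fp + cc$fn
      if (denom > 0) expect_identical(d1, 2 * cc$tp / denom)
    }
  }
})

test_that("precision and recall from counts, with undefined-denominator flags", {
  expect_equal(precision_recall(list(tp = 5, fp = 0, fn = 0)),
               list(precision = 1, recall = 1))
  pr <- precision_recall(list(tp = 3, fp = 1, fn = 2))
  expect_equal(pr$precision, 0.75)
  expect_equal(pr$recall, 0.6)
  expect_true(is.na(precision_recall(list(tp = 0, fp = 0, fn = 3))$precision))
  expect_error(precision_recall(list(tp = -1, fp = 0, fn = 0)), "negative")
})

test_that("per-case vs global Dice: collapse, pooled-count oracle, permutation", {
  set.seed(41)
  v1 <- list(pred = rand_mask(6, 6, 3), truth = rand_mask(6, 6, 3))
  single <- dice_per_case_and_global(list(v1), 1)
  expect_identical(single$per_case, single$global)

  # volume A perfect, volume B (different size) entirely missed
  pa <- matrix(0L, 4, 4); pa[1:2, 1:2] <- 1L
  va <- list(pred = pa, truth = pa)                       # Dice 1
  tb <- matrix(0L, 8, 8); tb[1:4, 1:4] <- 1L
  vb <- list(pred = matrix(0L, 8, 8), truth = tb)         # Dice 0
  r <- dice_per_case_and_global(list(va, vb), 1)
  expect_equal(r$per_case, 0.5)
  # pooled counts: intersection 4, |A| = 4, |B| = 4 + 16
  expect_equal(r$global, 2 * 4 / (4 + 20))
  expect_false(isTRUE(all.equal(r$global, r$per_case)))

  r2 <- dice_per_case_and_global(list(vb, va), 1)
  expect_identical(r2$per_case, r$per_case)
  expect_identical(r2$global, r$global)

  expect_error(dice_per_case_and_global(list(), 1), "empty")
})

test_that("patient-level k-fold splits are disjoint, balanced and seeded", {
  f <- kfold_split_patients(1:10, k = 5, seed = 1)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 2))
  expect_setequal(unlist(f), 1:10)

  expect_identical(kfold_split_patients(1:10, 5, seed = 3),
                   kfold_split_patients(1:10, 5, seed = 3))

  ids <- sprintf("pat%03d", 1:356)
  f356 <- kfold_split_patients(ids, k = 5, seed = 2)
  expect_identical(sort(lengths(f356), decreasing = TRUE),
                   c(72L, 71L, 71L, 71L, 71L))
  expect_identical(sort(unlist(f356)), sort(ids))
  expect_equal(sum(duplicated(unlist(f356))), 0)

  expect_error(kfold_split_patients(1:3, k = 5), "at least k")
})

test_that("paired t-test matches the textbook formula and flags degeneracy", {
  a <- c(3, 5, 7); b <- c(2, 3, 4)        # diffs 1, 2, 3
  r <- paired_t_test(a, b)
  o <- oracle_paired_t(a, b)
  expect_equal(r$t, o$t, tolerance = 1e-6)
  expect_equal(r$p, o$p, tolerance = 1e-6)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_false(r$degenerate)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_false(same$significant)
  expect_equal(same$p, 1)

  const <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(const$degenerate)
  expect_true(const$significant)
  expect_equal(const$p, 0)

  expect_error(paired_t_test(1:3, 1:4), "different lengths")
})

test_that("repeated-run aggregation: mean, sample std, permutation invariance", {
  runs <- list(c(dice = 0.8), c(dice = 0.8))
  agg <- aggregate_runs(runs)
  expect_equal(agg$mean, 0.8)
  expect_equal(agg$std, 0)

  runs2 <- list(c(dice = 0.7), c(dice = 0.9))
  agg2 <- aggregate_runs(runs2)
  expect_equal(agg2$mean, 0.8)
  expect_equal(agg2$std, sd(c(0.7, 0.9)))      # sample (n-1) definition
  expect_equal(agg2$std, 0.1414214, tolerance = 1e-6)

  expect_identical(aggregate_runs(rev(runs2))$std, agg2$std)

  one <- aggregate_runs(list(c(dice = 0.5)))
  expect_true(attr(one, "single_run"))
  expect_equal(one$std, 0)

  expect_error(aggregate_runs(list(c(a = 1), c(b = 1))), "inconsistent")
  expect_error(aggregate_runs(list()), "at least one run")
})

test_that("evaluate_segmentation excludes background and undefined values from means", {
  set.seed(42)
  p <- rand_mask(8, 8, 3)
  df <- evaluate_segmentation(p, p, classes = 1:2)
  expect_equal(df$dice, c(1, 1, 1))
  # a class absent from prediction and truth: dice 1 (empty), NA precision
  q <- matrix(0L, 4, 4)
  df2 <- evaluate_segmentation(q, q, classes = 1:2)
  expect_true(all(is.na(df2$precision[1:2])))
  expect_equal(df2$dice[3], 1)
})

test_that("mean foreground Dice is invariant to class relabelling", {
  set.seed(43)
  p <- rand_mask(8, 8, 4)
  t_ <- rand_mask(8, 8, 4)
  d1 <- mean(sapply(1:3, function(c) as.numeric(dice_coefficient(p, t_, c))))
  # swap labels 1 and 3 in both masks
  swap <- function(m) { m2 <- m; m2[m == 1] <- 3L; m2[m == 3] <- 1L; m2 }
  d2 <- mean(sapply(1:3, function(c)
    as.numeric(dice_coefficient(swap(p), swap(t_), c))))
  expect_equal(d1, d2, tolerance = 1e-12)
})
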