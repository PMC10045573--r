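test_that("confusion counts enumerate agreement cells", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc)[c("tp", "fn", "fp", "tn")],
               list(tp = 1, fn = 1, fp = 1, tn = 1))
  same <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(same$fp + same$fn, 0)
  compl <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(compl$tp + compl$tn, 0)
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "size")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0/1")
})

test_that("the metric panel reproduces hand arithmetic", {
  r <- compute_metrics(list(tp = 50, fp = 10, fn = 20, tn = 20))
  expect_equal(r$dsc, 100 / 130)
  expect_equal(r$jsc, 50 / 80)
  expect_equal(r$jsc, r$dsc / (2 - r$dsc))
  expect_equal(r$svd, 1 - r$dsc)
  expect_equal(r$accuracy, 70 / 100)
  expect_equal(r$sensitivity, 50 / 70)
  expect_equal(r$specificity, 20 / 30)
  expect_equal(r$precision, 50 / 60)
  expect_equal(r$f1, 2 * r$precision * r$sensitivity /
                 (r$precision + r$sensitivity))
  expect_length(metric_flags(r), 0L)

  perfect <- compute_metrics(list(tp = 30, fp = 0, fn = 0, tn = 70))
  expect_equal(perfect$dsc, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$fpr + perfect$fnr + perfect$fdr + perfect$svd, 0)
})

test_that("symmetric volume difference matches the published Dice scores", {
  expect_equal(round(svd_from_dsc(0.7711), 2), 0.23)
  expect_equal(round(svd_from_dsc(0.7754), 2), 0.22)
})

test_that("JSC-DSC identity and scale invariance hold on random counts", {
  set.seed(71)
  for (k in 1:50) {
    c0 <- list(tp = sample(0:40, 1), fp = sample(0:40, 1),
               fn = sample(0:40, 1), tn = sample(1:40, 1))
    if (c0$tp + c0$fp + c0$fn == 0) c0$tp <- 1
    r <- compute_metrics(c0)
    expect_equal(r$jsc, r$dsc / (2 - r$dsc), tolerance = 1e-12)
    expect_equal(r$svd, 1 - r$dsc)
    r4 <- compute_metrics(lapply(c0, `*`, 4))
    expect_equal(unlist(r), unlist(r4), tolerance = 1e-12)
  }
})

test_that("label swap exchanges the paired metrics", {
  set.seed(72)
  for (k in 1:20) {
    c0 <- list(tp = sample(1:30, 1), fp = sample(1:30, 1),
               fn = sample(1:30, 1), tn = sample(1:30, 1))
    a <- compute_metrics(c0)
    b <- compute_metrics(list(tp = c0$tn, fp = c0$fn,
                              fn = c0$fp, tn = c0$tp))
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$specificity, b$sensitivity)
    expect_equal(a$precision, b$npv)
    expect_equal(a$npv, b$precision)
    expect_equal(a$fpr, b$fnr)
    expect_equal(a$fnr, b$fpr)
    expect_equal(a$accuracy, b$accuracy)
    expect_equal(abs(a$mcc), abs(b$mcc), tolerance = 1e-12)
  }
})

test_that("degenerate denominators take the ideal value and are flagged", {
  no_pos <- compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_equal(no_pos$sensitivity, 1)
  expect_equal(no_pos$dsc, 1)   # empty-vs-empty convention
  expect_equal(no_pos$fnr, 0)
  expect_equal(no_pos$mcc, 0)
  expect_setequal(
    metric_flags(no_pos),
    c("dsc", "jsc", "sensitivity", "precision", "fnr", "fdr", "mcc")
  )
  expect_error(compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "zero")
})

test_that("mask evaluation wraps counts and metrics", {
  truth <- binary_mask(matrix(c(1, 1, 0, 0), 2))
  pred <- binary_mask(matrix(c(1, 0, 1, 0), 2))
  r <- evaluate_masks(truth, pred)
  expect_equal(r$dsc, 2 * 1 / (2 * 1 + 1 + 1))
  expect_equal(dice(truth, truth), 1)
})
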