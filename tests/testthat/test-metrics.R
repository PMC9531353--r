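test_that("confusion counts partition the samples", {
  expect_equal(confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1)),
               c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_equal(confusionCounts(c(1, 0), c(1, 0)),
               c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  expect_equal(sum(confusionCounts(integer(0), integer(0))), 0L)
  expect_error(confusionCounts(c(1, 0), 1), "equal length")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
  set.seed(61)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.4); p <- rbinom(30, 1, 0.6)
    expect_equal(sum(confusionCounts(y, p)), 30L)
  }
})

test_that("threshold metrics follow their confusion-count formulas", {
  perfect <- thresholdMetrics(c(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_true(all(perfect == 1))
  m <- thresholdMetrics(c(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(unname(m["mcc"]), 0)
  expect_equal(unname(m["ba"]), 0.5)
  # random counts against direct formula evaluation
  set.seed(62)
  for (i in 1:20) {
    ct <- c(tp = sample(0:50, 1), fp = sample(0:50, 1),
            tn = sample(0:50, 1), fn = sample(0:50, 1))
    m <- thresholdMetrics(ct)
    sn <- if (ct["tp"] + ct["fn"] == 0) 0 else ct[["tp"]] / (ct[["tp"]] + ct[["fn"]])
    sp <- if (ct["tn"] + ct["fp"] == 0) 0 else ct[["tn"]] / (ct[["tn"]] + ct[["fp"]])
    expect_equal(unname(m["ba"]), (sn + sp) / 2)
    if (m["pr"] + m["sn"] > 0)
      expect_equal(unname(m["f1"]),
                   2 * m[["pr"]] * m[["sn"]] / (m[["pr"]] + m[["sn"]]))
    expect_gte(m[["mcc"]], -1); expect_lte(m[["mcc"]], 1)
  }
})

test_that("MCC is invariant under swapping the classes' roles", {
  set.seed(63)
  for (i in 1:20) {
    ct <- c(tp = sample(1:50, 1), fp = sample(1:50, 1),
            tn = sample(1:50, 1), fn = sample(1:50, 1))
    swapped <- c(tp = ct[["tn"]], fp = ct[["fn"]],
                 tn = ct[["tp"]], fn = ct[["fp"]])
    expect_equal(thresholdMetrics(ct)[["mcc"]],
                 thresholdMetrics(swapped)[["mcc"]])
  }
})

test_that("benchmark-style published metric rows are reproduced from SN/SP/PR", {
  # worked examples: BA from printed SN/SP and F1 from printed PR/SN of
  # published promoter-classifier test results, to 2 decimals
  rows <- list(
    list(sn = 0.90, sp = 0.99, pr = 0.99, ba = 0.94, f1 = 0.94),
    list(sn = 0.62, sp = 0.89, pr = 0.85, ba = 0.75, f1 = 0.72),
    list(sn = 0.88, sp = 0.98, pr = 0.97, ba = 0.93, f1 = 0.92),
    list(sn = 0.74, sp = 0.91, pr = 0.90, ba = 0.83, f1 = 0.81),
    list(sn = 0.84, sp = 0.78, pr = 0.79, ba = 0.81, f1 = 0.81),
    list(sn = 0.94, sp = 0.39, pr = 0.61, ba = 0.67, f1 = 0.74))
  for (r in rows) {
    expect_lte(abs((r$sn + r$sp) / 2 - r$ba), 0.005 + 1e-9)
    expect_lte(abs(2 * r$pr * r$sn / (r$pr + r$sn) - r$f1), 0.005 + 1e-9)
    # the same numbers through the package's formulas, via counts on a
    # balanced 1000+1000 test set reconstructed from SN/SP
    tp <- round(1000 * r$sn); fn <- 1000 - tp
    tn <- round(1000 * r$sp); fp <- 1000 - tn
    m <- thresholdMetrics(c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_lte(abs(m[["ba"]] - r$ba), 0.005 + 1e-9)
    expect_equal(round(m[["sn"]], 2), r$sn)
    expect_equal(round(m[["sp"]], 2), r$sp)
  }
})

test_that("ROC area equals the pairwise concordance oracle", {
  # perfect and random ranking
  expect_equal(rocCurveArea(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  set.seed(64)
  yBig <- rbinom(4000, 1, 0.5); sBig <- runif(4000)
  expect_lt(abs(rocCurveArea(yBig, sBig)$auc - 0.5), 0.05)
  # tie handling on a 6-sample toy
  yToy <- c(1, 1, 1, 0, 0, 0); sToy <- c(0.9, 0.5, 0.3, 0.5, 0.2, 0.1)
  expect_equal(rocCurveArea(yToy, sToy)$auc, concordanceAuc(yToy, sToy))
  # 200 random small instances with heavy ties
  for (i in 1:200) {
    n <- sample(4:25, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(rocCurveArea(y, s)$auc, concordanceAuc(y, s),
                 tolerance = 1e-12)
  }
  expect_error(rocCurveArea(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("PR area follows the step summation rule", {
  expect_equal(prCurveArea(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  # all scores equal -> prevalence
  expect_equal(prCurveArea(c(1, 0, 0, 0), rep(0.3, 4))$auc, 0.25)
  # 8-sample toy against the brute-force sweep
  y8 <- c(1, 0, 1, 1, 0, 0, 1, 0)
  s8 <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.4, 0.3, 0.1)
  expect_equal(prCurveArea(y8, s8)$auc, brutePrArea(y8, s8))
  set.seed(65)
  for (i in 1:50) {
    n <- sample(4:25, 1)
    y <- c(1, rbinom(n - 1, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(prCurveArea(y, s)$auc, brutePrArea(y, s),
                 tolerance = 1e-12)
  }
  expect_error(prCurveArea(c(0, 0), c(0.1, 0.2)), "without positives")
})

test_that("ROC/PR agree with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  for (i in 1:10) {
    y <- c(1, 0, rbinom(40, 1, 0.5))
    s <- round(runif(42), 2)
    ours <- rocCurveArea(y, s)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})
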