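test_that("AUC equals pairwise concordance with ties at one half", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.7), rep(c("case", "control"),
                                            c(2, 1)))$auc, 1)
  sc <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.1)
  lb <- rep(c("case", "control"), each = 3)
  expect_equal(rocAuc(sc, lb)$auc, 8 / 9)
  expect_equal(rocAuc(sc, lb)$auc, pairwiseAuc(sc, lb))
  # ties
  sct <- c(0.5, 0.5, 0.5, 0.2)
  lbt <- c("case", "case", "control", "control")
  expect_equal(rocAuc(sct, lbt)$auc, pairwiseAuc(sct, lbt))
  expect_error(rocAuc(1:3, rep("case", 3)), "both classes")
})

test_that("the ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(2)
  sc <- rnorm(40); lb <- sample(rep(c("case", "control"), 20))
  r <- rocAuc(sc, lb)
  expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(7)
  sc <- rnorm(30); lb <- sample(rep(c("case", "control"), 15))
  base <- rocAuc(sc, lb)$auc
  expect_equal(rocAuc(exp(sc), lb)$auc, base)
  expect_equal(rocAuc(plogis(3 * sc + 1), lb)$auc, base)
})

test_that("confidence interval methods agree and reproduce", {
  set.seed(11)
  sc <- c(rnorm(60, 1), rnorm(60))
  lb <- rep(c("case", "control"), each = 60)
  dl <- aucCi(sc, lb, "delong")
  bs <- aucCi(sc, lb, "bootstrap", seed = 5)
  bs2 <- aucCi(sc, lb, "bootstrap", seed = 5)
  expect_identical(bs, bs2)
  expect_lt(abs(dl$ci_low - bs$ci_low), 0.02)
  expect_lt(abs(dl$ci_high - bs$ci_high), 0.02)
  expect_true(dl$ci_low <= dl$auc && dl$auc <= dl$ci_high)
  # degenerate: perfect separation
  expect_warning(dg <- aucCi(c(2, 3, -1, -2),
                             c("case", "case", "control", "control"),
                             "delong"),
                 "degenerate")
  expect_equal(c(dg$ci_low, dg$ci_high), c(1, 1))
})

test_that("DeLong intervals cover a known AUC at roughly 95%", {
  covered <- 0; nSim <- 60
  for (i in 1:nSim) {
    set.seed(1000 + i)
    sc <- rnorm(200)
    lb <- rep(c("case", "control"), each = 100)
    ci <- aucCi(sc, lb, "delong")
    covered <- covered + (ci$ci_low <= 0.5 && 0.5 <= ci$ci_high)
  }
  expect_gte(covered / nSim, 0.85)
})

test_that("exact proportions render like published rates", {
  p <- proportionCI(12, 15)
  expect_equal(p$percent, 80.0)
  expect_equal(proportionCI(39, 93)$percent, 41.9)
  expect_equal(proportionCI(9, 96)$percent, 9.4)
  expect_equal(p$rate, 12 / 15)
  # exact Clopper-Pearson upper bound at 0 successes: 1 - 0.025^(1/n)
  z <- proportionCI(0, 10)
  expect_equal(z$rate, 0)
  expect_equal(z$ci_high, 1 - 0.025^(1 / 10), tolerance = 1e-9)
  expect_equal(z$ci_low, 0)
  w <- proportionCI(12, 15, method = "wilson")
  expect_true(w$ci_low > 0 && w$ci_high < 1)
  expect_error(proportionCI(3, 0), "total")
  expect_error(proportionCI(5, 3), "successes")
})

test_that("half-up rounding matches the reporting convention", {
  expect_equal(roundHalfUp(26.65), 26.7)  # round() would give 26.6
  expect_equal(roundHalfUp(89.18918, 1), 89.2)
  expect_equal(formatPercent(39, 93), "41.9% (39/93)")
  expect_equal(formatPercent(36, 36), "100.0% (36/36)")
})

test_that("stage-stratified sensitivity uses cases only", {
  n <- c(15, 37, 36, 1)
  pos <- c(12, 33, 36, 1)
  stages <- rep(c("I", "II", "III", "IV"), n)
  calls <- unlist(mapply(function(p, t) c(rep(TRUE, p),
                                          rep(FALSE, t - p)),
                         pos, n))
  labels <- rep("case", sum(n))
  # controls must not leak into the stage table
  calls <- c(calls, rep(TRUE, 5))
  labels <- c(labels, rep("control", 5))
  stages <- c(stages, rep("none", 5))
  tab <- stageSensitivity(calls, labels, stages)
  expect_equal(tab$stage, c("I", "II", "III", "IV"))
  expect_equal(tab$percent, c(80.0, 89.2, 100.0, 100.0))
  expect_equal(tab$positives, pos)
  # all-positive cohort
  tabAll <- stageSensitivity(rep(TRUE, 4), rep("case", 4),
                             c("I", "II", "III", "IV"))
  expect_true(all(tabAll$percent == 100))
  # empty stage omitted
  tab2 <- stageSensitivity(c(TRUE, FALSE), c("case", "case"),
                           c("I", "I"))
  expect_equal(tab2$stage, "I")
})

test_that("single-marker thresholding mirrors model evaluation", {
  vals <- c(10, 2, 8, 1, 0.5, 3)
  lb <- rep(c("case", "control"), each = 3)
  lo <- singleMarkerEval(vals, lb, threshold = 0)
  expect_equal(lo$performance$sensitivity$rate, 1)
  expect_equal(lo$performance$specificity$rate, 0)
  hi <- singleMarkerEval(vals, lb, threshold = 100)
  expect_equal(hi$performance$sensitivity$rate, 0)
  expect_equal(hi$performance$specificity$rate, 1)
  st <- singleMarkerEval(c(rep(1, 4), rep(0, 11), rep(0, 5)),
                         rep(c("case", "control"), c(15, 5)),
                         threshold = 0.5,
                         stages = rep(c("I", "none"), c(15, 5)))
  expect_equal(st$performance$by_stage$percent, 26.7)
})

test_that("binary performance reports exact fractions with intervals", {
  calls <- c(rep(TRUE, 82), rep(FALSE, 7), rep(FALSE, 90), rep(TRUE, 5))
  lb <- rep(c("case", "control"), c(89, 95))
  perf <- binaryPerformance(calls, lb)
  expect_equal(perf$sensitivity$rate, 82 / 89)
  expect_equal(perf$specificity$rate, 90 / 95)
  expect_true(perf$sensitivity$ci_low < perf$sensitivity$rate)
  expect_true(perf$specificity$ci_high > perf$specificity$rate)
})
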