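logisticFixture <- function(n = 60, p = 3, beta = c(-0.3, 1, -0.7, 0.4),
                            seed = 8) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("x", 1:p)))
  eta <- beta[1] + X %*% beta[-1]
  y <- rbinom(n, 1, plogis(eta))
  list(X = X, y = y)
}

test_that("unpenalized IRLS reproduces glm on a well-posed fit", {
  fx <- logisticFixture()
  ours <- ridgeLogistic(fx$X, fx$y, lambda = 0)
  ref <- glm(fx$y ~ fx$X, family = binomial())
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_true(ours$converged)
})

test_that("the ridge penalty keeps separable fits finite", {
  x <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1,
              dimnames = list(sprintf("s%02d", 1:20), "x1"))
  y <- c(rep(0, 10), rep(1, 10))
  fit <- ridgeLogistic(x, y, lambda = 1e-4 * 20)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("stratified folds balance classes to within one sample", {
  lab <- setNames(rep(c("case", "control"), c(93, 96)),
                  sprintf("s%03d", 1:189))
  part <- makeCVPartition(lab, k = 10, seed = 3)
  for (j in 1:10) {
    ids <- names(part@assignments)[part@assignments == j]
    nc <- sum(lab[ids] == "case"); nh <- sum(lab[ids] == "control")
    expect_true(nc %in% c(9, 10))
    expect_true(nh %in% c(9, 10))
  }
  part2 <- makeCVPartition(lab, k = 10, seed = 3)
  expect_identical(part@assignments, part2@assignments)
  expect_error(makeCVPartition(lab, k = 1), "degenerate")
  expect_error(makeCVPartition(lab[1:15], k = 10), "at least k")
})

test_that("a label-aligned feature drives training AUC to 1", {
  set.seed(12)
  lab <- rep(c("case", "control"), each = 15)
  m <- matrix(as.numeric(lab == "case") + rnorm(30, sd = 0.01), 30, 1,
              dimnames = list(sprintf("s%02d", 1:30), "f1"))
  sm <- fitSubModel(m, lab, "f1", "methylation")
  p <- predict(sm, m)
  expect_equal(rocAuc(p, lab)$auc, 1)
})

test_that("zero-variance features are dropped at fit time", {
  set.seed(13)
  lab <- rep(c("case", "control"), each = 10)
  m <- cbind(f1 = rnorm(20) + (lab == "case"), f2 = rep(1, 20))
  rownames(m) <- sprintf("s%02d", 1:20)
  expect_warning(sm <- fitSubModel(m, lab, c("f1", "f2"), "cnv"), "f2")
  expect_equal(sm@features, "f1")
  expect_length(sm@coefficients, 2)
})

test_that("out-of-fold probabilities cover every sample and stay in (0,1)", {
  fx <- logisticFixture(n = 60)
  lab <- setNames(ifelse(fx$y == 1, "case", "control"), rownames(fx$X))
  part <- makeCVPartition(lab, k = 5, seed = 2)
  oof <- crossValProbs(fx$X, lab, part, colnames(fx$X))
  expect_false(anyNA(oof))
  expect_true(all(oof > 0 & oof < 1))
  oof2 <- crossValProbs(fx$X, lab, part, colnames(fx$X))
  expect_identical(oof, oof2)  # fixed assignments => identical probs
})

test_that("the Youden cutoff matches the exhaustive oracle", {
  probs <- c(0.1, 0.2, 0.4, 0.3, 0.7, 0.8)
  lab <- c("control", "control", "control", "case", "case", "case")
  expect_equal(chooseCutoff(probs, lab), oracleYouden(probs, lab))
  set.seed(3)
  for (i in 1:25) {
    p <- round(runif(14), 2)
    l <- sample(rep(c("case", "control"), 7))
    expect_equal(chooseCutoff(p, l), oracleYouden(p, l))
  }
})

test_that("cutoff edge cases behave as documented", {
  # perfect separation: smallest observed case score, sens = spec = 1
  probs <- c(0.05, 0.1, 0.9, 0.95)
  lab <- c("control", "control", "case", "case")
  expect_equal(chooseCutoff(probs, lab), 0.9)
  expect_warning(c0 <- chooseCutoff(rep(0.5, 4), lab), "degenerate")
  expect_equal(c0, 0.5)
  # specificity-floor method
  expect_equal(chooseCutoff(probs, lab, method = "specificity_floor",
                            specTarget = 1), 0.9)
})

test_that("the integrated combiner validates and tolerates collinearity", {
  n <- 40
  set.seed(5)
  lab <- rep(c("case", "control"), each = n / 2)
  ids <- sprintf("s%02d", 1:n)
  p1 <- setNames(plogis(rnorm(n) + (lab == "case")), ids)
  ms <- setNames(rbinom(n, 1, 0.3), ids)
  expect_error(fitIntegrated(p1, p1, p1, setNames(rep(0.5, n), ids), lab),
               "0/1")
  fit <- fitIntegrated(p1, p1, p1, ms, lab)   # duplicated slots
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("null inputs give chance-level integrated AUC", {
  set.seed(6)
  n <- 200
  lab <- rep(c("case", "control"), each = n / 2)
  ids <- sprintf("s%03d", 1:n)
  mk <- function() setNames(runif(n), ids)
  fit <- fitIntegrated(mk(), mk(), mk(), setNames(rbinom(n, 1, 0.1), ids),
                       lab)
  p <- plogis(fit$coefficients[1] +
                as.matrix(data.frame(mk(), mk(), mk(),
                                     rbinom(n, 1, 0.1))) %*%
                fit$coefficients[-1])
  expect_gt(rocAuc(as.vector(p), lab)$auc, 0.35)
  expect_lt(rocAuc(as.vector(p), lab)$auc, 0.65)
})

test_that("resubstitution stacking inflates null training AUC; OOF does not", {
  set.seed(31)
  n <- 80; p <- 60
  lab <- setNames(rep(c("case", "control"), each = n / 2),
                  sprintf("s%02d", 1:n))
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(names(lab), sprintf("f%02d", 1:p)))
  feats <- colnames(m)
  part <- makeCVPartition(lab, k = 5, seed = 1)
  oof <- crossValProbs(m, lab, part, feats)
  resub <- predict(fitSubModel(m, lab, feats, "cnv"), m)
  ms <- setNames(rep(0L, n), names(lab))
  ms[1] <- 1L
  aucResub <- rocAuc(resub, lab)$auc
  aucOof <- rocAuc(oof, lab)$auc
  expect_gt(aucResub, 0.9)        # leakage signature on pure noise
  expect_lt(aucOof, 0.7)
  expect_gt(aucResub - aucOof, 0.2)
})

test_that("nested fold-level selection yields valid out-of-fold scores", {
  cfg <- smallConfig(nCases = 15, nControls = 15, seed = 19)
  co <- simulateCohort(cfg)
  fx <- extractFeatures(co, minFragments = 1, minBinsPerArm = 1)
  fit <- suppressWarnings(trainStackedModel(
    fx$features, fx$mutScore,
    selConfig = selectionConfig(nSelect = c(methylation = 4,
                                            endmotif = 4, cnv = 4),
                                rfTrees = 100),
    k = 3, seed = 19, pon = fx$pon, nestedSelection = TRUE))
  expect_false(anyNA(fit$oof$p_integrated))
  expect_true(all(fit$oof$p_methylation > 0 & fit$oof$p_methylation < 1))
  # frozen validation-time selection still comes from the full cohort
  expect_lte(length(selectedFeatures(fit$model)$methylation), 4)
})

test_that("model bundles round-trip through JSON byte-compatibly", {
  cfg <- smallConfig(seed = 4)
  co <- simulateCohort(cfg)
  fx <- extractFeatures(co, minFragments = 1, minBinsPerArm = 1)
  fit <- trainStackedModel(fx$features, fx$mutScore,
                           selConfig = selectionConfig(
                             nSelect = c(methylation = 5, endmotif = 5,
                                         cnv = 5), rfTrees = 100),
                           k = 3, seed = 4, pon = fx$pon)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeModel(fit$model, f1)
  back <- readModel(f1)
  writeModel(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  pred1 <- predict(fit$model, fx$features, fx$mutScore)
  pred2 <- predict(back, fx$features, fx$mutScore)
  expect_equal(pred1, pred2, tolerance = 1e-12)
})

test_that("prediction applies frozen preprocessing and cutoffs", {
  cfg <- smallConfig(seed = 6)
  res <- runStudy(cfg, valConfig = {
    v <- smallConfig(nCases = 10, nControls = 10, seed = 99); v
  }, selConfig = selectionConfig(nSelect = c(methylation = 5,
                                             endmotif = 5, cnv = 5),
                                 rfTrees = 100),
  k = 3, minFragments = 1, minBinsPerArm = 1)
  pred <- res$predictions
  expect_true(all(pred$p_integrated > 0 & pred$p_integrated < 1))
  expect_equal(pred$call,
               pred$p_integrated >= cutoffs(res$model)[["integrated"]])
  # a duplicated sample gets identical outputs
  fx <- res$valFeatures
  dupVals <- lapply(fx$features, function(se) se[, c(1, 1)])
  dup <- predict(res$model,
                 lapply(dupVals, function(se) {
                   colnames(se) <- c("d1", "d2"); se
                 }),
                 setNames(rep(fx$mutScore[1], 2), c("d1", "d2")))
  expect_equal(dup$p_integrated[1], dup$p_integrated[2])
})
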