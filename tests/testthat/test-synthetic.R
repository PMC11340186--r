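test_that("configuration invariants are enforced by name", {
  expect_error(simulationConfig(nCases = 0), "nCases")
  expect_error(simulationConfig(stageProportions = c(I = 1, II = 1,
                                                     III = 1)),
               "stageProportions")
  expect_error(simulationConfig(motifEffectSize = -1), "motifEffectSize")
  expect_error(simulationConfig(controlMutationFpRate = 1.5),
               "controlMutationFpRate")
  expect_error(simulationConfig(nMethMarkers = 5, nInformativeMeth = 9),
               "nInformativeMeth")
  cfg <- simulationConfig()
  expect_equal(sum(cfg@stageProportions), 1, tolerance = 1e-12)
})

test_that("cohorts are byte-identical given config and seed", {
  cfg <- smallConfig(seed = 10)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  for (el in c("samples", "methylation", "fragments", "bins",
               "mutations"))
    expect_identical(c1[[el]], c2[[el]])
  expect_equal(nrow(c1$samples), 24)
  expect_true(all(c1$samples$tumor_fraction[c1$samples$label == "case"]
                  > 0))
  expect_true(all(c1$samples$tumor_fraction[
    c1$samples$label == "control"] == 0))
  expect_true(all(c1$samples$stage[c1$samples$label == "control"]
                  == "none"))
})

test_that("adding samples never perturbs existing samples' draws", {
  small <- simulateCohort(smallConfig(nCases = 6, nControls = 6,
                                      seed = 10))
  big <- simulateCohort(smallConfig(nCases = 9, nControls = 9, seed = 10))
  shared <- small$samples$sample_id
  keep <- function(d) {
    d <- d[d$sample_id %in% shared, ]
    rownames(d) <- NULL
    d
  }
  expect_identical(keep(big$methylation), keep(small$methylation))
  expect_identical(keep(big$fragments), keep(small$fragments))
  idx <- match(shared, big$samples$sample_id)
  expect_identical(big$samples$tumor_fraction[idx],
                   small$samples$tumor_fraction)
})

test_that("methylation counts follow the closed-form mean", {
  markers <- data.frame(marker_id = c("m1", "m2"),
                        baseline = c(0.01, 0), effect = c(0, 0.5))
  truth <- data.frame(sample_id = "x", label = "case",
                      tumor_fraction = 0)
  set.seed(1)
  cnt <- simulateMethylationCounts(truth, markers, depth = 1e5)
  beta <- cnt$methylated / (cnt$methylated + cnt$unmethylated)
  expect_lt(abs(beta[1] - 0.01), 0.005)
  expect_equal(beta[2], 0)
  truth$tumor_fraction <- 1
  set.seed(1)
  cnt <- simulateMethylationCounts(truth, markers, depth = 1e5)
  beta <- cnt$methylated / (cnt$methylated + cnt$unmethylated)
  expect_lt(abs(beta[2] - 0.5), 0.01)
  # beta = baseline + tf * effect
  markers2 <- data.frame(marker_id = "m", baseline = 0.02, effect = 0.3)
  truth$tumor_fraction <- 0.2
  set.seed(2)
  cnt <- simulateMethylationCounts(truth, markers2, depth = 1e5)
  expect_lt(abs(cnt$methylated / (cnt$methylated + cnt$unmethylated)
                - 0.08), 0.005)
  expect_error(simulateMethylationCounts(
    truth, data.frame(marker_id = "m", baseline = 2, effect = 0), 10),
    "baseline")
})

test_that("fragment motifs are drawn from the tf mixture", {
  motifs <- allMotifs(4)
  cp <- setNames(rep(1 / 256, 256), motifs)
  tp <- cp
  delta <- 1 / 512
  tp["CCCA"] <- cp["CCCA"] + delta
  tp["AAAA"] <- cp["AAAA"] - delta
  bins <- data.frame(chrom = "chr1", start = 0, end = 1e6, arm_id = "1p")
  mk <- function(tf, n = 60000, seed = 3) {
    set.seed(seed)
    truth <- data.frame(sample_id = "x", tumor_fraction = tf)
    motifFrequencies(simulateFragmentMotifs(truth, cp, tp, n, bins))
  }
  expect_equal(unname(mk(0)["CCCA"]), 1 / 256, tolerance = 0.1)
  expect_equal(unname(mk(1)["CCCA"]), unname(tp["CCCA"]),
               tolerance = 0.06)
  # tf = 0.5: expected frequency is the profile midpoint
  expect_equal(unname(mk(0.5, n = 2e5)["CCCA"]),
               unname((cp["CCCA"] + tp["CCCA"]) / 2), tolerance = 0.05)
  bad <- cp; bad[1] <- bad[1] + 0.01
  truth <- data.frame(sample_id = "x", tumor_fraction = 0)
  expect_error(simulateFragmentMotifs(truth, bad, tp, 10, bins),
               "summing to 1")
})

test_that("bin counts are flat without tumor content and validated", {
  cfg <- smallConfig(seed = 2)
  panel <- syntheticPanel(cfg)
  truth <- data.frame(sample_id = "x", label = "case",
                      tumor_fraction = 0)
  set.seed(4)
  b <- simulateBinCounts(truth, panel$armStates, panel$bins,
                         binDepth = 2000, nbSize = 1e5)
  corr <- gcCorrect(b)
  # no copy-number signal: corrected depth flat across arms
  armMeans <- tapply(corr$corrected, panel$bins$arm_id, mean)
  expect_lt(max(abs(log2(armMeans))), 0.05)
  expect_error(simulateBinCounts(truth,
                                 data.frame(arm_id = "99z", copies = 3),
                                 panel$bins, 100, 50),
               "99z")
})

test_that("mutation generation respects the response and fp knobs", {
  cfg <- smallConfig(seed = 5, controlMutationFpRate = 0)
  co <- simulateCohort(cfg)
  ctrl <- co$samples$sample_id[co$samples$label == "control"]
  scores <- mutationScores(co$mutations, ctrl)
  expect_true(all(scores == 0))   # fp rate 0: no control is positive
  # a near-zero response scale makes every case mutation-positive
  cfg2 <- smallConfig(seed = 5, mutationResponseScale = 1e-9,
                      controlMutationFpRate = 0)
  co2 <- simulateCohort(cfg2)
  cases <- co2$samples$sample_id[co2$samples$label == "case"]
  expect_true(all(mutationScores(co2$mutations, cases) == 1))
  # decoys exist and fail the filter
  dec <- filterEligible(co2$mutations)
  expect_true(any(!dec$eligible))
})

test_that("a null cohort is statistically indistinguishable between arms", {
  # tumor fraction ~ 0: two-sample KS p > 0.01 for >= 95% of features
  nOk <- 0; nTot <- 0
  for (s in 1:20) {
    cfg <- smallConfig(nCases = 15, nControls = 15, seed = 300 + s,
                       tfMedianByStage = c(I = 1e-9, II = 1e-9,
                                           III = 1e-9, IV = 1e-9))
    co <- simulateCohort(cfg)
    fx <- extractFeatures(co, minFragments = 1, minBinsPerArm = 1)
    lab <- canonicalLabels(co$samples$label)
    for (om in names(fx$features)) {
      m <- featureValues(fx$features[[om]])
      for (f in colnames(m)) {
        x <- m[lab == "case", f]; y <- m[lab == "control", f]
        if (length(unique(c(x, y))) < 3) next
        p <- suppressWarnings(stats::ks.test(x, y)$p.value)
        nTot <- nTot + 1
        nOk <- nOk + (p > 0.01)
      }
    }
  }
  expect_gte(nOk / nTot, 0.95)
})

test_that("cohort bundles round-trip through TSV", {
  co <- simulateCohort(smallConfig(nCases = 3, nControls = 3, seed = 12))
  d <- file.path(tempdir(), "cohort-rt")
  writeCohort(co, d)
  back <- readCohort(d)
  expect_equal(back$samples$sample_id, co$samples$sample_id)
  expect_equal(back$methylation$methylated, co$methylation$methylated)
  expect_equal(nrow(back$fragments), nrow(co$fragments))
  unlink(d, recursive = TRUE)
})

test_that("stronger tumor fractions never weaken any omics signal", {
  grid <- c(0.002, 0.008, 0.02, 0.05, 0.12)
  seeds <- 1:6
  aucs <- array(NA_real_, c(length(grid), 3, length(seeds)),
                dimnames = list(NULL, c("methylation", "endmotif", "cnv"),
                                NULL))
  for (gi in seq_along(grid)) {
    for (si in seq_along(seeds)) {
      cfg <- smallConfig(nCases = 16, nControls = 16, seed = 400 + si,
                         tfMedianByStage = c(I = grid[gi], II = grid[gi],
                                             III = grid[gi],
                                             IV = grid[gi]))
      co <- simulateCohort(cfg)
      fx <- extractFeatures(co, minFragments = 1, minBinsPerArm = 1)
      lab <- co$samples$label
      for (om in dimnames(aucs)[[2]]) {
        flt <- univariateFilter(fx$features[[om]], alpha = 0.2)
        feats <- head(flt$feature_id, 8)
        m <- featureValues(fx$features[[om]])
        sm <- suppressWarnings(fitSubModel(m, lab, feats, om))
        aucs[gi, om, si] <- rocAuc(predict(sm, m), lab)$auc
      }
    }
  }
  for (om in dimnames(aucs)[[2]]) {
    meanAuc <- apply(aucs[, om, ], 1, mean)
    rho <- cor(seq_along(grid), meanAuc, method = "spearman")
    expect_gte(rho, 0)
  }
})
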