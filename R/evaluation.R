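#' ROC curve and AUC of a score vector
#'
#' The AUC is computed as the Mann-Whitney U statistic divided by
#' `n_cases * n_controls`, counting ties as 1/2 — i.e. the probability
#' that a random case scores above a random control. The ROC curve is
#' traced by thresholding at every distinct score; it starts at (0, 0),
#' ends at (1, 1) and is monotone in both coordinates.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Case/control labels aligned to `scores`.
#' @return List of class `cfdnaROC`: auc, n_cases, n_controls, curve
#'   (data.frame fpr/tpr).
#' @export
rocAuc <- function(scores, labels) {
  lab <- canonicalLabels(labels)
  nCase <- sum(lab == "case"); nCtrl <- sum(lab == "control")
  assertThat(nCase > 0 && nCtrl > 0, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  u <- sum(r[lab == "case"]) - nCase * (nCase + 1) / 2
  auc <- u / (nCase * nCtrl)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    fpr = vapply(thr, function(t) mean(scores[lab == "control"] >= t), 1),
    tpr = vapply(thr, function(t) mean(scores[lab == "case"] >= t), 1))
  structure(list(auc = auc, n_cases = nCase, n_controls = nCtrl,
                 curve = curve), class = "cfdnaROC")
}

#' Confidence interval for an AUC
#'
#' DeLong's analytic nonparametric variance (default) or a stratified
#' percentile bootstrap (2000 resamples, seed-deterministic). A
#' degenerate DeLong variance (AUC 1 with no ties) returns
#' `[auc, 1]` with a warning. Intervals are clipped to \[0, 1\].
#'
#' @param scores,labels As in [rocAuc()].
#' @param method "delong" or "bootstrap".
#' @param level Confidence level (default 0.95).
#' @param nBoot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return List: auc, ci_low, ci_high, method, level.
#' @export
aucCi <- function(scores, labels, method = c("delong", "bootstrap"),
                  level = 0.95, nBoot = 2000, seed = 1) {
  method <- match.arg(method)
  lab <- canonicalLabels(labels)
  auc <- rocAuc(scores, labels)$auc
  if (method == "delong") {
    ro <- suppressMessages(pROC::roc(response = lab, predictor = scores,
                                     levels = c("control", "case"),
                                     direction = "<", quiet = TRUE))
    v <- pROC::var(ro, method = "delong")
    if (!is.finite(v) || v <= 0) {
      warning("degenerate DeLong variance; returning [auc, 1]")
      return(list(auc = auc, ci_low = auc, ci_high = 1,
                  method = method, level = level))
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- auc - z * sqrt(v); hi <- auc + z * sqrt(v)
  } else {
    caseS <- scores[lab == "case"]; ctrlS <- scores[lab == "control"]
    boots <- withChildSeed(seed, "aucboot", {
      vapply(seq_len(nBoot), function(i) {
        s <- c(sample(caseS, replace = TRUE),
               sample(ctrlS, replace = TRUE))
        l <- c(rep("case", length(caseS)), rep("control", length(ctrlS)))
        rocAuc(s, l)$auc
      }, 1)
    })
    qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(auc = auc, ci_low = max(0, lo), ci_high = min(1, hi),
       method = method, level = level)
}

#' Exact binomial proportion with Clopper-Pearson interval
#'
#' @param successes,total Counts, `0 <= successes <= total`, `total > 0`.
#' @param level Confidence level.
#' @param method "clopper-pearson" (exact, default) or "wilson".
#' @return List: rate (exact fraction), ci_low, ci_high, successes,
#'   total, percent (rate as a half-up one-decimal percentage).
#' @export
proportionCI <- function(successes, total, level = 0.95,
                         method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  assertThat(total > 0, "total must be > 0")
  assertThat(successes >= 0 && successes <= total,
             "need 0 <= successes <= total")
  if (method == "clopper-pearson") {
    ci <- binom.test(successes, total, conf.level = level)$conf.int
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- successes / total
    den <- 1 + z^2 / total
    ctr <- (p + z^2 / (2 * total)) / den
    hw <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / den
    ci <- c(ctr - hw, ctr + hw)
  }
  list(rate = successes / total, ci_low = max(0, ci[1]),
       ci_high = min(1, ci[2]), successes = successes, total = total,
       percent = roundHalfUp(100 * successes / total, 1))
}

#' Stage-stratified sensitivity
#'
#' Per-stage detection rates over case samples only (controls contribute
#' to specificity, never to this table). Stages with no cases are
#' omitted.
#'
#' @param calls Logical (or 0/1) positivity per sample.
#' @param labels Case/control labels.
#' @param stages Stage per sample (controls: "none"/NA, ignored).
#' @param level Confidence level of the Clopper-Pearson intervals.
#' @return data.frame stage / positives / total / rate / percent /
#'   ci_low / ci_high.
#' @export
stageSensitivity <- function(calls, labels, stages, level = 0.95) {
  lab <- canonicalLabels(labels)
  calls <- as.logical(calls)
  keep <- lab == "case"
  st <- as.character(stages)[keep]; cl <- calls[keep]
  lev <- intersect(c("I", "II", "III", "IV"), unique(st))
  lev <- c(lev, setdiff(sort(unique(st)), lev))
  rows <- lapply(lev, function(s) {
    idx <- st == s
    pr <- proportionCI(sum(cl[idx]), sum(idx), level)
    data.frame(stage = s, positives = pr$successes, total = pr$total,
               rate = pr$rate, percent = pr$percent,
               ci_low = pr$ci_low, ci_high = pr$ci_high)
  })
  do.call(rbind, rows)
}

#' Sensitivity/specificity of binary calls
#'
#' @param calls Logical positivity per sample.
#' @param labels Case/control labels.
#' @param stages Optional stages for the per-stage breakdown.
#' @param level Confidence level.
#' @return List: sensitivity and specificity ([proportionCI()] results)
#'   and, when stages are given, by_stage ([stageSensitivity()] table).
#' @export
binaryPerformance <- function(calls, labels, stages = NULL,
                              level = 0.95) {
  lab <- canonicalLabels(labels)
  calls <- as.logical(calls)
  out <- list(
    sensitivity = proportionCI(sum(calls[lab == "case"]),
                               sum(lab == "case"), level),
    specificity = proportionCI(sum(!calls[lab == "control"]),
                               sum(lab == "control"), level))
  if (!is.null(stages))
    out$by_stage <- stageSensitivity(calls, labels, stages, level)
  out
}

#' Threshold evaluation of a single continuous biomarker
#'
#' Evaluates `value >= threshold` calls exactly like a model's calls
#' (sensitivity/specificity with exact intervals, per-stage sensitivity)
#' plus the marker's ROC. Used for comparisons against conventional
#' single-protein markers such as CEA.
#'
#' @param values Marker values.
#' @param labels Case/control labels.
#' @param threshold Positivity threshold (`>=` is positive).
#' @param stages Optional stages.
#' @return List: performance ([binaryPerformance()]) and roc
#'   ([rocAuc()]).
#' @export
singleMarkerEval <- function(values, labels, threshold, stages = NULL) {
  list(performance = binaryPerformance(values >= threshold, labels,
                                       stages),
       roc = rocAuc(values, labels))
}

#' Full evaluation report of a prediction table
#'
#' AUCs with DeLong intervals for the integrated model and each sub-model
#' score, sensitivity/specificity at the stored cutoffs, and per-stage
#' sensitivity of the integrated call.
#'
#' @param pred Prediction table from `predict()` on a
#'   [StackedModel-class].
#' @param sampleInfo Sample sheet with label (and stage) for the
#'   predicted samples.
#' @param level Confidence level.
#' @return Nested list of metrics, JSON-serializable.
#' @export
evaluatePredictions <- function(pred, sampleInfo, level = 0.95) {
  si <- as.data.frame(sampleInfo)
  idx <- match(pred$sample_id, si$sample_id)
  assertThat(!anyNA(idx), "predictions contain unknown samples")
  lab <- si$label[idx]; stg <- si$stage[idx]
  scoreCols <- c(integrated = "p_integrated",
                 methylation = "p_methylation",
                 endmotif = "p_endmotif", cnv = "p_cnv",
                 mutation = "mutation_score")
  aucs <- lapply(scoreCols, function(cl)
    aucCi(pred[[cl]], lab, method = "delong", level = level))
  perf <- binaryPerformance(pred$call, lab, stages = stg, level = level)
  list(auc = aucs, integrated = perf,
       n_cases = sum(canonicalLabels(lab) == "case"),
       n_controls = sum(canonicalLabels(lab) == "control"))
}
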