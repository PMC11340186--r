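#' Ridge-penalized logistic regression via IRLS
#'
#' Maximum-likelihood logistic fit with an L2 penalty `lambda/2 * ||b||^2`
#' on the slopes (intercept unpenalized), solved by iteratively
#' reweighted least squares. The small default penalty guarantees a
#' finite optimum under complete separation while leaving well-posed fits
#' essentially unchanged.
#'
#' @param X Numeric design matrix (no intercept column).
#' @param y 0/1 response vector.
#' @param lambda Ridge strength (0 allowed).
#' @param maxit,tol IRLS iteration cap and coefficient-change tolerance.
#' @return List: coefficients (intercept first), converged, iterations.
#' @export
ridgeLogistic <- function(X, y, lambda = 0, maxit = 200, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  assertThat(all(y %in% c(0, 1)), "y must be 0/1")
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  converged <- FALSE
  it <- 0
  while (it < maxit) {
    it <- it + 1
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X1, X1 * w) + pen
    betaNew <- tryCatch(drop(solve(H, crossprod(X1, w * z))),
                        error = function(e)
                          stopf("IRLS normal equations singular at iteration %d: %s",
                                it, conditionMessage(e)))
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && lambda > 0)
    stopf("IRLS did not converge in %d iterations (last step %.3g)",
          maxit, delta)
  nms <- c("(Intercept)",
           colnames(X) %||% paste0("x", seq_len(p - 1)))
  list(coefficients = setNames(beta, nms), converged = converged,
       iterations = it)
}

#' Stratified cross-validation partition
#'
#' Samples of each class are shuffled (seed-deterministically) and dealt
#' round-robin into `k` folds, so per-fold class counts differ by at most
#' one from exact proportionality.
#'
#' @param labels Named case/control vector (names = sample ids) or a
#'   sample sheet data.frame.
#' @param k Fold count (default 10).
#' @param seed Partition seed.
#' @return A [CVPartition-class].
#' @export
makeCVPartition <- function(labels, k = 10, seed = 1) {
  if (is.data.frame(labels))
    labels <- setNames(labels$label, labels$sample_id)
  lab <- canonicalLabels(labels)
  assertThat(!is.null(names(labels)), "labels must be named by sample id")
  k <- as.integer(k)
  assertThat(k >= 2, "k must be >= 2 (k = %d is degenerate)", k)
  assertThat(min(table(lab)) >= k,
             "each class must have at least k = %d samples", k)
  assign <- integer(0)
  withChildSeed(seed, "cv", {
    for (cl in levels(lab)) {
      ids <- sample(names(labels)[lab == cl])
      assign <- c(assign, setNames(((seq_along(ids) - 1L) %% k) + 1L, ids))
    }
  })
  new("CVPartition", k = as.integer(k),
      assignments = assign[names(labels)], stratified = TRUE,
      seed = as.integer(seed))
}

standardizeFit <- function(m, features) {
  center <- colMeans(m[, features, drop = FALSE])
  scl <- apply(m[, features, drop = FALSE], 2, sd)
  keep <- scl > 0
  if (!all(keep))
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(features[!keep], collapse = ", ")))
  list(features = features[keep], center = center[keep],
       scale = scl[keep])
}

standardizeApply <- function(m, std) {
  missing <- setdiff(std$features, colnames(m))
  assertThat(length(missing) == 0, "matrix lacks required feature(s): %s",
             paste(missing, collapse = ", "))
  scale(m[, std$features, drop = FALSE], center = std$center,
        scale = std$scale)
}

#' Fit one per-omics logistic sub-model
#'
#' Selected features are z-standardized with training statistics
#' (zero-variance features dropped) and a ridge-logistic model is fit.
#' Default ridge strength is `1e-4 * n`.
#'
#' @param se Feature `SummarizedExperiment` (training samples) or a
#'   samples-by-features matrix.
#' @param labels Labels (defaults to the colData of `se`).
#' @param features Selected feature ids.
#' @param omicsTag Tag stored on the model.
#' @param lambda Ridge strength; `NULL` means `1e-4 * n`.
#' @return A [CfSubModel-class].
#' @export
fitSubModel <- function(se, labels = NULL, features, omicsTag = "omics",
                        lambda = NULL) {
  m <- if (is.matrix(se)) se else featureValues(se)
  lab <- canonicalLabels(labels %||%
                           SummarizedExperiment::colData(se)$label)
  assertThat(min(table(lab)) >= 2, "need >= 2 samples per class")
  assertThat(length(features) >= 1, "no features to fit")
  lambda <- lambda %||% (1e-4 * nrow(m))
  std <- standardizeFit(m, features)
  assertThat(length(std$features) >= 1,
             "all selected features have zero variance")
  Z <- standardizeApply(m, std)
  fit <- ridgeLogistic(Z, as.numeric(lab == "case"), lambda)
  new("CfSubModel", omicsTag = omicsTag, features = std$features,
      center = std$center, scale = std$scale,
      coefficients = unname(fit$coefficients), lambda = lambda,
      cutoff = NA_real_, converged = fit$converged)
}

# Intercept-only degenerate sub-model used when selection retains nothing:
# emits the constant training prevalence.
constantSubModel <- function(lab, omicsTag, lambda) {
  p <- mean(lab == "case")
  new("CfSubModel", omicsTag = omicsTag, features = character(0),
      center = numeric(0), scale = numeric(0),
      coefficients = stats::qlogis(min(max(p, 1e-6), 1 - 1e-6)),
      lambda = lambda, cutoff = NA_real_, converged = TRUE)
}

#' @describeIn fitSubModel Predicted case probabilities of a sub-model on
#'   new data (`newdata`: feature `SummarizedExperiment` or
#'   samples-by-features matrix).
#' @param object A fitted [CfSubModel-class].
#' @param newdata New samples.
#' @param ... Ignored.
#' @export
setMethod("predict", "CfSubModel", function(object, newdata, ...) {
  m <- if (is.matrix(newdata)) newdata else featureValues(newdata)
  if (length(object@features) == 0)
    return(setNames(rep(stats::plogis(object@coefficients[1]), nrow(m)),
                    rownames(m)))
  Z <- standardizeApply(m, list(features = object@features,
                                center = object@center,
                                scale = object@scale))
  eta <- object@coefficients[1] +
    drop(Z %*% object@coefficients[-1])
  setNames(stats::plogis(eta), rownames(m))
})

#' Out-of-fold sub-model probabilities
#'
#' For each fold, standardization and coefficients are re-fit on the
#' remaining folds and the held-out fold is predicted, so every training
#' sample receives exactly one out-of-fold probability. Marker selection
#' is performed once on the full training cohort upstream (see
#' [trainStackedModel()]); only preprocessing statistics and coefficients
#' are re-estimated per fold.
#'
#' @param se Feature container or samples-by-features matrix (training).
#' @param labels Labels aligned to the samples.
#' @param partition A [CVPartition-class] over these samples.
#' @param features Selected feature ids (may be empty; then the constant
#'   fold prevalence is emitted).
#' @param omicsTag Tag for diagnostics.
#' @param lambda Ridge strength (`NULL` = `1e-4 * n`).
#' @return Named numeric vector of out-of-fold probabilities in (0, 1).
#' @export
crossValProbs <- function(se, labels = NULL, partition, features,
                          omicsTag = "omics", lambda = NULL) {
  m <- if (is.matrix(se)) se else featureValues(se)
  lab <- canonicalLabels(labels %||%
                           SummarizedExperiment::colData(se)$label)
  names(lab) <- rownames(m)
  fold <- partition@assignments[rownames(m)]
  assertThat(!anyNA(fold), "partition does not cover all samples")
  out <- setNames(rep(NA_real_, nrow(m)), rownames(m))
  for (j in seq_len(partition@k)) {
    trIdx <- which(fold != j); teIdx <- which(fold == j)
    if (!length(teIdx)) next
    if (length(unique(lab[trIdx])) < 2)
      stopf("fold %d leaves a single-class training set; use fewer folds", j)
    sm <- if (length(features) == 0)
      constantSubModel(lab[trIdx], omicsTag,
                       lambda %||% (1e-4 * length(trIdx)))
    else fitSubModel(m[trIdx, , drop = FALSE], lab[trIdx], features,
                     omicsTag, lambda)
    out[teIdx] <- predict(sm, m[teIdx, , drop = FALSE])
  }
  out
}

# Out-of-fold probabilities with selection nested inside each fold.
nestedCrossValProbs <- function(se, labels, partition, om, selConfig,
                                lambda = NULL) {
  m <- featureValues(se)
  lab <- canonicalLabels(labels %||%
                           SummarizedExperiment::colData(se)$label)
  names(lab) <- rownames(m)
  fold <- partition@assignments[rownames(m)]
  out <- setNames(rep(NA_real_, nrow(m)), rownames(m))
  for (j in seq_len(partition@k)) {
    tr <- which(fold != j); te <- which(fold == j)
    if (!length(te)) next
    selJ <- selectOneOmics(se[, tr], om, selConfig,
                           labels = lab[tr])$selected
    sm <- if (length(selJ) == 0)
      constantSubModel(lab[tr], om, lambda %||% (1e-4 * length(tr)))
    else fitSubModel(m[tr, , drop = FALSE], lab[tr], selJ, om, lambda)
    out[te] <- predict(sm, m[te, , drop = FALSE])
  }
  out
}

#' Youden-optimal probability cutoff
#'
#' Default method maximizes sensitivity + specificity - 1 over the
#' observed probabilities (calls are `probability >= cutoff`); ties are
#' broken toward the smallest cutoff. The alternative
#' `"specificity_floor"` maximizes sensitivity subject to specificity at
#' least `specTarget`.
#'
#' @param probs Named probabilities.
#' @param labels Case/control labels aligned to `probs`.
#' @param method "youden" or "specificity_floor".
#' @param specTarget Specificity floor for the alternative method.
#' @return The cutoff (numeric scalar).
#' @export
chooseCutoff <- function(probs, labels, method = c("youden",
                                                   "specificity_floor"),
                         specTarget = 0.95) {
  method <- match.arg(method)
  lab <- canonicalLabels(labels)
  cand <- sort(unique(unname(probs)))
  if (length(cand) == 1) {
    warning("all probabilities identical; degenerate cutoff")
    return(cand)
  }
  sens <- vapply(cand, function(c) mean(probs[lab == "case"] >= c), 1)
  spec <- vapply(cand, function(c) mean(probs[lab == "control"] < c), 1)
  if (method == "youden") {
    j <- sens + spec - 1
    cand[which(j == max(j))[1]]
  } else {
    ok <- spec >= specTarget
    if (!any(ok)) {
      warning("no cutoff reaches the specificity floor; returning max")
      return(max(cand))
    }
    cand[ok][which.max(sens[ok])]
  }
}

#' Fit the integrated logistic combiner
#'
#' Logistic regression of the label on the three sub-model probability
#' scores plus the binary mutation score. The sub-model inputs must be
#' out-of-fold values when fitting on the training cohort, otherwise the
#' combiner sees optimistically biased inputs.
#'
#' @param pMeth,pMotif,pCnv Sub-model probabilities aligned by name.
#' @param mutScore Binary 0/1 mutation scores aligned by name.
#' @param labels Labels aligned by name.
#' @param lambda Ridge strength (`NULL` = `1e-4 * n`).
#' @return List: coefficients (length 5), converged.
#' @export
fitIntegrated <- function(pMeth, pMotif, pCnv, mutScore, labels,
                          lambda = NULL) {
  assertThat(all(mutScore %in% c(0, 1)),
             "mutation score must be 0/1")
  ids <- names(pMeth)
  assertThat(!is.null(ids) &&
               identical(ids, names(pMotif)) &&
               identical(ids, names(pCnv)) &&
               identical(ids, names(mutScore)),
             "the four input vectors must be aligned to the same samples")
  lab <- canonicalLabels(labels)
  X <- cbind(p_methylation = pMeth, p_endmotif = pMotif, p_cnv = pCnv,
             mutation_score = as.numeric(mutScore))
  fit <- ridgeLogistic(X, as.numeric(lab == "case"),
                       lambda %||% (1e-4 * length(ids)))
  list(coefficients = fit$coefficients, converged = fit$converged)
}

predictIntegrated <- function(coefs, pMeth, pMotif, pCnv, mutScore) {
  eta <- coefs[1] + coefs[2] * pMeth + coefs[3] * pMotif +
    coefs[4] * pCnv + coefs[5] * as.numeric(mutScore)
  setNames(stats::plogis(eta), names(pMeth))
}

#' Train the full stacked multiomics classifier
#'
#' On the training cohort: select markers per omics, draw a stratified
#' k-fold partition, compute out-of-fold sub-model probabilities, fit the
#' full-cohort sub-models, fit the integrated combiner on the out-of-fold
#' probabilities plus the mutation score, compute integrated out-of-fold
#' probabilities with the same partition, and choose Youden cutoffs from
#' the out-of-fold scores.
#'
#' @param featureSEs Named list (methylation/endmotif/cnv) of training
#'   feature containers.
#' @param mutScore Named 0/1 vector for the training samples.
#' @param selConfig A [SelectionConfig-class].
#' @param mutConfig A [MutationFilterConfig-class] frozen into the bundle.
#' @param k Fold count (default 10).
#' @param seed Partition seed.
#' @param lambda Ridge strength (`NULL` = `1e-4 * n`).
#' @param pon Panel-of-normals reference to freeze (may be empty).
#' @param arms Arm table to freeze.
#' @param cutoffMethod Passed to [chooseCutoff()].
#' @param nestedSelection If `TRUE`, marker selection is additionally
#'   re-run inside every cross-validation fold when computing the
#'   out-of-fold sub-model probabilities, removing the optimistic bias
#'   of selecting on the full training cohort (the default mirrors the
#'   selection-then-model sequence; the frozen validation-time selection
#'   always comes from the full training cohort).
#' @return List: model ([StackedModel-class]) and oof (data.frame of
#'   training out-of-fold scores: sample_id, label, p_methylation,
#'   p_endmotif, p_cnv, mutation_score, p_integrated).
#' @export
trainStackedModel <- function(featureSEs, mutScore,
                              selConfig = selectionConfig(),
                              mutConfig = mutationFilterConfig(),
                              k = 10, seed = 1, lambda = NULL,
                              pon = data.frame(), arms = armTable(),
                              cutoffMethod = "youden",
                              nestedSelection = FALSE) {
  si <- as.data.frame(
    SummarizedExperiment::colData(featureSEs$methylation))
  labels <- setNames(canonicalLabels(si$label), si$sample_id)
  selection <- selectMarkers(featureSEs, selConfig)
  partition <- makeCVPartition(labels, k = k, seed = seed)
  tags <- c("methylation", "endmotif", "cnv")
  oof <- list(); subs <- list()
  for (om in tags) {
    feats <- selection[[om]]$selected
    oof[[om]] <- if (nestedSelection)
      nestedCrossValProbs(featureSEs[[om]], labels, partition, om,
                          selConfig, lambda)
    else crossValProbs(featureSEs[[om]], labels, partition,
                       feats, om, lambda)
    subs[[om]] <- if (length(feats) == 0)
      constantSubModel(labels, om,
                       lambda %||% (1e-4 * length(labels)))
    else fitSubModel(featureSEs[[om]], labels, feats, om, lambda)
  }
  ms <- mutScore[names(labels)]
  assertThat(!anyNA(ms), "mutation scores missing for some samples")
  integ <- fitIntegrated(oof$methylation, oof$endmotif, oof$cnv, ms,
                         labels, lambda)
  # integrated out-of-fold probabilities under the same partition
  fold <- partition@assignments[names(labels)]
  pInt <- setNames(rep(NA_real_, length(labels)), names(labels))
  for (j in seq_len(partition@k)) {
    tr <- fold != j
    if (!any(!tr)) next
    fitJ <- fitIntegrated(oof$methylation[tr], oof$endmotif[tr],
                          oof$cnv[tr], ms[tr], labels[tr], lambda)
    te <- !tr
    pInt[te] <- predictIntegrated(fitJ$coefficients,
                                  oof$methylation[te], oof$endmotif[te],
                                  oof$cnv[te], ms[te])
  }
  cut <- c(vapply(tags, function(om)
    chooseCutoff(oof[[om]], labels, cutoffMethod), 1),
    integrated = chooseCutoff(pInt, labels, cutoffMethod))
  imputation <- S4Vectors::metadata(featureSEs$methylation)$imputation %||%
    numeric(0)
  provenance <- list(
    seed = seed, k = k,
    selection_config = list(alpha = selConfig@univariateAlpha,
                            n_select = as.list(selConfig@nSelect),
                            rf_trees = selConfig@rfTrees,
                            rf_seed = selConfig@rfSeed),
    package_version = as.character(utils::packageVersion("cfdnaStack")))
  provenance$config_hash <- configHash(provenance)
  model <- new("StackedModel", subModels = subs,
               integrated = unname(integ$coefficients), cutoffs = cut,
               cvPartition = partition, mutationFilter = mutConfig,
               imputation = imputation, pon = as.data.frame(pon),
               armTable = as.data.frame(arms),
               selection = lapply(selection, `[[`, "selected"),
               provenance = provenance)
  oofTab <- data.frame(sample_id = names(labels),
                       label = as.character(labels),
                       p_methylation = unname(oof$methylation),
                       p_endmotif = unname(oof$endmotif),
                       p_cnv = unname(oof$cnv),
                       mutation_score = unname(ms),
                       p_integrated = unname(pInt))
  list(model = model, oof = oofTab)
}

#' @describeIn trainStackedModel Predict a cohort with a fitted stacked
#'   model: per-omics probabilities, the integrated probability and the
#'   binary call at the stored cutoff. Validation features must have been
#'   extracted with the training-frozen preprocessing (imputation
#'   medians, panel of normals) — see `extractFeatures()`.
#' @param object A [StackedModel-class].
#' @param featureSEs Named list of validation feature containers.
#' @param mutScore Named 0/1 vector for the validation samples.
#' @param missingPolicy "fail" (default) errors on samples missing an
#'   omics; "skip" drops them with a warning.
#' @export
setMethod("predict", "StackedModel",
          function(object, featureSEs, mutScore,
                   missingPolicy = c("fail", "skip"), ...) {
  missingPolicy <- match.arg(missingPolicy)
  mats <- lapply(c("methylation", "endmotif", "cnv"),
                 function(om) featureValues(featureSEs[[om]]))
  names(mats) <- c("methylation", "endmotif", "cnv")
  common <- Reduce(intersect, c(lapply(mats, rownames),
                                list(names(mutScore))))
  all <- Reduce(union, c(lapply(mats, rownames), list(names(mutScore))))
  dropped <- setdiff(all, common)
  if (length(dropped)) {
    if (missingPolicy == "fail")
      stopf("samples missing one or more omics inputs: %s",
            paste(dropped, collapse = ", "))
    warning(sprintf("skipping samples missing omics inputs: %s",
                    paste(dropped, collapse = ", ")))
  }
  p <- lapply(names(mats), function(om)
    predict(object@subModels[[om]], mats[[om]][common, , drop = FALSE]))
  names(p) <- names(mats)
  ms <- mutScore[common]
  pInt <- predictIntegrated(object@integrated, p$methylation,
                            p$endmotif, p$cnv, ms)
  data.frame(sample_id = common,
             p_methylation = unname(p$methylation),
             p_endmotif = unname(p$endmotif),
             p_cnv = unname(p$cnv),
             mutation_score = unname(ms),
             p_integrated = unname(pInt),
             call_methylation = unname(p$methylation >=
                                         object@cutoffs[["methylation"]]),
             call_endmotif = unname(p$endmotif >=
                                      object@cutoffs[["endmotif"]]),
             call_cnv = unname(p$cnv >= object@cutoffs[["cnv"]]),
             call = unname(pInt >= object@cutoffs[["integrated"]]))
})

#' Serialize a stacked model to a JSON bundle
#'
#' The whole fitted state (selection, standardization, coefficients,
#' cutoffs, CV partition, mutation filter, imputation medians, panel of
#' normals, arm table, provenance) round-trips through one JSON document.
#'
#' @param model A [StackedModel-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeModel <- function(model, path) {
  sm <- lapply(model@subModels, function(s) list(
    omics = s@omicsTag, features = as.list(s@features),
    center = as.list(s@center), scale = as.list(s@scale),
    coefficients = s@coefficients, lambda = s@lambda,
    cutoff = if (is.finite(s@cutoff)) s@cutoff else NULL))
  doc <- list(
    format = "cfdnaStack/model/1",
    sub_models = sm,
    integrated = model@integrated,
    cutoffs = as.list(model@cutoffs),
    cv_partition = list(k = model@cvPartition@k,
                        seed = model@cvPartition@seed,
                        stratified = model@cvPartition@stratified,
                        assignments = as.list(model@cvPartition@assignments)),
    mutation_filter = list(
      allowed_effects = model@mutationFilter@allowedEffects,
      min_cosmic_count = model@mutationFilter@minCosmicCount,
      require_hotspot_for_missense =
        model@mutationFilter@requireHotspotForMissense,
      min_vaf = model@mutationFilter@minVaf,
      min_alt_reads = model@mutationFilter@minAltReads,
      gene_panel = model@mutationFilter@genePanel),
    imputation = as.list(model@imputation),
    pon = as.list(model@pon),
    arm_table = as.list(model@armTable),
    selection = lapply(model@selection, as.list),
    provenance = model@provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stacked model bundle written by [writeModel()]
#'
#' @param path JSON path.
#' @return A [StackedModel-class].
#' @export
readModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  assertThat(identical(doc$format, "cfdnaStack/model/1"),
             "not a cfdnaStack model bundle: %s", path)
  num <- function(x) if (length(x)) setNames(as.numeric(unlist(x)),
                                             names(x)) else numeric(0)
  chr <- function(x) as.character(unlist(x))
  tab <- function(x) if (length(x))
    as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE) else
    data.frame()
  subs <- lapply(doc$sub_models, function(s) {
    new("CfSubModel", omicsTag = s$omics, features = chr(s$features),
        center = num(s$center), scale = num(s$scale),
        coefficients = as.numeric(unlist(s$coefficients)),
        lambda = s$lambda,
        cutoff = if (length(s$cutoff) == 0) NA_real_ else
          as.numeric(s$cutoff),
        converged = TRUE)
  })
  cv <- new("CVPartition", k = as.integer(doc$cv_partition$k),
            assignments = setNames(
              as.integer(unlist(doc$cv_partition$assignments)),
              names(doc$cv_partition$assignments)),
            stratified = isTRUE(doc$cv_partition$stratified),
            seed = as.integer(doc$cv_partition$seed))
  mf <- new("MutationFilterConfig",
            allowedEffects = chr(doc$mutation_filter$allowed_effects),
            minCosmicCount = doc$mutation_filter$min_cosmic_count,
            requireHotspotForMissense =
              isTRUE(doc$mutation_filter$require_hotspot_for_missense),
            minVaf = doc$mutation_filter$min_vaf,
            minAltReads = doc$mutation_filter$min_alt_reads,
            genePanel = chr(doc$mutation_filter$gene_panel))
  new("StackedModel", subModels = subs,
      integrated = as.numeric(unlist(doc$integrated)),
      cutoffs = num(doc$cutoffs),
      cvPartition = cv, mutationFilter = mf,
      imputation = num(doc$imputation),
      pon = tab(doc$pon),
      armTable = tab(doc$arm_table),
      selection = lapply(doc$selection, chr),
      provenance = doc$provenance)
}
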