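#' Marker-selection configuration
#'
#' @param univariateAlpha BH-adjusted alpha of the rank-sum filter
#'   (default 0.05).
#' @param nSelect Per-omics target marker counts; defaults mirror a
#'   typical retained panel of 23 methylation markers, 14 end motifs and
#'   34 chromosome arms.
#' @param rfTrees Random-forest size (default 500).
#' @param rfSeed Forest seed.
#' @return A [SelectionConfig-class].
#' @export
selectionConfig <- function(univariateAlpha = 0.05,
                            nSelect = c(methylation = 23, endmotif = 14,
                                        cnv = 34),
                            rfTrees = 500, rfSeed = 20240822) {
  new("SelectionConfig", univariateAlpha = univariateAlpha,
      nSelect = unlist(nSelect), rfTrees = as.integer(rfTrees),
      rfSeed = as.integer(rfSeed))
}

#' Univariate rank-sum feature filter
#'
#' Two-sided Wilcoxon rank-sum test of each feature between cases and
#' controls, with Benjamini-Hochberg correction; features with adjusted
#' p below `alpha` survive. Constant features get p = 1 by convention.
#'
#' @param se Feature `SummarizedExperiment` (training cohort).
#' @param labels Optional label vector (defaults to `colData(se)$label`).
#' @param alpha BH-adjusted significance level.
#' @return data.frame feature_id / statistic / p_value / p_adjusted /
#'   keep, ordered by adjusted then raw p.
#' @export
univariateFilter <- function(se, labels = NULL, alpha = 0.05) {
  lab <- canonicalLabels(labels %||%
                           SummarizedExperiment::colData(se)$label)
  m <- featureValues(se)
  assertThat(min(table(lab)) >= 2, "need >= 2 samples per class")
  res <- lapply(colnames(m), function(f) {
    x <- m[lab == "case", f]; y <- m[lab == "control", f]
    if (length(unique(c(x, y))) < 2) {
      data.frame(feature_id = f, statistic = NA_real_, p_value = 1)
    } else {
      w <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
      data.frame(feature_id = f, statistic = unname(w$statistic),
                 p_value = w$p.value)
    }
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$keep <- res$p_adjusted < alpha
  res[order(res$p_adjusted, res$p_value, res$feature_id), ]
}

#' Random-forest importance marker selection
#'
#' Ranks the surviving features by mean decrease in Gini impurity from a
#' random forest fit on the training cohort and keeps the top `nSelect`.
#' Ties are broken lexicographically by feature id; the forest seed makes
#' the ranking deterministic. If fewer than `nSelect` features are
#' offered, all are returned with a warning.
#'
#' @param se Feature `SummarizedExperiment` (training cohort).
#' @param features Candidate feature ids (e.g. rank-sum survivors).
#' @param nSelect Number of markers to keep.
#' @param labels Optional label override.
#' @param rfTrees,rfSeed Forest size and seed.
#' @return data.frame feature_id / importance / rank, best first.
#' @export
rfSelect <- function(se, features, nSelect, labels = NULL,
                     rfTrees = 500, rfSeed = 20240822) {
  lab <- canonicalLabels(labels %||%
                           SummarizedExperiment::colData(se)$label)
  assertThat(nlevels(droplevels(lab)) == 2,
             "random-forest selection needs both classes present")
  m <- featureValues(se)[, features, drop = FALSE]
  sord <- order(rownames(m))  # canonical sample order: invariant to input shuffles
  m <- m[sord, , drop = FALSE]
  lab <- lab[sord]
  if (length(features) < nSelect)
    warning(sprintf(
      "only %d features offered for selection of %d; returning all",
      length(features), nSelect))
  ord <- order(colnames(m))  # seed-stable column order
  m <- m[, ord, drop = FALSE]
  colnames(m) <- paste0("f", seq_len(ncol(m)))  # RF-safe names
  rf <- withChildSeed(rfSeed, "rf", {
    randomForest::randomForest(x = m, y = lab, ntree = rfTrees,
                               importance = FALSE)
  })
  imp <- randomForest::importance(rf, type = 2)[, 1]
  ids <- sort(features)
  res <- data.frame(feature_id = ids, importance = unname(imp))
  res <- res[order(-res$importance, res$feature_id), ]
  res <- head(res, min(nSelect, nrow(res)))
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Select markers for every omics on the training cohort
#'
#' Methylation and end-motif features pass the univariate rank-sum filter
#' and are then ranked by random-forest importance; CNV features use the
#' univariate filter only (top `nSelect` arms by adjusted p among
#' survivors). Selection consumes training-cohort matrices only; the
#' returned ids are frozen into the fitted model and applied unchanged to
#' validation data.
#'
#' @param featureSEs Named list of feature `SummarizedExperiment`s
#'   (methylation, endmotif, cnv), training cohort.
#' @param config A [SelectionConfig-class].
#' @param labels Optional label override applied to every omics.
#' @return List with per-omics elements: selected (ids), filter (filter
#'   table), importance (RF table or NULL).
#' @export
selectMarkers <- function(featureSEs, config = selectionConfig(),
                          labels = NULL) {
  validObject(config)
  out <- list()
  for (om in c("methylation", "endmotif", "cnv")) {
    se <- featureSEs[[om]]
    assertThat(!is.null(se), "missing %s feature matrix", om)
    out[[om]] <- selectOneOmics(se, om, config, labels)
  }
  out
}

# Selection path of a single omics: rank-sum filter for all, RF ranking
# for methylation/endmotif, filter-only (top by adjusted p) for CNV.
selectOneOmics <- function(se, om, config, labels = NULL) {
  flt <- univariateFilter(se, labels, config@univariateAlpha)
  surv <- flt$feature_id[flt$keep]
  n <- config@nSelect[[om]]
  if (om == "cnv" || length(surv) == 0) {
    sel <- if (om == "cnv") head(surv, n) else character(0)
    imp <- NULL
  } else {
    imp <- rfSelect(se, surv, n, labels,
                    rfTrees = config@rfTrees, rfSeed = config@rfSeed)
    sel <- imp$feature_id
  }
  list(selected = sel, filter = flt, importance = imp)
}

#' Write the selected-marker list consumed by model fitting
#'
#' @param selection A [selectMarkers()] result.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeSelectedMarkers <- function(selection, path) {
  rows <- lapply(names(selection), function(om) {
    s <- selection[[om]]
    if (!length(s$selected)) return(NULL)
    flt <- s$filter[match(s$selected, s$filter$feature_id), ]
    data.frame(feature_id = s$selected, omics = om,
               statistic = flt$statistic, p_adjusted = flt$p_adjusted,
               importance_rank = if (is.null(s$importance)) NA_integer_
                 else s$importance$rank[match(s$selected,
                                              s$importance$feature_id)])
  })
  writeTsv(do.call(rbind, rows), path)
}
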