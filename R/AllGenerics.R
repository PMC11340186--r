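#' Omics tag of a feature container or model
#'
#' @param x A feature `SummarizedExperiment` built by this package, or a
#'   [CfSubModel-class].
#' @return Character scalar ("methylation", "endmotif" or "cnv").
#' @export
setGeneric("omicsTag", function(x) standardGeneric("omicsTag"))

#' Decision cutoffs of a fitted model
#'
#' @param x A [StackedModel-class] or [CfSubModel-class].
#' @return Named numeric vector of probability cutoffs.
#' @export
setGeneric("cutoffs", function(x) standardGeneric("cutoffs"))

#' Selected feature identifiers
#'
#' @param x A [StackedModel-class] or [CfSubModel-class].
#' @param omics Optional omics tag to restrict to.
#' @return Character vector (or named list) of feature ids.
#' @export
setGeneric("selectedFeatures",
           function(x, omics = NULL) standardGeneric("selectedFeatures"))

#' Extract one per-omics sub-model
#'
#' @param x A [StackedModel-class].
#' @param omics "methylation", "endmotif" or "cnv".
#' @return A [CfSubModel-class].
#' @export
setGeneric("subModel", function(x, omics) standardGeneric("subModel"))

#' @describeIn omicsTag Tag stored in the metadata of a feature
#'   SummarizedExperiment.
#' @export
setMethod("omicsTag", "SummarizedExperiment",
          function(x) S4Vectors::metadata(x)$omics_tag)

#' @describeIn omicsTag Tag of a sub-model.
#' @export
setMethod("omicsTag", "CfSubModel", function(x) x@omicsTag)

#' @describeIn cutoffs Cutoff of a sub-model (length-1).
#' @export
setMethod("cutoffs", "CfSubModel",
          function(x) setNames(x@cutoff, x@omicsTag))

#' @describeIn cutoffs All four cutoffs of a stacked model.
#' @export
setMethod("cutoffs", "StackedModel", function(x) x@cutoffs)

#' @describeIn selectedFeatures Feature ids of a sub-model.
#' @export
setMethod("selectedFeatures", "CfSubModel",
          function(x, omics = NULL) x@features)

#' @describeIn selectedFeatures Per-omics selected ids of a stacked model.
#' @export
setMethod("selectedFeatures", "StackedModel", function(x, omics = NULL) {
  if (is.null(omics)) return(x@selection)
  x@selection[[match.arg(omics, names(x@selection))]]
})

#' @describeIn subModel Accessor.
#' @export
setMethod("subModel", "StackedModel", function(x, omics) {
  x@subModels[[match.arg(omics, names(x@subModels))]]
})

setMethod("show", "CfSubModel", function(object) {
  cat(sprintf("CfSubModel <%s>: %d features, lambda = %.3g, cutoff = %s\n",
              object@omicsTag, length(object@features), object@lambda,
              ifelse(is.na(object@cutoff), "unset",
                     sprintf("%.3f", object@cutoff))))
})

setMethod("show", "StackedModel", function(object) {
  cat("StackedModel (integrated cfDNA multiomics classifier)\n")
  for (sm in object@subModels)
    cat(sprintf("  %-12s %3d features, cutoff %.3f\n", sm@omicsTag,
                length(sm@features), object@cutoffs[[sm@omicsTag]]))
  cat(sprintf("  %-12s p_meth/p_motif/p_cnv + mutation score, cutoff %.3f\n",
              "integrated", object@cutoffs[["integrated"]]))
  cat(sprintf("  CV: %d-fold stratified (seed %d), %d training samples\n",
              object@cvPartition@k, object@cvPartition@seed,
              length(object@cvPartition@assignments)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d cases / %d controls (seed %d)\n",
    object@nCases, object@nControls, object@seed))
  cat(sprintf("  stage mix I-IV: %s\n",
              paste(sprintf("%.1f%%", 100 * object@stageProportions),
                    collapse = " / ")))
  cat(sprintf("  median tumor fraction by stage: %s\n",
              paste(sprintf("%.3f", exp(object@tfMeanlog)),
                    collapse = " / ")))
})
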