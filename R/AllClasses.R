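#' @importClassesFrom S4Vectors DataFrame
NULL

#' Simulation configuration for synthetic cfDNA cohorts
#'
#' Parameters of the two-arm (cancer cases vs healthy controls) cohort
#' simulator. Cases draw a tumor fraction from a stage-specific log-normal
#' distribution (clamped to \[0, 1\]); every omics signal scales with that
#' tumor fraction. See [simulationConfig()] for defaults and units.
#'
#' @slot nCases,nControls Cohort arm sizes.
#' @slot stageProportions Named probability 4-vector over stages I--IV
#'   (sums to 1).
#' @slot tfMeanlog,tfSdlog Named per-stage location/scale of the
#'   log-normal tumor-fraction distribution.
#' @slot nMethMarkers,nInformativeMeth Number of targeted methylation
#'   markers and how many carry a tumor signal.
#' @slot methDepth Mean molecule count per methylation site (Poisson).
#' @slot nFragments Fragments drawn per sample for end-motif profiling.
#' @slot nMotifAffected Number of 4-mers enriched in the tumor end-motif
#'   profile.
#' @slot motifEffectSize Relative enrichment (fold change minus 1 >= 0) of
#'   affected motifs in the tumor profile before renormalization.
#' @slot nAlteredArms Number of chromosome arms with clonal copy-number
#'   change in cases.
#' @slot binDepth Mean read count per genomic bin (library-size scale).
#' @slot nbSize Negative-binomial size (dispersion) of bin counts.
#' @slot binSize Genomic bin width in bp.
#' @slot mutationResponseScale Scale `tau` of the monotone detection curve
#'   `P(true positive | tf) = 1 - exp(-tf / tau)`.
#' @slot controlMutationFpRate Probability that a sample carries a
#'   CHIP-like filter-passing false-positive mutation (background rate,
#'   applied to both arms).
#' @slot seed Integer base seed; per-sample streams are derived from it by
#'   stable hashing of the sample identifier.
#' @slot panelSeed Seed fixing the marker-panel ground truth, shared
#'   across cohorts so trained models transfer between them.
#' @export
setClass("SimulationConfig", representation(
  nCases = "integer", nControls = "integer",
  stageProportions = "numeric",
  tfMeanlog = "numeric", tfSdlog = "numeric",
  nMethMarkers = "integer", nInformativeMeth = "integer",
  methDepth = "numeric",
  nFragments = "integer", nMotifAffected = "integer",
  motifEffectSize = "numeric",
  nAlteredArms = "integer", binDepth = "numeric", nbSize = "numeric",
  binSize = "numeric",
  mutationResponseScale = "numeric", controlMutationFpRate = "numeric",
  seed = "integer", panelSeed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  chkPos <- function(v, nm) if (any(v <= 0)) sprintf("%s must be > 0", nm)
  msg <- c(msg,
    chkPos(object@nCases, "nCases"), chkPos(object@nControls, "nControls"),
    chkPos(object@nMethMarkers, "nMethMarkers"),
    chkPos(object@methDepth, "methDepth"),
    chkPos(object@nFragments, "nFragments"),
    chkPos(object@binDepth, "binDepth"), chkPos(object@nbSize, "nbSize"),
    chkPos(object@binSize, "binSize"),
    chkPos(object@mutationResponseScale, "mutationResponseScale"))
  if (abs(sum(object@stageProportions) - 1) > 1e-9)
    msg <- c(msg, "stageProportions must sum to 1 (tolerance 1e-9)")
  if (length(object@stageProportions) != 4L ||
      !identical(names(object@stageProportions), c("I", "II", "III", "IV")))
    msg <- c(msg, "stageProportions must be named I, II, III, IV")
  if (!identical(names(object@tfMeanlog), c("I", "II", "III", "IV")) ||
      !identical(names(object@tfSdlog), c("I", "II", "III", "IV")))
    msg <- c(msg, "tfMeanlog/tfSdlog must be named I, II, III, IV")
  if (any(object@tfSdlog < 0)) msg <- c(msg, "tfSdlog must be >= 0")
  if (object@motifEffectSize < 0)
    msg <- c(msg, "motifEffectSize must be >= 0")
  if (object@controlMutationFpRate < 0 || object@controlMutationFpRate > 1)
    msg <- c(msg, "controlMutationFpRate must be in [0, 1]")
  if (object@nInformativeMeth > object@nMethMarkers)
    msg <- c(msg, "nInformativeMeth cannot exceed nMethMarkers")
  if (length(msg)) msg else TRUE
})

#' Mutation eligibility filter configuration
#'
#' Thresholds of the stringent candidate-mutation filter: mutation type
#' (effect class), hotspot/COSMIC recurrence, variant allele frequency and
#' supporting-read floor, restricted to a driver-gene panel.
#'
#' @slot allowedEffects Eligible effect classes.
#' @slot minCosmicCount Minimum COSMIC recurrence count when the call is
#'   not a curated hotspot.
#' @slot requireHotspotForMissense If `TRUE`, missense calls must be
#'   hotspots regardless of COSMIC count.
#' @slot minVaf Minimum variant allele frequency.
#' @slot minAltReads Minimum alt-supporting reads.
#' @slot genePanel Gene symbols eligible for scoring.
#' @export
setClass("MutationFilterConfig", representation(
  allowedEffects = "character", minCosmicCount = "numeric",
  requireHotspotForMissense = "logical", minVaf = "numeric",
  minAltReads = "numeric", genePanel = "character"))

setValidity("MutationFilterConfig", function(object) {
  msg <- character(0)
  if (object@minCosmicCount < 0 || object@minVaf < 0 ||
      object@minAltReads < 0)
    msg <- c(msg, "thresholds must be non-negative")
  known <- c("missense", "nonsense", "frameshift", "splice", "synonymous",
             "other")
  if (!all(object@allowedEffects %in% known))
    msg <- c(msg, sprintf("unknown effect classes: %s",
                          paste(setdiff(object@allowedEffects, known),
                                collapse = ", ")))
  if (length(object@genePanel) == 0) msg <- c(msg, "genePanel is empty")
  if (length(msg)) msg else TRUE
})

#' Marker selection configuration
#'
#' @slot univariateAlpha BH-adjusted significance level of the per-feature
#'   Wilcoxon rank-sum filter.
#' @slot nSelect Named per-omics target marker counts
#'   (methylation/endmotif/cnv).
#' @slot rfTrees Random forest size.
#' @slot rfSeed Seed of the forest used for importance ranking.
#' @export
setClass("SelectionConfig", representation(
  univariateAlpha = "numeric", nSelect = "numeric",
  rfTrees = "integer", rfSeed = "integer"))

setValidity("SelectionConfig", function(object) {
  msg <- character(0)
  if (object@univariateAlpha <= 0 || object@univariateAlpha > 1)
    msg <- c(msg, "univariateAlpha must be in (0, 1]")
  if (!all(c("methylation", "endmotif", "cnv") %in% names(object@nSelect)))
    msg <- c(msg, "nSelect must name methylation, endmotif and cnv")
  if (any(object@nSelect < 1)) msg <- c(msg, "nSelect must be >= 1")
  if (object@rfTrees < 1) msg <- c(msg, "rfTrees must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Stratified cross-validation partition
#'
#' @slot k Fold count.
#' @slot assignments Named integer vector, sample id to fold index.
#' @slot stratified Whether folds were stratified by class label.
#' @slot seed Seed used to draw the partition.
#' @export
setClass("CVPartition", representation(
  k = "integer", assignments = "integer", stratified = "logical",
  seed = "integer"))

setValidity("CVPartition", function(object) {
  msg <- character(0)
  if (object@k < 2) msg <- c(msg, "k must be >= 2")
  if (is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by sample id")
  if (length(object@assignments) &&
      (min(object@assignments) < 1 || max(object@assignments) > object@k))
    msg <- c(msg, "fold indices must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Per-omics ridge-logistic sub-model
#'
#' A logistic regression on z-standardized selected features with a small
#' L2 penalty on the slopes (the intercept is unpenalized). Features whose
#' training standard deviation is zero are dropped at fit time.
#'
#' @slot omicsTag One of methylation/endmotif/cnv (or "integrated").
#' @slot features Ordered selected feature ids.
#' @slot center,scale Per-feature training mean and standard deviation.
#' @slot coefficients Intercept followed by per-feature weights on the
#'   standardized scale.
#' @slot lambda Ridge strength actually used.
#' @slot cutoff Probability threshold (NA until chosen).
#' @slot converged Whether IRLS met its tolerance.
#' @export
setClass("CfSubModel", representation(
  omicsTag = "character", features = "character",
  center = "numeric", scale = "numeric", coefficients = "numeric",
  lambda = "numeric", cutoff = "numeric", converged = "logical"))

setValidity("CfSubModel", function(object) {
  msg <- character(0)
  p <- length(object@features)
  if (length(object@coefficients) != p + 1L)
    msg <- c(msg, "coefficients must have length |features| + 1")
  if (length(object@center) != p || length(object@scale) != p)
    msg <- c(msg, "center/scale must match features")
  if (p && any(object@scale <= 0))
    msg <- c(msg, "scale must be > 0 (zero-sd features are dropped)")
  if (length(msg)) msg else TRUE
})

#' Stacked multiomics classifier
#'
#' The full fitted bundle: three per-omics sub-models, the mutation filter
#' configuration (the fourth input is the binary mutation score), the
#' integrated logistic combiner over the four inputs, per-model cutoffs,
#' the training cross-validation partition, training-frozen preprocessing
#' (methylation imputation medians, CNV panel of normals, arm table) and
#' provenance (config hash, seeds).
#'
#' @slot subModels Named list of [CfSubModel-class] objects
#'   (methylation, endmotif, cnv).
#' @slot integrated Integrated coefficients: intercept then weights on
#'   p_methylation, p_endmotif, p_cnv, mutation_score.
#' @slot cutoffs Named cutoffs (methylation, endmotif, cnv, integrated).
#' @slot cvPartition [CVPartition-class] used for out-of-fold scores.
#' @slot mutationFilter [MutationFilterConfig-class].
#' @slot imputation Named per-marker methylation imputation medians.
#' @slot pon Per-bin panel-of-normals reference (data.frame:
#'   chrom/start/end/gc/reference).
#' @slot armTable Arm definition table used for CNV summarization.
#' @slot selection Named list of selected feature ids per omics.
#' @slot provenance List: config hash, seeds, package version.
#' @export
setClass("StackedModel", representation(
  subModels = "list", integrated = "numeric", cutoffs = "numeric",
  cvPartition = "CVPartition", mutationFilter = "MutationFilterConfig",
  imputation = "numeric", pon = "data.frame", armTable = "data.frame",
  selection = "list", provenance = "list"))

setValidity("StackedModel", function(object) {
  msg <- character(0)
  need <- c("methylation", "endmotif", "cnv")
  if (!all(need %in% names(object@subModels)))
    msg <- c(msg, "subModels must name methylation, endmotif and cnv")
  if (length(object@integrated) != 5L)
    msg <- c(msg, "integrated must be intercept + exactly 4 input weights")
  if (!all(c(need, "integrated") %in% names(object@cutoffs)))
    msg <- c(msg, "cutoffs must name the three sub-models and integrated")
  ic <- object@cutoffs[["integrated"]]
  if (is.finite(ic) && (ic <= 0 || ic >= 1))
    msg <- c(msg, "integrated cutoff must be in (0, 1)")
  if (length(msg)) msg else TRUE
})
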