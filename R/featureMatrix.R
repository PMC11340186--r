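#' Assemble a feature SummarizedExperiment
#'
#' Feature matrices are carried as `SummarizedExperiment` objects with
#' features as rows and samples as columns, two assays (`values` and the
#' logical `missing` mask marking imputed entries), the sample sheet as
#' `colData` and the omics tag in `metadata`.
#'
#' @param values Numeric matrix, features x samples (dimnames required).
#' @param sampleInfo data.frame keyed by `sample_id` (sample sheet rows).
#' @param omicsTag "methylation", "endmotif" or "cnv".
#' @param missing Logical matrix of the same shape; defaults to all-FALSE.
#' @return A `SummarizedExperiment`.
#' @export
featureMatrix <- function(values, sampleInfo, omicsTag,
                          missing = NULL) {
  assertThat(is.matrix(values) && !is.null(rownames(values)) &&
               !is.null(colnames(values)),
             "values must be a matrix with feature and sample dimnames")
  omicsTag <- match.arg(omicsTag, c("methylation", "endmotif", "cnv"))
  if (is.null(missing))
    missing <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  assertThat(identical(dim(missing), dim(values)),
             "missing mask must match values dimensions")
  assertThat(!anyNA(values[!missing]),
             "NaN/NA outside the missing mask in %s matrix", omicsTag)
  si <- as.data.frame(sampleInfo)
  assertThat(all(colnames(values) %in% si$sample_id),
             "samples absent from the sample sheet: %s",
             paste(setdiff(colnames(values), si$sample_id), collapse = ", "))
  si <- si[match(colnames(values), si$sample_id), , drop = FALSE]
  rownames(si) <- si$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values, missing = missing),
    colData = S4Vectors::DataFrame(si))
  S4Vectors::metadata(se)$omics_tag <- omicsTag
  se
}

#' Samples-by-features value matrix of a feature container
#'
#' Modeling code works on the transposed (samples as rows) orientation.
#'
#' @param se A feature `SummarizedExperiment`.
#' @return Numeric matrix, samples x features.
#' @export
featureValues <- function(se) t(SummarizedExperiment::assay(se, "values"))

#' Missing-value mask, samples x features
#'
#' @param se A feature `SummarizedExperiment`.
#' @return Logical matrix marking imputed entries.
#' @export
missingMask <- function(se) t(SummarizedExperiment::assay(se, "missing"))

#' Sample labels attached to a feature container
#'
#' @param se A feature `SummarizedExperiment`.
#' @return Factor with levels control, case.
#' @export
sampleLabels <- function(se) {
  canonicalLabels(SummarizedExperiment::colData(se)$label)
}

#' Write a feature matrix as TSV (samples as rows)
#'
#' @param se A feature `SummarizedExperiment`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeFeatureMatrix <- function(se, path) {
  m <- featureValues(se)
  dt <- data.table::data.table(sample_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  writeTsv(dt, path)
}
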