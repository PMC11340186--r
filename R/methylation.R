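#' Per-site DNA methylation level
#'
#' The methylation level (beta) of a targeted marker is the number of
#' methylated molecules divided by the total number of methylated plus
#' unmethylated molecules observed at that position. Sites with zero
#' denominator, or with total coverage below `minMolecules`, return `NA`:
#' ratios from a handful of molecules are too unstable to use as features
#' and are left to downstream imputation.
#'
#' @param methylated,unmethylated Non-negative integer counts (vectorized).
#' @param minMolecules Coverage floor below which the level is `NA`
#'   (default 10).
#' @return Numeric vector of levels in \[0, 1\], `NA` where undefined.
#' @examples
#' methylationLevel(30, 70)        # 0.3
#' methylationLevel(2, 3)          # NA: below the coverage floor
#' @export
methylationLevel <- function(methylated, unmethylated, minMolecules = 10) {
  chk <- function(x, nm) {
    assertThat(all(is.finite(x)) && all(x >= 0) && all(x == floor(x)),
               "%s must be non-negative integer counts", nm)
  }
  chk(methylated, "methylated"); chk(unmethylated, "unmethylated")
  total <- methylated + unmethylated
  out <- ifelse(total == 0 | total < minMolecules, NA_real_,
                methylated / total)
  as.numeric(out)
}

#' Build the methylation feature matrix
#'
#' One row per marker, one column per sample. Entries with insufficient
#' coverage are imputed with the per-marker median over the cohort the
#' matrix is built from (the training cohort when fitting); the imputation
#' medians are returned so they can be frozen into the model and re-applied
#' unchanged to validation cohorts. Markers that are missing in every
#' sample are dropped with a warning.
#'
#' @param counts data.frame with columns sample_id, marker_id, methylated,
#'   unmethylated.
#' @param sampleInfo Sample sheet (sample_id, label, stage, ...).
#' @param minMolecules Coverage floor passed to [methylationLevel()].
#' @param imputation Optional named vector of frozen per-marker medians
#'   (from a fitted model); when supplied, it is used instead of cohort
#'   medians and markers are restricted to its names.
#' @return A feature `SummarizedExperiment` with attribute-free assays and
#'   the imputation medians in `metadata(se)$imputation`.
#' @export
buildMethylationMatrix <- function(counts, sampleInfo, minMolecules = 10,
                                   imputation = NULL) {
  counts <- data.table::as.data.table(counts)
  need <- c("sample_id", "marker_id", "methylated", "unmethylated")
  assertThat(all(need %in% names(counts)),
             "methylation counts need columns: %s", paste(need, collapse = ", "))
  si <- as.data.frame(sampleInfo)
  unknown <- setdiff(unique(counts$sample_id), si$sample_id)
  assertThat(length(unknown) == 0,
             "count rows for samples absent from the sample sheet: %s",
             paste(unknown, collapse = ", "))
  dup <- counts[duplicated(counts[, c("sample_id", "marker_id")]), ]
  assertThat(nrow(dup) == 0,
             "duplicate (sample, marker) pairs: %s",
             paste(unique(paste(dup$sample_id, dup$marker_id, sep = "/")),
                   collapse = ", "))
  counts$level <- methylationLevel(counts$methylated, counts$unmethylated,
                                   minMolecules)
  markers <- if (is.null(imputation)) sort(unique(counts$marker_id)) else
    names(imputation)
  samples <- si$sample_id
  m <- matrix(NA_real_, length(markers), length(samples),
              dimnames = list(markers, samples))
  m[cbind(match(counts$marker_id, markers),
          match(counts$sample_id, samples))] <- counts$level
  miss <- is.na(m)
  med <- if (is.null(imputation)) {
    apply(m, 1, median, na.rm = TRUE)
  } else imputation
  allMissing <- !is.finite(med)
  if (any(allMissing)) {
    warning(sprintf("dropping markers with no usable coverage: %s",
                    paste(markers[allMissing], collapse = ", ")))
    m <- m[!allMissing, , drop = FALSE]
    miss <- miss[!allMissing, , drop = FALSE]
    med <- med[!allMissing]
  }
  if (any(miss)) m[miss] <- med[row(m)[miss]]
  se <- featureMatrix(m, si, "methylation", missing = miss)
  S4Vectors::metadata(se)$imputation <- med
  se
}
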