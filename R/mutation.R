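#' Default mutation eligibility filter
#'
#' Constructs a [MutationFilterConfig-class]. Defaults implement a
#' stringent somatic-call filter for cfDNA screening: eligible calls must
#' be protein-altering (missense/nonsense/frameshift/splice), lie in a
#' colorectal-cancer driver panel (APC, TP53, KRAS, PIK3CA, FBXW7, BRAF,
#' ACVR2A), be either a curated hotspot or recurrent in COSMIC, and clear
#' VAF and supporting-read floors; missense calls additionally require a
#' hotspot by default (missense passengers and CHIP artifacts dominate the
#' false positives).
#'
#' @param allowedEffects Eligible effect classes.
#' @param minCosmicCount COSMIC recurrence floor for non-hotspot calls.
#' @param requireHotspotForMissense Require hotspot annotation on missense.
#' @param minVaf VAF floor.
#' @param minAltReads Supporting-read floor.
#' @param genePanel Gene symbols scored.
#' @return A `MutationFilterConfig`.
#' @export
mutationFilterConfig <- function(
    allowedEffects = c("missense", "nonsense", "frameshift", "splice"),
    minCosmicCount = 3, requireHotspotForMissense = TRUE,
    minVaf = 0.001, minAltReads = 3,
    genePanel = c("APC", "TP53", "KRAS", "PIK3CA", "FBXW7", "BRAF",
                  "ACVR2A")) {
  new("MutationFilterConfig", allowedEffects = allowedEffects,
      minCosmicCount = minCosmicCount,
      requireHotspotForMissense = requireHotspotForMissense,
      minVaf = minVaf, minAltReads = minAltReads, genePanel = genePanel)
}

.effectClasses <- c("missense", "nonsense", "frameshift", "splice",
                    "synonymous", "other")

validateCalls <- function(calls) {
  calls <- as.data.frame(calls)
  need <- c("sample_id", "gene", "effect_class", "vaf", "alt_reads",
            "depth", "cosmic_count", "hotspot")
  assertThat(all(need %in% names(calls)),
             "mutation calls need columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(calls$effect_class), .effectClasses)
  assertThat(length(bad) == 0, "unknown effect_class value(s): %s",
             paste(bad, collapse = ", "))
  assertThat(all(calls$alt_reads <= calls$depth),
             "alt_reads exceeds depth in %d call(s)",
             sum(calls$alt_reads > calls$depth))
  incons <- abs(calls$vaf - calls$alt_reads / pmax(calls$depth, 1)) > 0.005
  assertThat(!any(incons),
             "vaf inconsistent with alt_reads/depth in %d call(s)",
             sum(incons))
  calls$hotspot <- as.logical(calls$hotspot)
  calls
}

#' Apply the mutation eligibility filter
#'
#' A call is eligible iff, evaluated in order: its gene is in the panel;
#' its effect class is allowed; it is a hotspot or has COSMIC recurrence
#' at least `minCosmicCount` (missense additionally requires a hotspot
#' when configured); its VAF and alt-read count clear the floors. Every
#' rejected call is annotated with the first failing criterion, so
#' diagnostics are deterministic.
#'
#' @param calls Candidate mutation table (see [readMutationTsv()] schema).
#' @param config A [MutationFilterConfig-class].
#' @return The call table with logical `eligible` and character `reason`
#'   ("pass" or the first failing criterion: gene_panel, mutation_type,
#'   hotspot_cosmic, vaf, alt_reads).
#' @export
filterEligible <- function(calls, config = mutationFilterConfig()) {
  calls <- validateCalls(calls)
  n <- nrow(calls)
  reason <- rep("pass", n)
  fail <- function(reason, cond, tag) ifelse(reason == "pass" & cond,
                                             tag, reason)
  reason <- fail(reason, !(calls$gene %in% config@genePanel), "gene_panel")
  reason <- fail(reason,
                 !(calls$effect_class %in% config@allowedEffects),
                 "mutation_type")
  recOk <- calls$hotspot | calls$cosmic_count >= config@minCosmicCount
  if (config@requireHotspotForMissense)
    recOk <- recOk & !(calls$effect_class == "missense" & !calls$hotspot)
  reason <- fail(reason, !recOk, "hotspot_cosmic")
  reason <- fail(reason, calls$vaf < config@minVaf, "vaf")
  reason <- fail(reason, calls$alt_reads < config@minAltReads, "alt_reads")
  calls$eligible <- reason == "pass"
  calls$reason <- reason
  calls
}

#' Binary mutation score of one sample
#'
#' 1 if the sample carries at least one eligible mutation, else 0
#' (including for an empty call list).
#'
#' @param calls Candidate calls of one sample (may be empty).
#' @param config A [MutationFilterConfig-class].
#' @return 0 or 1.
#' @export
mutationScore <- function(calls, config = mutationFilterConfig()) {
  if (is.null(calls) || nrow(as.data.frame(calls)) == 0) return(0L)
  as.integer(any(filterEligible(calls, config)$eligible))
}

#' Per-sample mutation scores for a cohort
#'
#' @param calls Cohort-wide candidate call table (sample_id column).
#' @param sampleIds Samples to score (samples without calls score 0).
#' @param config A [MutationFilterConfig-class].
#' @return Named integer vector of 0/1 scores.
#' @export
mutationScores <- function(calls, sampleIds,
                           config = mutationFilterConfig()) {
  scores <- setNames(rep(0L, length(sampleIds)), sampleIds)
  if (!is.null(calls) && nrow(as.data.frame(calls)) > 0) {
    flt <- filterEligible(calls, config)
    pos <- unique(flt$sample_id[flt$eligible])
    scores[intersect(pos, sampleIds)] <- 1L
  }
  scores
}

#' Per-gene and overall mutation detection table
#'
#' For each panel gene, the fraction of case and control samples carrying
#' at least one eligible call in that gene, plus an overall row giving the
#' mutation-score positivity of each arm.
#'
#' @param calls Cohort-wide candidate call table.
#' @param sampleInfo Sample sheet with sample_id and label.
#' @param config A [MutationFilterConfig-class].
#' @return data.frame gene / case_positive / case_total / case_rate /
#'   control_positive / control_total / control_rate, with a final
#'   "overall" row.
#' @export
geneDetectionTable <- function(calls, sampleInfo,
                               config = mutationFilterConfig()) {
  si <- as.data.frame(sampleInfo)
  lab <- canonicalLabels(si$label)
  caseIds <- si$sample_id[lab == "case"]
  ctrlIds <- si$sample_id[lab == "control"]
  flt <- if (!is.null(calls) && nrow(as.data.frame(calls)) > 0)
    filterEligible(calls, config) else
    data.frame(sample_id = character(0), gene = character(0),
               eligible = logical(0))
  elig <- flt[flt$eligible, , drop = FALSE]
  rate <- function(ids, gene = NULL) {
    hits <- if (is.null(gene)) unique(elig$sample_id) else
      unique(elig$sample_id[elig$gene == gene])
    sum(ids %in% hits)
  }
  rows <- lapply(c(config@genePanel, "overall"), function(g) {
    gn <- if (g == "overall") NULL else g
    data.frame(gene = g,
               case_positive = rate(caseIds, gn),
               case_total = length(caseIds),
               case_rate = rate(caseIds, gn) / max(length(caseIds), 1),
               control_positive = rate(ctrlIds, gn),
               control_total = length(ctrlIds),
               control_rate = rate(ctrlIds, gn) / max(length(ctrlIds), 1))
  })
  do.call(rbind, rows)
}

#' Write the per-call eligibility report
#'
#' Runs [filterEligible()] and writes the annotated table (eligible flag
#' plus first-failing-criterion reason per call) as TSV.
#'
#' @param calls Candidate call table.
#' @param path Output path.
#' @param config A [MutationFilterConfig-class].
#' @return The path, invisibly.
#' @export
writeEligibilityReport <- function(calls, path,
                                   config = mutationFilterConfig()) {
  writeTsv(filterEligible(calls, config), path)
}

#' Read a candidate-mutation TSV
#'
#' Columns: sample_id, gene, chrom, pos (1-based), ref, alt, effect_class,
#' vaf, alt_reads, depth, cosmic_count, hotspot.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
readMutationTsv <- function(path) validateCalls(readTsv(path))

#' Read candidate mutations from an annotated VCF
#'
#' Expects one sample column and per-record INFO annotations: `GENE`
#' (symbol), `EFFECT` (effect class), `COSMIC_CNT` (COSMIC recurrence),
#' `HOTSPOT` (flag). Alt reads and depth come from the AD and DP FORMAT
#' fields; VAF is AD\[alt\]/DP.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @param sampleId Sample id to assign (defaults to the VCF sample name).
#' @return Validated candidate-call data.frame.
#' @export
readMutationVcf <- function(path, sampleId = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("readMutationVcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  info1 <- function(key) vcfR::extract.info(v, element = key)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  dp <- as.numeric(vcfR::extract.gt(v, element = "DP")[, 1])
  altReads <- as.numeric(vapply(strsplit(ad, ","), `[`, character(1), 2))
  sid <- sampleId %||% colnames(v@gt)[2]
  calls <- data.frame(
    sample_id = sid, gene = info1("GENE"), chrom = fix$CHROM,
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    effect_class = info1("EFFECT"),
    vaf = altReads / dp, alt_reads = altReads, depth = dp,
    cosmic_count = as.numeric(info1("COSMIC_CNT")),
    hotspot = grepl("(^|;)HOTSPOT(;|=|$)", fix$INFO))
  validateCalls(calls)
}
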