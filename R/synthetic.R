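#' Default synthetic-cohort configuration
#'
#' Builds a [SimulationConfig-class]. The defaults describe a desk-scale
#' two-arm colorectal-cancer screening cohort: 93 cases / 96 controls,
#' stage mix I--IV of 17.2/39.8/38.7/2.2% (renormalized to sum to 1),
#' stage-dependent log-normal tumor fractions with medians 1/2/4/10%,
#' 30 targeted methylation markers (25 informative) at ~800 molecules per
#' site, 20,000 fragments per sample for end-motif profiling with 20
#' tumor-enriched motifs, 12 recurrently altered chromosome arms observed
#' through ~200 reads per 1-Mb bin, and a mutation detection curve
#' `1 - exp(-tf / 0.0633)` calibrated together with a 9.4% CHIP-like
#' background false-positive rate so that the expected mutation positivity
#' is about 41.9% in cases and 9.4% in controls.
#'
#' @param nCases,nControls Arm sizes.
#' @param stageProportions Stage I--IV mixing proportions (renormalized).
#' @param tfMedianByStage Median tumor fraction per stage (log-normal
#'   location = log of this).
#' @param tfSdlog Log-scale spread of tumor fraction (per stage).
#' @param nMethMarkers,nInformativeMeth,methDepth Methylation panel size,
#'   informative markers, mean molecules per site.
#' @param nFragments,nMotifAffected,motifEffectSize End-motif profiling
#'   depth and tumor-profile perturbation.
#' @param nAlteredArms,binDepth,nbSize,binSize Copy-number signal and
#'   bin-count noise.
#' @param mutationResponseScale Scale of the detection response curve.
#' @param controlMutationFpRate Background filter-passing mutation rate.
#' @param seed Cohort seed.
#' @param panelSeed Seed fixing the marker panel truth (baselines,
#'   effects, motif profiles, altered arms, bin GC); shared across
#'   cohorts so a model trained on one cohort transfers to another.
#' @return A `SimulationConfig`.
#' @export
simulationConfig <- function(
    nCases = 93, nControls = 96,
    stageProportions = c(I = 0.172, II = 0.398, III = 0.387, IV = 0.022),
    tfMedianByStage = c(I = 0.01, II = 0.02, III = 0.04, IV = 0.10),
    tfSdlog = 0.6,
    nMethMarkers = 30, nInformativeMeth = 25, methDepth = 800,
    nFragments = 12000, nMotifAffected = 20, motifEffectSize = 7,
    nAlteredArms = 12, binDepth = 200, nbSize = 50, binSize = 1e6,
    mutationResponseScale = 0.0633, controlMutationFpRate = 0.094,
    seed = 1, panelSeed = 104729) {
  sp <- stageProportions / sum(stageProportions)
  cfg <- new("SimulationConfig",
             nCases = as.integer(nCases), nControls = as.integer(nControls),
             stageProportions = sp,
             tfMeanlog = log(tfMedianByStage),
             tfSdlog = setNames(rep_len(tfSdlog, 4),
                                c("I", "II", "III", "IV")),
             nMethMarkers = as.integer(nMethMarkers),
             nInformativeMeth = as.integer(nInformativeMeth),
             methDepth = methDepth,
             nFragments = as.integer(nFragments),
             nMotifAffected = as.integer(nMotifAffected),
             motifEffectSize = motifEffectSize,
             nAlteredArms = as.integer(nAlteredArms),
             binDepth = binDepth, nbSize = nbSize, binSize = binSize,
             mutationResponseScale = mutationResponseScale,
             controlMutationFpRate = controlMutationFpRate,
             seed = as.integer(seed), panelSeed = as.integer(panelSeed))
  cfg
}

panelSeedOf <- function(config) config@panelSeed

# Arms with recurrent clonal copy-number change in colorectal tumors,
# gains first (copies = 3), then losses (copies = 1).
.crcGains  <- c("20q", "13q", "8q", "7p", "7q", "20p")
.crcLosses <- c("18q", "18p", "17p", "8p", "4q", "1p")

#' Marker-panel ground truth of the simulator
#'
#' Deterministic given the panel seed: methylation marker baselines and
#' tumor effect sizes, control and tumor end-motif profiles, case
#' copy-number arm states, the binned genome with per-bin GC, and panel
#' gene weights for mutation placement.
#'
#' @param config A [SimulationConfig-class].
#' @param arms Arm definition table (default [armTable()]).
#' @return List with elements methMarkers, controlProfile, tumorProfile,
#'   armStates, bins, geneWeights.
#' @export
syntheticPanel <- function(config, arms = armTable()) {
  ps <- panelSeedOf(config)
  withChildSeed(ps, "panel", {
    nm <- config@nMethMarkers
    methMarkers <- data.frame(
      marker_id = sprintf("M%03d", seq_len(nm)),
      baseline = runif(nm, 0.005, 0.03),
      effect = c(runif(config@nInformativeMeth, 0.07, 0.28),
                 rep(0, nm - config@nInformativeMeth)))
    motifs <- allMotifs(4)
    cp <- stats::rgamma(length(motifs), shape = 5)
    cp <- cp / sum(cp)
    names(cp) <- motifs
    affected <- sample(motifs, config@nMotifAffected)
    tp <- cp
    tp[affected] <- tp[affected] * (1 + config@motifEffectSize)
    tp <- tp / sum(tp)
    armsAvail <- c(.crcGains, .crcLosses)
    armsAvail <- armsAvail[armsAvail %in% arms$arm_id]
    k <- config@nAlteredArms
    pick <- if (k <= length(armsAvail)) armsAvail[seq_len(k)] else
      c(armsAvail, sample(setdiff(arms$arm_id, armsAvail),
                          k - length(armsAvail)))
    armStates <- data.frame(
      arm_id = pick,
      copies = ifelse(pick %in% .crcGains, 3, 1))
    bins <- binGrid(arms, config@binSize)
    bins$gc <- runif(nrow(bins), 0.35, 0.60)
    geneWeights <- c(APC = 0.30, TP53 = 0.28, KRAS = 0.20, PIK3CA = 0.10,
                     FBXW7 = 0.05, BRAF = 0.02, ACVR2A = 0.05)
    list(methMarkers = methMarkers, controlProfile = cp, tumorProfile = tp,
         armStates = armStates, bins = bins, geneWeights = geneWeights)
  })
}

# Unimodal GC bias of sequencing depth, peaking near 45% GC.
gcBiasCurve <- function(gc) 0.6 + 0.8 * exp(-((gc - 0.45) / 0.10)^2)

#' Simulate methylation molecule counts for one sample
#'
#' Total molecules per site are Poisson(depth); methylated molecules are
#' Binomial(total, clamp(baseline + tumor_fraction * effect, 0, 1)).
#'
#' @param truth One-row sample-truth data.frame (sample_id,
#'   tumor_fraction).
#' @param markers data.frame marker_id / baseline / effect.
#' @param depth Mean molecules per site.
#' @return data.frame sample_id / marker_id / methylated / unmethylated.
#' @export
simulateMethylationCounts <- function(truth, markers, depth) {
  assertThat(all(markers$baseline >= 0 & markers$baseline <= 1),
             "marker baselines must be in [0, 1]")
  assertThat(all(markers$effect >= 0), "marker effects must be >= 0")
  beta <- pmin(1, pmax(0, markers$baseline +
                         truth$tumor_fraction * markers$effect))
  total <- rpois(nrow(markers), depth)
  meth <- rbinom(nrow(markers), total, beta)
  data.frame(sample_id = truth$sample_id, marker_id = markers$marker_id,
             methylated = meth, unmethylated = total - meth)
}

#' Simulate cfDNA fragment records with 5' end motifs for one sample
#'
#' Motifs are drawn multinomially from the mixture
#' `(1 - tf) * controlProfile + tf * tumorProfile`; coordinates are
#' uniform over the binned genome with fragment lengths around 167 bp.
#'
#' @param truth One-row sample truth.
#' @param controlProfile,tumorProfile Probability vectors over the 256
#'   4-mers (must sum to 1 within 1e-6).
#' @param nFragments Fragments to draw.
#' @param bins Bin table supplying coordinates.
#' @return data.frame sample_id / chrom / start / end / strand / motif5
#'   (0-based half-open coordinates).
#' @export
simulateFragmentMotifs <- function(truth, controlProfile, tumorProfile,
                                   nFragments, bins) {
  for (p in list(controlProfile, tumorProfile))
    assertThat(abs(sum(p) - 1) <= 1e-6 && all(p >= 0),
               "motif profiles must be probability vectors summing to 1")
  tf <- truth$tumor_fraction
  mix <- (1 - tf) * controlProfile + tf * tumorProfile
  motifs <- names(controlProfile)[
    sample.int(length(mix), nFragments, replace = TRUE, prob = mix)]
  bi <- sample.int(nrow(bins), nFragments, replace = TRUE)
  len <- pmax(60L, as.integer(round(rnorm(nFragments, 167, 10))))
  start <- bins$start[bi] +
    floor(runif(nFragments) * pmax(1, bins$end[bi] - bins$start[bi] - len))
  data.frame(sample_id = truth$sample_id, chrom = bins$chrom[bi],
             start = as.integer(start), end = as.integer(start + len),
             strand = sample(c("+", "-"), nFragments, replace = TRUE),
             motif5 = motifs)
}

#' Simulate binned read counts for one sample
#'
#' Expected depth per bin is
#' `binDepth * (1 + tf * (copies / 2 - 1)) * gcBias(gc) * librarySize`,
#' with negative-binomial noise. Controls (tf = 0) and unaltered arms have
#' copies = 2.
#'
#' @param truth One-row sample truth.
#' @param armStates data.frame arm_id / copies applying to cases.
#' @param bins Bin table with arm_id and gc.
#' @param binDepth,nbSize Depth scale and NB size parameter.
#' @return data.frame sample_id / chrom / start / end / gc / count.
#' @export
simulateBinCounts <- function(truth, armStates, bins, binDepth, nbSize) {
  unknown <- setdiff(armStates$arm_id, bins$arm_id)
  assertThat(length(unknown) == 0, "arm state refers to unknown arm(s): %s",
             paste(unknown, collapse = ", "))
  copies <- rep(2, nrow(bins))
  if (truth$label == "case" && nrow(armStates)) {
    idx <- match(bins$arm_id, armStates$arm_id)
    copies[!is.na(idx)] <- armStates$copies[idx[!is.na(idx)]]
  }
  lib <- rlnorm(1, 0, 0.1)
  mu <- binDepth * (1 + truth$tumor_fraction * (copies / 2 - 1)) *
    gcBiasCurve(bins$gc) * lib
  data.frame(sample_id = truth$sample_id, chrom = bins$chrom,
             start = bins$start, end = bins$end, gc = bins$gc,
             count = rnbinom(nrow(bins), mu = mu, size = nbSize))
}

.decoyGenes <- c("TTN", "OR4F5", "MUC16")

eligibleCall <- function(sid, gene, vafTarget, hotspotMissense) {
  depth <- 3000L + rpois(1, 1000)
  alt <- max(3L, rbinom(1, depth, max(vafTarget, 0.0015)))
  effect <- if (hotspotMissense) "missense" else
    sample(c("nonsense", "frameshift", "splice"), 1)
  data.frame(sample_id = sid, gene = gene,
             chrom = "chr17", pos = sample.int(2e6, 1) + 7.5e6,
             ref = sample(c("A", "C", "G", "T"), 1), alt = "T",
             effect_class = effect, vaf = alt / depth,
             alt_reads = alt, depth = depth,
             cosmic_count = 3L + rpois(1, 40),
             hotspot = hotspotMissense || runif(1) < 0.5)
}

decoyCall <- function(sid, panelGenes) {
  kind <- sample(c("synonymous", "low_cosmic", "off_panel", "low_vaf"), 1)
  depth <- 3000L + rpois(1, 1000)
  gene <- if (kind == "off_panel") sample(.decoyGenes, 1) else
    sample(panelGenes, 1)
  alt <- switch(kind, low_vaf = 1L, 4L + rpois(1, 10))
  data.frame(sample_id = sid, gene = gene,
             chrom = "chr5", pos = sample.int(2e6, 1) + 1.1e8,
             ref = "G", alt = "A",
             effect_class = switch(kind, synonymous = "synonymous",
                                   low_cosmic = "missense", "missense"),
             vaf = alt / depth, alt_reads = alt, depth = depth,
             cosmic_count = if (kind == "low_cosmic") rbinom(1, 2, 0.5)
                            else 3L + rpois(1, 10),
             hotspot = FALSE)
}

#' Simulate candidate mutation calls for one sample
#'
#' Cases acquire a filter-passing tumor mutation with probability
#' `1 - exp(-tf / tau)` (VAF around tf/2); both arms carry CHIP-like
#' filter-passing false positives at the background rate and a Poisson(2)
#' number of filter-failing decoys (synonymous calls, non-hotspot
#' low-COSMIC missense, off-panel genes, sub-threshold VAF).
#'
#' @param truth One-row sample truth.
#' @param geneWeights Named sampling weights over the gene panel.
#' @param config A [SimulationConfig-class].
#' @return data.frame in the candidate-call schema (possibly 0 rows).
#' @export
simulateMutations <- function(truth, geneWeights, config) {
  assertThat(length(geneWeights) > 0, "gene panel is empty")
  sid <- truth$sample_id
  calls <- list()
  if (truth$label == "case") {
    resp <- 1 - exp(-truth$tumor_fraction / config@mutationResponseScale)
    if (runif(1) < resp) {
      nMut <- 1L + rbinom(1, 1, 0.5)
      for (i in seq_len(nMut)) {
        gene <- sample(names(geneWeights), 1, prob = geneWeights)
        hot <- gene %in% c("TP53", "KRAS", "PIK3CA", "BRAF")
        calls[[length(calls) + 1]] <-
          eligibleCall(sid, gene, truth$tumor_fraction / 2, hot)
      }
    }
  }
  if (runif(1) < config@controlMutationFpRate) {
    gene <- sample(c("TP53", "KRAS"), 1, prob = c(0.7, 0.3))
    calls[[length(calls) + 1]] <-
      eligibleCall(sid, gene, rlnorm(1, log(0.004), 0.5), TRUE)
  }
  nDecoy <- rpois(1, 2)
  for (i in seq_len(nDecoy))
    calls[[length(calls) + 1]] <- decoyCall(sid, names(geneWeights))
  if (!length(calls))
    return(data.frame(sample_id = character(0), gene = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      effect_class = character(0), vaf = numeric(0),
                      alt_reads = integer(0), depth = integer(0),
                      cosmic_count = integer(0), hotspot = logical(0)))
  do.call(rbind, calls)
}

#' Generate a full synthetic cohort bundle
#'
#' Draws sample truths (labels, stages, tumor fractions) and all four
#' omics inputs. One global RNG stream is split per sample by stable
#' hashing of the sample id, so draws are byte-reproducible given
#' config + seed and adding samples never perturbs existing ones.
#'
#' @param config A [SimulationConfig-class].
#' @param cohortName Prefix of sample ids (e.g. "train", "val").
#' @param arms Arm definition table.
#' @return List: samples (sample sheet with tumor_fraction), methylation,
#'   fragments, bins, mutations (cohort-long tables), panel (ground
#'   truth), config, arms.
#' @export
simulateCohort <- function(config, cohortName = "train",
                           arms = armTable()) {
  validObject(config)
  panel <- syntheticPanel(config, arms)
  nC <- config@nCases; nH <- config@nControls
  stages <- withChildSeed(config@seed, paste0(cohortName, ":stages"),
    sample(names(config@stageProportions), nC, replace = TRUE,
           prob = config@stageProportions))
  samples <- rbind(
    data.frame(sample_id = sprintf("%s_case_%03d", cohortName, seq_len(nC)),
               label = "case", stage = stages),
    data.frame(sample_id = sprintf("%s_ctrl_%03d", cohortName, seq_len(nH)),
               label = "control", stage = "none"))
  perSample <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, , drop = FALSE]
    withChildSeed(config@seed, s$sample_id, {
      tf <- if (s$label == "case")
        min(1, rlnorm(1, config@tfMeanlog[[s$stage]],
                      config@tfSdlog[[s$stage]])) else 0
      truth <- cbind(s, tumor_fraction = tf)
      list(truth = truth,
           methylation = simulateMethylationCounts(
             truth, panel$methMarkers, config@methDepth),
           fragments = simulateFragmentMotifs(
             truth, panel$controlProfile, panel$tumorProfile,
             config@nFragments, panel$bins),
           bins = simulateBinCounts(truth, panel$armStates, panel$bins,
                                    config@binDepth, config@nbSize),
           mutations = simulateMutations(truth, panel$geneWeights, config))
    })
  })
  pull <- function(el) {
    tabs <- lapply(perSample, `[[`, el)
    data.table::rbindlist(tabs[vapply(tabs, nrow, 1L) > 0])
  }
  list(samples = as.data.frame(data.table::rbindlist(
         lapply(perSample, `[[`, "truth"))),
       methylation = as.data.frame(pull("methylation")),
       fragments = as.data.frame(pull("fragments")),
       bins = as.data.frame(pull("bins")),
       mutations = as.data.frame(pull("mutations")),
       panel = panel, config = config, arms = arms)
}

#' Write a cohort bundle to TSV files
#'
#' Emits samples.tsv, methylation.tsv, fragments.tsv, bins.tsv,
#' mutations.tsv into `dir`.
#'
#' @param cohort A [simulateCohort()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (el in c("samples", "methylation", "fragments", "bins", "mutations"))
    writeTsv(cohort[[el]], file.path(dir, paste0(el, ".tsv")))
  invisible(dir)
}

#' Read a cohort bundle written by [writeCohort()]
#'
#' @param dir Directory holding the TSVs.
#' @return List with samples/methylation/fragments/bins/mutations.
#' @export
readCohort <- function(dir) {
  out <- lapply(c(samples = "samples", methylation = "methylation",
                  fragments = "fragments", bins = "bins",
                  mutations = "mutations"),
                function(f) as.data.frame(readTsv(file.path(dir,
                                                            paste0(f, ".tsv")))))
  out
}
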