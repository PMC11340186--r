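#' All k-mer end motifs in lexicographic order
#'
#' @param k Motif length (default 4, giving 256 motifs).
#' @return Character vector of the `4^k` DNA k-mers.
#' @export
allMotifs <- function(k = 4) {
  b <- c("A", "C", "G", "T")
  out <- b
  if (k > 1) for (i in 2:k)
    out <- as.vector(t(outer(out, b, paste0)))
  sort(out)
}

#' 5' end-motif frequency vector of one sample
#'
#' Frequencies of each k-mer at cfDNA fragment 5' ends: the count of each
#' motif among fragments whose recorded motif is free of N, divided by the
#' total number of such usable fragments. N-containing motifs are excluded
#' from both numerator and denominator. The result is a probability vector
#' over all `4^k` motifs (exact zero for unobserved motifs).
#'
#' @param fragments data.frame of fragment records with a `motif5` column
#'   (chrom/start/end/strand tolerated and ignored here).
#' @param k Motif length; every N-free motif must have `nchar == k`.
#' @param minFragments Minimum usable fragments required (default 1;
#'   production profiles should use ~1000+).
#' @return Named numeric vector over `allMotifs(k)`, summing to 1.
#' @export
motifFrequencies <- function(fragments, k = 4, minFragments = 1) {
  motifs <- if (is.character(fragments)) fragments else {
    assertThat("motif5" %in% names(fragments),
               "fragment table needs a motif5 column")
    as.character(fragments[["motif5"]])
  }
  usable <- motifs[!grepl("N", motifs, fixed = TRUE)]
  assertThat(all(nchar(usable) == k),
             "motif5 entries must have length k = %d", k)
  assertThat(all(grepl("^[ACGT]+$", usable)),
             "motif5 must be over the alphabet A, C, G, T, N")
  if (length(usable) < max(1, minFragments))
    stopf("no usable fragments (found %d, need >= %d)",
          length(usable), max(1, minFragments))
  lev <- allMotifs(k)
  tab <- table(factor(usable, levels = lev))
  setNames(as.numeric(tab) / length(usable), lev)
}

#' Build the end-motif feature matrix
#'
#' One row per motif (all `4^k`), one column per sample; each sample's
#' column is its full frequency vector and sums to 1. Frequencies are
#' always defined when the per-sample computation succeeds, so there is no
#' imputation; a sample with zero usable fragments is a pipeline error
#' naming the sample.
#'
#' @param fragmentsBySample Named list of per-sample fragment tables, or a
#'   single table with a `sample_id` column.
#' @param sampleInfo Sample sheet.
#' @param k Motif length.
#' @param minFragments Per-sample usable-fragment floor.
#' @return A feature `SummarizedExperiment` (omics tag "endmotif").
#' @export
buildMotifMatrix <- function(fragmentsBySample, sampleInfo, k = 4,
                             minFragments = 1) {
  si <- as.data.frame(sampleInfo)
  if (!is.data.frame(fragmentsBySample)) {
    for (s in names(fragmentsBySample))
      fragmentsBySample[[s]]$sample_id <- s
    fragmentsBySample <- data.table::rbindlist(fragmentsBySample,
                                               fill = TRUE)
  }
  dt <- data.table::as.data.table(fragmentsBySample)
  assertThat(all(c("sample_id", "motif5") %in% names(dt)),
             "fragment table needs sample_id and motif5 columns")
  dt <- dt[!grepl("N", dt$motif5, fixed = TRUE)]
  umot <- unique(dt$motif5)
  assertThat(all(nchar(umot) == k),
             "motif5 entries must have length k = %d", k)
  assertThat(all(grepl("^[ACGT]+$", umot)),
             "motif5 must be over the alphabet A, C, G, T, N")
  usable <- dt[, list(n = .N), by = "sample_id"]
  perSample <- setNames(rep(0L, nrow(si)), si$sample_id)
  perSample[usable$sample_id[usable$sample_id %in% si$sample_id]] <-
    usable$n[usable$sample_id %in% si$sample_id]
  starved <- names(perSample)[perSample < max(1, minFragments)]
  assertThat(length(starved) == 0,
             "no usable fragments (or fewer than %d) for sample(s): %s",
             max(1, minFragments), paste(starved, collapse = ", "))
  lev <- allMotifs(k)
  counts <- dt[, list(n = .N), by = c("sample_id", "motif5")]
  m <- matrix(0, length(lev), nrow(si),
              dimnames = list(lev, si$sample_id))
  keep <- counts$sample_id %in% si$sample_id
  m[cbind(match(counts$motif5[keep], lev),
          match(counts$sample_id[keep], si$sample_id))] <- counts$n[keep]
  m <- sweep(m, 2, perSample, "/")
  featureMatrix(m, si, "endmotif")
}

#' Derive 5' end motifs from fragment coordinates and a reference FASTA
#'
#' For a plus-strand fragment the motif is the k reference bases starting
#' at `start`; for a minus-strand fragment it is the reverse complement of
#' the k bases ending at `end` (the fragment's physical 5' end on the
#' minus strand). Coordinates are 0-based half-open.
#'
#' @param fragments data.frame with chrom, start, end, strand.
#' @param fastaPath Path to the reference FASTA.
#' @param k Motif length.
#' @return The fragment table with a `motif5` column added.
#' @export
motifsFromFasta <- function(fragments, fastaPath, k = 4) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stopf("motifsFromFasta requires the Biostrings package")
  ref <- Biostrings::readDNAStringSet(fastaPath)
  names(ref) <- sub("\\s.*$", "", names(ref))
  fragments <- as.data.frame(fragments)
  assertThat(all(fragments$chrom %in% names(ref)),
             "chromosomes absent from FASTA: %s",
             paste(setdiff(fragments$chrom, names(ref)), collapse = ", "))
  assertThat(all(fragments$end - fragments$start >= k),
             "fragments shorter than k")
  plus <- fragments$strand != "-"
  from <- ifelse(plus, fragments$start + 1L, fragments$end - k + 1L)
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(fragments)),
    function(i) Biostrings::subseq(ref[[fragments$chrom[i]]],
                                   from[i], from[i] + k - 1L)))
  seqs[!plus] <- Biostrings::reverseComplement(seqs[!plus])
  fragments$motif5 <- as.character(seqs)
  fragments
}
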