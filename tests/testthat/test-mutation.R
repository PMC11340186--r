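eligibleFixture <- function() {
  data.frame(sample_id = "s1", gene = "TP53", chrom = "chr17",
             pos = 7577538, ref = "C", alt = "T",
             effect_class = "nonsense", vaf = 0.02, alt_reads = 10L,
             depth = 500L, cosmic_count = 50L, hotspot = FALSE)
}

test_that("the default filter passes a canonical driver call", {
  flt <- filterEligible(eligibleFixture())
  expect_true(flt$eligible)
  expect_equal(flt$reason, "pass")
})

test_that("synonymous calls are rejected as mutation_type", {
  call <- eligibleFixture()
  call$effect_class <- "synonymous"
  call$cosmic_count <- 1000L; call$hotspot <- TRUE
  flt <- filterEligible(call)
  expect_false(flt$eligible)
  expect_equal(flt$reason, "mutation_type")
})

test_that("rejection reasons follow the documented criterion order", {
  call <- eligibleFixture()
  call$gene <- "EGFR"; call$effect_class <- "synonymous"
  expect_equal(filterEligible(call)$reason, "gene_panel")
  call$gene <- "TP53"
  expect_equal(filterEligible(call)$reason, "mutation_type")
  call$effect_class <- "missense"; call$hotspot <- FALSE
  expect_equal(filterEligible(call)$reason, "hotspot_cosmic")
  call$hotspot <- TRUE
  call$vaf <- 0.0004; call$alt_reads <- 0L
  call$vaf <- call$alt_reads / call$depth  # keep consistency invariant
  expect_equal(filterEligible(call)$reason, "vaf")
  cfg <- mutationFilterConfig(minVaf = 0)
  expect_equal(filterEligible(call, cfg)$reason, "alt_reads")
})

test_that("filter decisions match the independent per-call oracle", {
  calls <- randomCalls(50, seed = 77)
  cfg <- mutationFilterConfig()
  flt <- filterEligible(calls, cfg)
  for (i in seq_len(nrow(calls)))
    expect_equal(flt$eligible[i], oracleEligible(calls[i, ], cfg),
                 info = paste("call", i))
})

test_that("relaxing any threshold never removes an eligible call", {
  calls <- randomCalls(50, seed = 42)
  base <- mutationFilterConfig()
  eligBase <- filterEligible(calls, base)$eligible
  relaxed <- list(
    mutationFilterConfig(minCosmicCount = 0),
    mutationFilterConfig(minVaf = 0),
    mutationFilterConfig(minAltReads = 0),
    mutationFilterConfig(requireHotspotForMissense = FALSE),
    mutationFilterConfig(allowedEffects = c("missense", "nonsense",
                                            "frameshift", "splice",
                                            "synonymous", "other")),
    mutationFilterConfig(genePanel = c("APC", "TP53", "KRAS", "PIK3CA",
                                       "FBXW7", "BRAF", "ACVR2A", "TTN",
                                       "EGFR")))
  for (cfg in relaxed) {
    elig <- filterEligible(calls, cfg)$eligible
    expect_true(all(elig[eligBase]))
  }
})

test_that("mutation score is the eligible-call indicator", {
  expect_equal(mutationScore(eligibleFixture()[0, ]), 0L)
  expect_equal(mutationScore(NULL), 0L)
  expect_equal(mutationScore(eligibleFixture()), 1L)
  rejected <- eligibleFixture()
  rejected$effect_class <- "synonymous"
  expect_equal(mutationScore(rejected[rep(1, 5), ]), 0L)
  # idempotence: duplicating an eligible call changes nothing
  expect_equal(mutationScore(eligibleFixture()[c(1, 1, 1), ]), 1L)
})

test_that("call validation enforces the schema invariants", {
  bad <- eligibleFixture(); bad$effect_class <- "weird"
  expect_error(filterEligible(bad), "effect_class")
  bad <- eligibleFixture(); bad$alt_reads <- 600L
  expect_error(filterEligible(bad), "exceeds depth")
  bad <- eligibleFixture(); bad$vaf <- 0.5
  expect_error(filterEligible(bad), "inconsistent")
})

test_that("gene detection table reproduces arm-level positivity", {
  si <- data.frame(sample_id = sprintf("c%03d", 1:10),
                   label = rep(c("case", "control"), c(6, 4)))
  calls <- do.call(rbind, lapply(c("c001", "c002", "c003"), function(s) {
    x <- eligibleFixture(); x$sample_id <- s; x
  }))
  calls$gene <- c("TP53", "TP53", "APC")
  tab <- geneDetectionTable(calls, si)
  expect_equal(tab$case_rate[tab$gene == "overall"], 3 / 6)
  expect_equal(tab$case_positive[tab$gene == "TP53"], 2)
  expect_equal(tab$case_positive[tab$gene == "APC"], 1)
  expect_equal(tab$control_rate[tab$gene == "overall"], 0)
  # per-gene positives sum >= overall (no co-mutation here: equality)
  perGene <- sum(tab$case_positive[tab$gene != "overall"])
  expect_gte(perGene, tab$case_positive[tab$gene == "overall"])
  empty <- geneDetectionTable(calls[0, ], si)
  expect_true(all(empty$case_rate == 0))
})

test_that("annotated VCF calls round-trip into the schema", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect\">",
    "##INFO=<ID=COSMIC_CNT,Number=1,Type=Integer,Description=\"n\">",
    "##INFO=<ID=HOTSPOT,Number=0,Type=Flag,Description=\"hs\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1",
    paste0("chr17\t7577538\t.\tC\tT\t.\tPASS\t",
           "GENE=TP53;EFFECT=missense;COSMIC_CNT=120;HOTSPOT\t",
           "AD:DP\t490,10:500"),
    paste0("chr5\t112175000\t.\tG\tA\t.\tPASS\t",
           "GENE=APC;EFFECT=nonsense;COSMIC_CNT=8\t",
           "AD:DP\t990,10:1000")), vcf)
  calls <- readMutationVcf(vcf, sampleId = "P1")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$gene, c("TP53", "APC"))
  expect_equal(calls$vaf, c(10 / 500, 10 / 1000))
  expect_equal(calls$hotspot, c(TRUE, FALSE))
  expect_true(all(filterEligible(calls)$eligible))
})
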