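# Shared fixtures and independent oracles used across the suite.

# Scaled-down simulation config for unit tests: small cohorts, shallow
# profiling, coarse 5-Mb bins. Statistical assertions at this scale use
# correspondingly loose tolerances.
smallConfig <- function(nCases = 12, nControls = 12, seed = 1, ...) {
  simulationConfig(nCases = nCases, nControls = nControls,
                   nFragments = 1500, methDepth = 300,
                   binSize = 5e6, seed = seed, ...)
}

# Minimal sample sheet for matrix-builder tests.
sheet <- function(ids, labels = rep(c("case", "control"),
                                    length.out = length(ids)),
                  stages = NULL) {
  data.frame(sample_id = ids, label = labels,
             stage = stages %||% ifelse(labels == "case", "II", "none"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force AUC oracle: pairwise concordance with ties counted 1/2.
pairwiseAuc <- function(scores, labels) {
  cs <- scores[labels == "case"]; ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# Independent per-call re-evaluation of the mutation eligibility
# predicate (no vectorization, no shared code with the package filter).
oracleEligible <- function(call, cfg) {
  if (!(call$gene %in% cfg@genePanel)) return(FALSE)
  if (!(call$effect_class %in% cfg@allowedEffects)) return(FALSE)
  rec <- isTRUE(call$hotspot) || call$cosmic_count >= cfg@minCosmicCount
  if (cfg@requireHotspotForMissense && call$effect_class == "missense" &&
      !isTRUE(call$hotspot)) rec <- FALSE
  if (!rec) return(FALSE)
  if (call$vaf < cfg@minVaf) return(FALSE)
  if (call$alt_reads < cfg@minAltReads) return(FALSE)
  TRUE
}

# Random candidate-call table exercising every filter branch.
randomCalls <- function(n, seed) {
  set.seed(seed)
  depth <- 2000L + rpois(n, 500)
  alt <- rbinom(n, depth, runif(n, 0.0002, 0.05))
  data.frame(
    sample_id = sprintf("s%02d", sample.int(8, n, replace = TRUE)),
    gene = sample(c("APC", "TP53", "KRAS", "FBXW7", "TTN", "EGFR"), n,
                  replace = TRUE),
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
    effect_class = sample(c("missense", "nonsense", "frameshift",
                            "splice", "synonymous", "other"), n,
                          replace = TRUE),
    vaf = alt / depth, alt_reads = alt, depth = depth,
    cosmic_count = rpois(n, 4),
    hotspot = runif(n) < 0.4)
}

# Independent ridge-IRLS oracle: same statistical definition, separate
# code path (explicit loop, qr.solve). Intercept unpenalized.
oracleRidgeLogistic <- function(X, y, lambda, iters = 200, tol = 1e-12) {
  X1 <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X1))
  D <- diag(c(0, rep(lambda, ncol(X1) - 1)))
  for (i in seq_len(iters)) {
    eta <- as.vector(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- diag(pmax(mu * (1 - mu), 1e-10))
    g <- t(X1) %*% (y - mu) - D %*% beta
    H <- t(X1) %*% W %*% X1 + D
    step <- qr.solve(H, g)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Exhaustive Youden-cutoff oracle over observed score thresholds.
oracleYouden <- function(probs, labels) {
  cand <- sort(unique(probs))
  best <- -Inf; bestC <- cand[1]
  for (c in cand) {
    sens <- mean(probs[labels == "case"] >= c)
    spec <- mean(probs[labels == "control"] < c)
    if (sens + spec - 1 > best + 1e-15) {
      best <- sens + spec - 1; bestC <- c
    }
  }
  bestC
}
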