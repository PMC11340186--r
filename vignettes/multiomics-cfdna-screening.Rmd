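---
title: "Stacked multiomics cfDNA classification: model, simulator and design notes"
author: "cfdnaStack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked multiomics cfDNA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The screening problem

Plasma cell-free DNA (cfDNA) in a cancer patient is a mixture: most
fragments derive from normal (largely hematopoietic) cells, and a small
fraction — the *tumor fraction* (tf) — from tumor cells. Every
tumor-derived signal in cfDNA scales with tf, which in early-stage
disease is often below a few percent. No single modality is reliable in
that regime, which motivates profiling several orthogonal signal types
from one blood draw and combining them:

* **Targeted DNA methylation.** For a panel of CpG markers
  hypermethylated in tumor tissue, the methylation level (beta) at a
  marker is
  $\beta = m / (m + u)$, the number of methylated molecules over all
  methylated plus unmethylated molecules observed there.
* **5' end motifs.** The first $k=4$ bases of each fragment's 5' end
  reflect the nuclease and chromatin context of its release; the
  per-sample feature is the frequency vector over all $4^k = 256$
  motifs, which shifts subtly in cancer.
* **Arm-level copy number.** Shallow WGS read counts in fixed genomic
  bins, GC-corrected and normalized to a panel of normals, summarized
  per chromosome arm as a log2 ratio. A clonal single-copy gain at
  tumor fraction tf shifts an arm by
  $\log_2\!\big(1 + \mathrm{tf}\,(c/2 - 1)\big)$ (e.g.
  $\log_2 1.1 \approx 0.1375$ at $c=3$, tf = 0.2).
* **Mutations.** Candidate somatic calls in a colorectal driver panel
  are passed through a stringent eligibility filter (effect class,
  hotspot/COSMIC recurrence, VAF and alt-read floors); the per-sample
  *mutation score* is the binary indicator of at least one eligible
  call.

# The stacked classifier

Marker selection runs on the training cohort only: a two-sided Wilcoxon
rank-sum test per feature with Benjamini–Hochberg correction
(adjusted p < 0.05 retained), followed for methylation and end motifs by
random-forest importance ranking (mean decrease in Gini impurity, fixed
forest seed, lexicographic tie-break) down to per-omics target counts
(defaults 23 methylation markers, 14 motifs, 34 arms). The CNV path uses
the univariate filter alone.

Each omics then gets a logistic sub-model on z-standardized selected
features, fit by IRLS with a small ridge penalty on the slopes
($\lambda = 10^{-4} n$, intercept unpenalized) so that complete
separation cannot diverge. With a stratified 10-fold partition, each
training sample receives an out-of-fold (OOF) probability: fold models
re-estimate standardization and coefficients on the other nine folds.
Selection is performed once on the full training cohort by default —
mirroring the usual select-then-model sequence and keeping the selected
panel interpretable — and the residual optimistic bias of that choice is
acknowledged; `nestedSelection = TRUE` re-runs selection inside every
fold instead.

The integrated model is a logistic regression on four inputs: the three
OOF sub-model probabilities plus the mutation score. Training on OOF
values (never resubstitution values) is what makes the stack honest; the
test suite includes a regression test showing that stacking on
resubstitution probabilities inflates training AUC on pure noise.
Integrated OOF probabilities are computed with the same partition for
training-cohort evaluation. Decision cutoffs default to the Youden
maximizer (sensitivity + specificity − 1) over the observed OOF
probabilities, ties broken toward the smallest cutoff; a
specificity-floor alternative is available.

Validation cohorts are processed with training-frozen state only:
selected features, imputation medians, the panel of normals, the
standardization statistics, coefficients and cutoffs all come from the
fitted bundle, which serializes to a single JSON document.

Evaluation uses the rank-statistic AUC (Mann–Whitney, ties ½) with
DeLong or stratified-bootstrap confidence intervals, exact
Clopper–Pearson intervals for sensitivity/specificity, per-stage
sensitivity over cases only, and a single-marker threshold evaluator for
comparisons against conventional protein markers (CEA-style).
Percentages in reports are rounded half-up to one decimal.

# The synthetic cohort generator

Real cfDNA multiomics cohorts for this problem are controlled-access, so
the package ships a generator that reproduces the statistical structure
the classifier assumes, and the whole pipeline is exercised end-to-end
on it.

Each case draws a stage from the configured stage mix and a tumor
fraction from a stage-specific log-normal; controls have tf = 0.
Signals follow the simplest count models with the right support:

| Component | Model | Default |
|---|---|---|
| cohort sizes | two arms, training + validation | 93/96 and 89/95 |
| stage mix I–IV | multinomial | 17.2/39.8/38.7/2.2% (renormalized) |
| tumor fraction | log-normal per stage, clamped to [0,1] | medians 1/2/4/10%, sdlog 0.6 |
| methylation | total ~ Poisson(depth); methylated ~ Binomial(total, clamp(baseline + tf·effect)) | 30 markers (25 informative), depth 800, baselines U(0.005, 0.03), effects U(0.07, 0.28) |
| end motifs | multinomial from (1−tf)·control + tf·tumor profile | 12,000 fragments, 20 enriched motifs, 8-fold enrichment |
| bin counts | NB(mean = depth·(1 + tf(c/2−1))·gcBias·libSize) | 1-Mb bins, depth 200/bin, size 50, 12 altered arms (classic gains 7/8q/13q/20, losses 1p/4q/8p/17p/18) |
| mutations | case true positive with prob 1 − exp(−tf/τ); CHIP-like background false positives in both arms; filter-failing decoys | τ = 0.0633, background 9.4% |

The tumor-fraction medians, depths and effect sizes are not empirical
constants; they were fixed once so that the default cohort reproduces
the qualitative behavior expected of this assay class — sub-model AUC
ordering methylation > end motif > CNV > mutation, an integrated model
that dominates every single omics, and expected mutation positivity of
about 42% in cases versus 9.4% in controls (the response scale τ solves
that expectation in closed form given the stage mix, with the CHIP-like
background applied identically to both arms so a zero-tf cohort is
exchangeable between arms). Eligible tumor mutations are drawn to pass
the default filter (VAF ≈ tf/2 with floors), so the detection curve —
not call-level attrition — controls positivity.

One global RNG stream is split per sample by a stable hash of the
sample id: cohorts are byte-reproducible given config + seed, and
enlarging a cohort never perturbs existing samples. The marker-panel
ground truth (baselines, effects, profiles, altered arms, bin GC) is
drawn from a separate panel seed shared between cohorts, so a model
trained on one cohort transfers to another.

**What the generator does not emulate** — and hence what green tests do
*not* establish about clinical data: batch and assay drift, age/sex
confounding, fragment-length structure, correlated marker panels,
realistic CHIP mutation spectra, sequencing error profiles, or
subclonal copy-number architecture. Passing the suite demonstrates that
the statistical machinery is correct and honest (no leakage, calibrated
under the null), not that any particular clinical operating point is
achievable. In particular, stage-I sensitivity under the conservative
1% median tumor fraction assumed here runs well below the headline
numbers clinical studies report.

# Numerical and design notes

* **Coverage floor.** Methylation levels from fewer than 10 molecules
  are treated as missing; targeted panels are deep, so the floor costs
  little and stabilizes the ratio. Missing entries are imputed with
  per-marker training medians, which are frozen into the model — the
  validation cohort never contributes to its own imputation.
* **End motifs.** Motifs containing N are excluded from numerator and
  denominator rather than redistributed. Each fragment record
  contributes exactly one motif (its recorded 5' motif); counting both
  physical ends of a duplex fragment requires two records, keeping the
  record format strand-explicit.
* **GC correction.** Counts are divided by a rolling-median
  (window 3) curve over GC deciles, linearly interpolated; it is scale-
  free and needs no parametric bias model. Arm summaries are
  length-weighted bin means after per-sample median centering, which
  assumes under half the genome is altered — a documented limitation for
  extreme aneuploidy. Acrocentric short arms (13p, 14p, 15p, 21p, 22p)
  are excluded from the default arm table. A transparent log-ratio
  pipeline deliberately replaces HMM-based copy-number callers here:
  only arm-level features enter the model, and tumor-fraction
  estimation is out of scope.
* **Mutation filter order.** Criteria are evaluated in a fixed order
  (gene panel, effect class, hotspot/COSMIC, VAF, alt reads) and each
  rejected call carries the first failing criterion, so diagnostics are
  deterministic. Thresholds are assumptions, not published constants,
  and everything is configurable.
* **IRLS.** Convergence is declared at a coefficient change below
  1e-10; with the default ridge the normal equations are always
  well-posed. Setting λ = 0 recovers the ML fit where it exists.
* **Cross-validation.** Folds are stratified and dealt round-robin
  after a seeded shuffle, so per-fold class counts differ by at most
  one from proportionality.
* **Determinism.** Every stochastic step (simulation, forest, folds,
  bootstrap) derives its seed from a named child of the run seed;
  identical configs produce byte-identical model bundles and metrics.
  Timing goes to the run log, never into deterministic artifacts.

# Problem sizes in the test suite

Unit tests run on miniature cohorts (tens of samples, ~1,500 fragments,
5-Mb bins) with correspondingly loose statistical tolerances; the
end-to-end property suites use the default study conditions (189
training / 184 validation samples) across 20 seeds, and null-calibration
checks use 100 + 100 samples per cohort. These sizes are the package's
choice of desk-scale conditions: large enough for the assertions'
tolerances, small enough to iterate on.

# Limitations

* The simplified CNV pipeline reports relative arm-level log2 ratios
  only — no segmentation, absolute copy states or tumor-fraction
  estimates.
* Median imputation and full-cohort selection are pragmatic defaults;
  nested selection is available but slower.
* The generator's independence assumptions (markers conditionally
  independent given tf) make marker selection easier than on real,
  correlated panels; retained-marker counts on synthetic data are
  targets, not guarantees.
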