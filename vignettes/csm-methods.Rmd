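---
title: "Inferring cell-subset specific methylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-subset specific methylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmeth)
```

## The problem

Single-cell bisulfite sequencing (scBS-seq) reads out CpG methylation one
cell and one molecule at a time, but with shallow, patchy coverage. Within
a seemingly homogeneous cell population, some loci are methylated in one
subset of cells and unmethylated in another — cell-subset specific
methylation (CSM). Two within-cell phenomena mimic that bipolar signal and
must be excluded first: allele-specific methylation (ASM, the two parental
alleles differ) and asymmetric or hemi-methylation (AM, the two strands of
one molecule differ, visible directly in hairpin bisulfite data and as
discordant full-length read patterns within one cell). `csmeth` implements
the full inference chain: read-level pattern extraction, ASM/AM exclusion,
candidate-region construction, an empirical-Bayes beta-binomial two-state
mixture model with a likelihood-ratio test, a random-effects estimator of
cell-to-cell methylation variance, a simulation/assessment harness, and
downstream co-methylation and genomic-feature characterization.

## From reads to candidate regions

The unit of pattern analysis is the **4-CpG segment**: every run of four
consecutive CpG sites observed on a single read (sliding, so a read with
c CpGs yields c − 3 windows). Minus-strand calls are shifted to the
forward-strand C of the dyad so both strands pool into one site; hairpin
reads keep their strand and pair identity because AM detection must not
pool strands. Only autosomes are analysed by default.

Candidate construction then follows four deterministic steps:

1. **ASM exclusion.** A segment is dropped when any of its four CpG
   positions falls inside an annotated ASM interval. We use position
   membership rather than span overlap because ASM annotations are
   CpG-resolved.
2. **AM exclusion.** A segment is AM when a hairpin read pair shows
   `1111` on one strand and `0000` on the mate, or when a single cell
   carries both a fully methylated and a fully unmethylated read.
3. **Bipolar seeds.** A remaining segment is a CSM seed when one cell has
   a `1111` read and a *different* cell a `0000` read.
4. **Extension, merging, coverage.** Segment spans are widened by 100 bp,
   transitively overlapping spans are unioned (overlap means sharing at
   least one base; merely touching intervals stay separate), merged
   regions containing at least one seed become candidates, and a region
   is kept when at least 5 cells each contribute at least 10 CpG
   observations. "10 cytosine counts" is read as the per-cell total of
   site-level observations (reads × covered CpGs), the same counts the
   beta-binomial layer models. Site counts are rebuilt from *all* reads
   overlapping a merged region, not only from 4-CpG windows. A control
   universe is built identically from all ASM-filtered segments without
   the seed requirement, so every candidate is contained in a control
   region.

## The empirical-Bayes beta-binomial layer

Within region r, cell i, the methylated count at CpG j is
m_j ~ Binomial(n_j, theta) with theta ~ Beta(alpha, beta). Conjugacy
gives the posterior Beta(sum m + alpha, sum n − sum m + beta) whose mean
and variance feed everything downstream. The prior is estimated by the
method of moments on observed group levels e = m/n, reparameterized by
the mean mu and precision M = alpha + beta, with the correction term
mu(1 − mu)/c · sum(1/n) over the c replicate groups. When the moment
estimate of M is zero, negative or non-finite — one group, identical
levels, or under-dispersion — the flat Beta(1, 1) prior is used. Missing
sites enter with zero counts and therefore do not perturb the moments.

**Replicate groups are cells, not sites, by default.** The precision
formula averages the reciprocal *cell totals* 1/sum_j n_ji across cells,
which identifies the cells of a region as the replicate groups: one prior
per region, estimated from the cells' pooled levels and shared by all
cells (`pool = "cells"`). The alternative reading — each cell gets its
own prior from its handful of sites (`pool = "sites"`) — is implemented
behind the `pool` flag but is not the default, for a calibration reason
we verified by simulation: a per-cell prior with precision M ≈ 25
estimated from only 4 sites injects large spurious between-cell
heterogeneity, and the two-state test then rejects ~23% of truly
single-state regions at nominal 5%. With the shared per-region prior the
test is conservative (empirical rejection ≈ 0) and state recovery is
accurate. Both conventions keep the same downstream interfaces.

## The two-state beta mixture model

Cells in a candidate region are modelled as a mixture of K = 2 latent
methylation states. Writing a_i = sum m_i + alpha_i and
b_i = sum n_i − sum m_i + beta_i, the component density of cell i at
state probability theta is

Pr(i | theta) = Γ(a_i) Γ(b_i) / Γ(a_i + b_i) ·
theta^(a_i − 1) (1 − theta)^(b_i − 1),

and the likelihood is ∏_i ∑_k lambda_k Pr(i | theta_k). EM alternates
the membership E-step with M-step updates lambda_k = mean membership and
theta_k = ∑_i g_ik (a_i − 1) / ∑_i g_ik (a_i + b_i − 2) — the
posterior-mode offsets (−1, −2) are kept exactly as the model defines
them, with negative numerators clamped at 1e-6 and theta clamped to
[1e-6, 1 − 1e-6]. States are relabelled so theta1 ≥ theta2.

Numerical choices (the model statement is silent on all of them):

* **Initialization.** One symmetric start (all memberships ½ — the
  one-state fixed point, which guarantees the fitted likelihood never
  falls below the nested null), one median split of the posterior means,
  and `restarts − 1` uniform random membership draws; default
  `restarts = 10`. Restart randomness is seeded per region id so scans
  are reproducible and independent of region order.
* **Convergence.** |Δ log-likelihood| < 1e-6, at most 500 iterations.
* **Degeneracy.** An empty state (total membership < 1e-6) flags the fit.

The one-state null has the closed-form maximizer
theta = ∑(a − 1) / ∑(a + b − 2); the LRT statistic 2(l2 − l1) is referred
to chi-squared with 2 df (3 free parameters vs 1). Mixture LRT regularity
fails on the boundary, so this reference is conservative here (verified:
empirical null rejection ≈ 0.001 after BH at nominal 0.05); a parametric
bootstrap reference is available via `lrt(fit, method = "bootstrap")`.
P-values are BH-adjusted across regions, and a region is called CSM when
the adjusted p-value is below 0.05, theta1 − theta2 ≥ 0.3, and at least
8 cells carried data. The observed between-group level difference is
reported alongside and can optionally serve as an extra screen
(`use_delta_min`), but does not gate calls by default. K > 2 is out of
scope: the model targets bimodal states.

## Cell-to-cell methylation variance

Each cell's posterior mean theta_i (variance V_i) is treated as a noisy
observation of an abstract region-level methylation probability with a
between-cell variance component Delta². The model is resolved
non-iteratively with the DerSimonian–Laird moment estimator:
Q = ∑ w_i (theta_i − mu_FE)² with w = 1/V, Delta² = max(0, (Q − (N−1)) /
(∑w − ∑w²/∑w)), adjusted weights w* = 1/(V + Delta²), mu = weighted mean
and V̂ = 1/∑w*. Truncation of Delta² at 0 is standard practice. The 95%
confidence interval of V̂ comes from 1000 bootstrap resamples; the
resampling unit is the cell and the interval is the percentile interval
(the source states only the resample count), deterministic under a seed.

## What the simulation harness emulates — and what it does not

`simulate_region()` draws cell states with probability lambda, per-site
depths Poisson(mean depth) — depth 0 is the missing-data mechanism — and
methylated counts Binomial(n, theta_state); an extra independent masking
rate is available for stress tests (off by default). Defaults are 20
cells, 4 sites, mean depth 20, lambda and theta uniform on [0, 1].

`make_synthetic_methylome()` writes read-level data with planted CSM
(default theta 0.8/0.2 across two cell subsets), ASM (heterozygous
alleles near 1 and 0), AM (within-cell fully methylated and fully
unmethylated molecules, plus matching hairpin pairs) and null loci (one
shared level per locus), 4-CpG windows 1 kb apart on one synthetic
chromosome, Poisson(15) reads per cell and locus. Molecules within one
cell are kept epigenetically coherent: a cell never carries both a fully
methylated and a fully unmethylated molecule unless the locus is planted
as AM. Without that constraint, independent per-site coin flips at
intermediate levels would stamp the AM signature onto a large fraction
of null and CSM loci — a sequencing-noise artifact, not a property of
real methylomes, where molecules from the same allele are highly
concordant.

The generator does **not** emulate: non-uniform genomic CpG spacing,
coverage biases and read-length variation, bisulfite conversion errors,
correlated missingness across neighbouring sites, or chromosome-scale
methylation domains. Passing the end-to-end tests therefore demonstrates
the correctness of the filtering/merging logic and the calibration and
power of the statistical layer under the stated generative model, not
performance on any particular real data set.

## Assessment conditions and estimands

The assessment harness reports estimator accuracy under the rule that an
estimate is accurate when it is within 1e-2 of its true value, and
classification quality as FDR/TPR/FPR/PPV. Three conditions deserve
explicit statement, since the model description leaves them open:

* **The mixing-proportion estimand.** At N = 20 cells the realized
  fraction of cells in the hyper state — not the sampled parameter
  lambda — is what any estimator can identify; |realized − parameter|
  alone has standard deviation ≈ 0.11. Recovery is therefore measured
  against the realized fraction for lambda, and against the set
  parameter values for theta. The theta of a state that no cell realized
  carries no information and is excluded from the accuracy rule.
* **Balanced design for recovery runs.** The parameter-recovery and
  accuracy-curve runs fix lambda = 0.5 so both states are populated;
  with lambda uniform, ~10% of 20-cell regions realize an empty or
  single-cell state whose theta is unidentifiable or noise-bound, which
  measures the design, not the estimator.
* **Depth for the accuracy curve.** The 1e-2 accuracy rule is
  informative only when the estimator's sampling standard deviation
  sqrt(theta(1−theta)/(cells-per-state · sites · depth)) is below 1e-2.
  The per-region recovery benchmark uses the pipeline's own conditions
  (4 sites, mean depth 20), where that floor is ≈ 0.013 — hence its
  companion criteria are "within 0.05" and the median pooled parameter
  error. The accuracy-versus-difference *curve* instead uses mean depth
  500 (floor ≈ 0.0035), where accuracy saturates once the states
  separate and the curve exhibits its characteristic rise-then-plateau
  shape, stable from a state difference of ≈ 0.3 — the basis of the 0.3
  calling cutoff.

Problem sizes used by the acceptance checks: 100 posterior-conjugacy
draws against a 10⁴-point grid oracle; 500 recovery replicates; 1,000
replicates per 0.05-wide difference bin for the curve; 600 replicates
for the difference correlation; 1,000 single-state regions for null
calibration; one synthetic methylome with 50/20/20/200 planted
CSM/ASM/AM/null loci; 1,000 random segment sets against an O(n²) merge
oracle; 100 random-effects fixtures against an independent
meta-analysis implementation at 1e-10. Harness fits use 3 random
restarts on top of the two deterministic initializations, which is ample
for these separations; the pipeline default remains 10.

## Downstream characterization

Across-sample co-methylation modules are found by Pearson correlation of
region methylation profiles (rows with missing values or zero variance
dropped), average-linkage hierarchical clustering on 1 − r, and a tree
cut at r = 0.75; linkage is exposed because only the cutoff is part of
the method's definition. Feature enrichment is the fraction of CSM
regions overlapping a feature set (≥ 1 bp) divided by the same fraction
for control regions; promoters are 1 kb upstream of the TSS, CGI shores
the 2 kb flanking an island, shelves the further 2–4 kb. Histone-peak
profiles scale each peak to 100 bins and count, per bin, the frequency
of regions overlapping it. Sequence features are GC content and the CpG
observed/expected ratio #CG · L / (#C · #G).

## Known limitations

* The chi-squared df = 2 reference is conservative for this mixture
  test; power at small effect sizes is correspondingly reduced. The
  bootstrap reference trades runtime for calibration.
* The per-region shared prior assumes cells are exchangeable a priori
  within a region; systematic per-cell conversion differences would
  violate this.
* Delta-squared truncation at zero biases the variance estimator upward
  near the boundary, a standard property of DL-type estimators.
* Hairpin AM detection requires exact 4-CpG coordinate agreement between
  mates; partially overlapping pairs are ignored.
* Upstream read processing (trimming, alignment, deduplication,
  contamination removal) is out of scope; inputs are read-level
  methylation calls.
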