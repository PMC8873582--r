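---
title: "Multi-omics molecular subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics molecular subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

momsub reconstructs a complete tumor-subtyping workflow from matched bulk
profiles: gene expression (log2 fold change against normal tissue),
segmented DNA copy number, 450K-style DNA methylation beta values, somatic
mutations and overall survival. This vignette documents the statistical
models, every tunable parameter that matters, the synthetic cohort the
package tests itself against, and the places where the design was genuinely
open and a choice had to be made.

## The analysis in one paragraph

Transcriptional dysregulation in tumors has two major cis-acting drivers:
copy-number dosage (more copies, more transcript) and promoter
hypermethylation (silencing). The workflow identifies genes whose expression
tracks their own copy number (CNVcor, positive correlation) or their own
methylation (METcor, negative correlation), keeps those that also carry
survival information, clusters samples on each feature set by NMF consensus,
then fits one joint latent-variable model across all three layers to produce
integrated subtypes, and finally characterizes the subtypes by survival,
categorical omics differentials and mutation enrichment.

## Data model

An `omics_layer` is a features-by-samples numeric matrix tagged with its
kind (`EXP`, `CNV`, `MET`) and a `centered` flag (tumor minus normal-tissue
mean). Two conventions matter and are enforced rather than assumed:

* Methylation has two scales. Raw beta values live in [0, 1] and are what
  the hyper/hypomethylation thresholds (0.8 / 0.2) apply to. Correlation
  and clustering use centered M-values (`log2(beta / (1 - beta))` minus the
  normal-tissue mean), where effects are additive. Supplying the wrong
  scale to `call_aberrations()` is an error, not a warning.
* Copy-number thresholds (gain > 0.3, loss < -0.3, strict inequalities)
  apply to log2 segment ratios, a different scale from the methylation
  cutoffs despite the similar numbers.

Segment-to-gene mapping is the length-weighted mean of overlapping segment
means (1-based inclusive coordinates; a dialect flag handles 0-based
half-open input). Probes map to genes through a manifest; when a gene has
several probes, the representative is the probe with the smallest (most
negative) correlation with that gene's expression (`min_r`, default) or the
probe closest to the per-gene mean correlation (`mean_r`). Missingness
filtering removes features with strictly more than 30% missing values
(configurable; 50% is the conventional cross-platform merge threshold), and
the remaining gaps are filled by k-nearest-neighbor imputation over
features (k = 10, Euclidean distance over jointly observed samples, row-mean
fallback with a warning when neighbors run out).

## CNVcor and METcor genes

Per gene, Pearson r between expression and the other layer across samples;
Fisher Z = atanh(r) stabilizes the variance so the two distributions can be
compared by their skewness (adjusted Fisher-Pearson G1 with the D'Agostino
test). Planted dosage effects push the EXP~CNV z-distribution right;
silencing pushes EXP~MET left. Selection takes r > 0 (CNVcor) or r < 0
(METcor) at p < 0.05 (t-test on n - 2 df, unadjusted by default to match
the simple per-gene screening style; a BH mode exists), optionally
intersected with a per-gene log-rank filter: samples split at the gene's
median expression, two-group log-rank p < 0.05. The median split is a
design choice — the grouping was genuinely open — because it is the most
reproducible dichotomization; a tertile variant is available. r is clamped
to +/-(1 - 1e-15) before atanh so perfect correlations stay finite.

## NMF consensus subtyping

Centered expression of the selected genes is made nonnegative by the
standard pos/neg row split (each row x becomes max(x,0) and max(-x,0)), then
factorized by multiplicative KL-divergence (Brunet) updates, implemented in
C++ with the objective recorded every iteration — the updates guarantee a
non-increasing objective, and the tests assert it. Consensus clustering
runs 50 random restarts (uniform random initializations from a seeded
generator), takes hard labels per run by the maximal H entry (ties to the
lowest index), and averages co-membership indicators into a consensus
matrix C. Final labels cut an average-linkage dendrogram of 1 - C at k; the
cophenetic correlation between 1 - C and the dendrogram's ultrametric
distances scores the stability of each k in 2..10, with the smallest
maximizing k chosen (exact ties broken by mean silhouette width computed on
1 - C). Per-run iteration caps (default 2000, tolerance 1e-6) matter only
for speed; hard labels stabilize long before the objective does, which is
why the analysis drivers can run with a cap of 200.

## Integrative clustering

The joint model stacks the standardized layers: X_t = W_t Z + eps_t per
layer t, with shared latent factors Z ~ N(0, I) of dimension k - 1,
diagonal noise Psi_t, and an elementwise lasso penalty lambda on the
loadings. EM is exact in the E-step; the penalized M-step for each loading
row is solved by coordinate descent (closed-form soft threshold per
coordinate). This is a deliberate strengthening over the classical
shortcut of soft-thresholding the unpenalized update: with an exact
(or merely improving) M-step, the penalized observed-data objective is
provably non-decreasing across EM iterations, and the package treats any
violation as a bug, not noise. Initialization is spectral — latent
directions start at the top left singular vectors, restarts differing by a
random rotation plus jitter — because from a near-zero random start the
lasso threshold can truncate all loadings before any signal accumulates.
Labels come from seeded k-means (10 restarts) on the latent posterior
means; the best of 20 EM restarts by penalized objective is returned.
`lambda = 0.2` on the standardized scale is the default; the model-selection
helper scores each k by the mean pairwise adjusted Rand index across
restart labelings (ties to the higher objective).

## The synthetic cohort

Every stage is validated against a generator whose defaults are the study
conditions: 300 samples, 2000 genes, three equally mixed subtypes.

* Aberrations are planted on contiguous 25-gene blocks. Each aberrant
  block carries one of the six sign patterns over the three subtypes
  (permutations of (+s, 0, -s)), each pattern equally often — 30 CNV blocks
  (s = 0.45 log2 units) and 24 methylation blocks (s = 1.2 M units),
  disjoint. The balance means every subtype has exactly the same expected
  gain/loss and hyper/hypo load, so subtype identity alone cannot couple
  aberration frequencies; the disjointness gives every planted gene a
  single causal layer.
* Dosage: 15% of genes get expression a * c with a = 3.75 and noise
  sd 1.0. By the attenuation formula r = a sigma_c / sqrt(a^2 sigma_c^2 +
  sigma_e^2), an unshifted dosage gene (sigma_c = 0.2) sits at r ~ 0.6.
* Silencing: a disjoint 15% get expression -b * m with b = 0.8 on the
  M-value scale (per-gene baselines ~ N(0, 1.8), noise sd 0.6), keeping
  beta in (0, 1) by construction.
* Instability: each sample draws u ~ |N(0, 0.8)| and its planted aberration
  shifts scale by (1 + u). Scaling only the aberration component — not the
  methylation baseline — is deliberate: a scaled baseline would act as a
  global latent factor with loadings proportional to the baselines, and it
  measurably consumes one latent dimension of the integrative model
  (leaving too few for three subtypes). With the aberration-only scaling,
  all four per-sample aberration frequencies rise with u, which is what
  produces the positive coupling among all six frequency pairs; setting
  sigma_inst = 0 severs it. Calibration note: because gain and loss calls
  are mutually exclusive per gene, their frequencies carry a negative
  binomial covariance that cancels weak coupling — the CNV noise
  (sigma_cnv = 0.2) and shift (0.45, near the 0.3 calling threshold) were
  chosen so the instability-driven variance dominates.
* Survival: exponential per subtype with rates 1/1500, 1/950, 1/600 per
  day (worst/best hazard ratio 2.5) and uniform censoring on (0, 4000)
  days. The truth object marks as "survival-linked" the planted genes in
  blocks with opposite shifts in the best- and worst-hazard subtypes:
  with a hazard ratio of 2.5 diluted through a median split, only such
  full-contrast genes give the per-gene log-rank filter usable power, so
  recovery rates are evaluated over that set.
* Mutations: a 30-gene panel, Bernoulli rates 0.05 everywhere except 10
  genes at 0.4 in subtype 1 — the configuration the mutation-differential
  power checks assume.
* Probes: one probe per gene plus a second for 30% of genes (probe noise
  sd 0.3), with region-class and gene-relation annotations drawn from
  realistic proportions, so the representative-probe and CpG-breakdown
  code paths are exercised.

What the generator does not emulate: array-level intensities, batch
effects, tumor purity, copy-number breakpoints within genes (segments are
reconstructed per gene), or any correlation between mutations and the
continuous layers beyond subtype membership. Passing tests on this cohort
therefore demonstrate the machinery recovers planted structure under
realistic effect sizes — not that real tumor data are this clean.

A note on evaluating false discoveries: with instability coupling, a
silenced gene's expression can genuinely correlate with copy number through
shared amplitude variation (and a dosage gene's with methylation), so such
genes have no well-defined null status in the other layer's screen.
Recovery metrics count a false discovery only for definite-null genes
(neither dosage nor silenced).

## Numerical choices and degenerate inputs

* NMF divisions are guarded by 1e-16; KL terms with V = 0 contribute WH.
* Noise variances in the integrative model are floored at 1e-6; a fit whose
  loadings are entirely zeroed (huge lambda) is flagged degenerate and
  labeled as a single cluster rather than erroring.
* Consensus matrices that are exactly constant (perfect separation) define
  cophenetic correlation as 1.
* Zero-variance rows are excluded from correlation with a log; constant
  expression in the tertile analysis falls back to rank assignment and
  reports p = 1; heavy ties that empty a tertile trigger the same fallback.
* Fisher tests on category tables use full enumeration up to total 200 and
  seeded Monte-Carlo (1e5 tables) beyond; 2x2 mutation tests are always
  exact. Chi-square tests of independence use no continuity correction.
* All randomness flows from explicit seeds; the pipeline derives per-stage
  seeds from one global seed (seed + 100 * stage index) so stages are
  independently reproducible, and two runs with the same configuration
  produce byte-identical tables.

## Problem sizes in the shipped drivers and tests

The analysis drivers run the full 300 x 2000 cohort with 20 NMF restarts
per k (the package default is 50, used in the recovery checks at a
200-iteration cap); model selection in the driver scans k = 2..10. The
test-suite recovery simulations use the default cohort for single-cohort
checks and a reduced 150 x 600 replica (same planted design) for the
20-seed model-selection sweep. These sizes are the package's choice of a
thorough-but-quick default; all of them are configuration, not constants.

## Known limitations

* The exponential survival model has no covariates; hazard links to genes
  only through subtype membership.
* The integrative model is Gaussian in every layer; mutation data enter
  characterization only, not the joint fit.
* The survival filter's median dichotomization is low-powered for effects
  concentrated in a middle subtype (by design of the test conditions, only
  extreme-contrast genes pass reliably); the driver output shows the
  consequence — survival-filtered METcor features can prefer two classes
  where the unfiltered set cleanly shows three.
* Consensus NMF scales as restarts x iterations x matrix size; the C++
  core keeps the default conditions to roughly a minute per feature set,
  but genome-scale feature sets (tens of thousands of rows) would need
  subsetting first.
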