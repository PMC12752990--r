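---
title: "Methods: from methylation counts to held-out disease prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from methylation counts to held-out disease prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrpredict)
```

# Scope and model

`dmrpredict` implements a blood WGBS case/control analysis chain for
cohorts of a few dozen individuals: coverage filtering, variance
attribution (PCA/PVCA), covariate-adjusted per-CpG differential
methylation testing with a permutation-null false-positive filter,
merging of differentially methylated cytosines (DMCs) into regions
(DMRs), subtraction of treatment-confounded regions and censoring of the
X chromosome, k-means clustering of region methylation, gene mapping
with hypergeometric term enrichment, and two tracks of predictive
modelling evaluated strictly on a held-out split.

The motivating application is canine gastrointestinal lymphoma detection
from whole blood, but every stage is generic case/control WGBS
methodology.

## The per-CpG test

At each CpG the data are per-sample pairs (methylated reads, total
reads). We model the methylated count as binomial with a logit-linear
mean:

$$\mathrm{logit}\, p_i = \beta_0 + \beta_g\, \mathrm{group}_i +
  \gamma^\top z_i$$

where $z_i$ are covariates (by default breed, one-hot with levels seen
in fewer than two training samples pooled into `other`, and age in
years, centred). The group term is tested by a likelihood-ratio
chi-square with one degree of freedom. This is the standard
count-regression test for bisulfite data. Three consequences matter:

* **No overdispersion correction is applied by default.** Per-CpG
  biological variability between individuals makes the binomial test
  anti-conservative; the pipeline compensates *downstream*, with the
  effect-size cutoff (|difference| > 10 percentage points), the
  permutation-null filter, and the region-level member rule. This layered
  design is deliberate: the final unit of inference is the region, not
  the CpG.
* **Covariate adjustment costs power when covariates align with the
  contrast.** In a cohort where most case breeds do not occur among
  controls, breed indicators absorb a large share of the case samples,
  and the conditional group effect is estimated from the breed-sharing
  remainder. This is the honest price of confounder adjustment in small
  cohorts and is visible in the synthetic experiments below.
* A degenerate or separated fit yields $p = 1$ with a convergence flag
  rather than an error, so a genome-wide scan never aborts on a corner
  case.

The effect size reported alongside (`meth_diff`) is the difference of
unweighted per-sample mean beta values (case minus control), in
percentage points — deliberately *marginal*, matching how average
methylation differences are usually quoted, while the p-value is
conditional on covariates.

The scan is implemented in C++ (IRLS per site, shared design matrix).
The reduced, covariate-only model does not depend on the case/control
labels, so the permutation filter fits it once and caches its per-site
log-likelihood across all label permutations.

## The permutation-null filter

Case/control labels are shuffled (covariates stay attached to their
samples), the *entire* DMC call — including Benjamini–Hochberg
adjustment — is re-run per permutation, and every original candidate's
recurrences are counted. A candidate detected **more than once** across
100 permutations is removed (`max_hits = 1`, both configurable). The
filter is monotone in `max_hits` and bit-reproducible given a seed.
Candidates driven by a single extreme sample are its main victims: the
outlier travels with whichever pseudo-group receives it, so such sites
keep recurring under permuted labels.

## From DMCs to DMRs

Retained DMCs within 100 bp of their neighbour (inclusive) chain into
one region; chains with at least 6 members become DMRs (the "more than
5" rule). Region span runs from the first to the last member DMC, with
no flank. Direction is the majority sign of member effects, ties
resolved by the summed effect and then toward hypomethylation.

Confounder (steroid) regions are called by the same machinery with the
steroid flag as the contrast, **no** covariates, and a looser member
rule (at least 4), then any candidate sharing at least one base with a
confounder region is removed. X-chromosome candidates are censored last.
The order — test, filter, merge, subtract, censor — mirrors standard
practice: censoring applies to final candidates, not to the site-level
test.

## Variance attribution (PVCA)

`run_pvca()` retains principal components until their cumulative
variance reaches 0.6, fits each retained PC's scores with a
random-intercept model per factor (main effects only; `lme4` backs the
fits), and averages the per-PC variance fractions with eigenvalue
weights. Continuous age is binned to whole years so it can act as a
grouping factor, matching how PVCA treats continuous covariates.
Single-level factors contribute zero with a warning. This module is the
package's own implementation of the PVCA procedure on top of `lme4`.

## Predictive models

Feature values are per-region mean beta values (`region_beta`),
unweighted across member CpGs. All selection and fitting uses training
samples only; the held-out split is touched exactly once, at
evaluation, and a leakage guard hard-errors on any train/test overlap.

**Single-region track.** One logistic regression per region
(`label ~ mean beta`). Preliminary ranking uses 1,000 class-stratified
bootstrap resamples (cases resampled among cases, controls among
controls, so AU-ROC is always defined); the model is refit on each
resample and scored in-bag, and regions are ranked by mean bootstrap
AU-ROC with 2.5/97.5 percentile intervals. An interval over identical
bootstrap AUCs — typical for perfectly separating regions in small
cohorts — is printed as `(-, -)`. Out-of-bag scoring exists behind a
flag; in-bag is the default because the screening step is a ranking
device, not an estimate of generalisation.

**Sparse multi-probe track.** L0+L2-penalised logistic regression:

$$\min_{\beta_0, \beta}\ \frac1n \sum_i \log\bigl(1 +
  e^{-\tilde y_i(\beta_0 + x_i^\top\beta)}\bigr) +
  \lambda \lVert\beta\rVert_0 + \gamma \lVert\beta\rVert_2^2$$

with $\gamma$ fixed at 0.001 and $\lambda$ chosen by 4-fold
class-stratified cross-validation over a 50-point geometric grid
descending four decades from $\lambda_{\max}$ (the smallest penalty with
empty support). The solver is cyclic coordinate descent with
hard-threshold updates (majorisation constants $L_j = \tfrac14
\overline{x_j^2}$), exact ridge refits on the active support, and local
swap refinement: candidate one-for-one exchanges are screened by their
one-coordinate majorisation gain and the best few are evaluated by exact
refit. On 10-feature instances the solver's penalised objective matches
an exhaustive best-subset-with-ridge search to $10^{-6}$ (asserted in
the test suite); the objective is non-increasing across sweeps by the
majorisation argument, also asserted.

**Tree + forest track.** Region methylation is clustered by k-means
(k = 4 by default; the elbow curve over k = 2..10 is advisory, computed
with nested restarts so WCSS is non-increasing). One depth-2
classification tree (Gini) is fit per cluster using only that cluster's
regions; regions used at any split are selected — typically one or two
per cluster. Their union feeds a 500-tree random forest whose predicted
probability is the fraction of trees voting case. Depth 2 bounds each
cluster's contribution at three regions; clusters where no split
improves impurity contribute nothing, with a warning. A `--quota` on
the total selection is deliberately absent: the count is emergent.

## Metrics

`auroc()` is the Mann–Whitney statistic (ties one half, computed from
midranks); `auprc()` is average precision — the step-function integral
of the precision-recall curve with ties entering as threshold groups and
no interpolation, which avoids the optimism of trapezoidal PR areas.
With all-equal scores average precision equals the prevalence, which is
the honest "no information" reference under class imbalance (the default
test split holds 4 cases among 11 samples). Both agree exactly with
brute-force oracles (all-pairs concordance; per-positive precision sums)
on randomized instances in the test suite.

# The synthetic cohort generator

Real cohorts of this design are not redistributable, so `sim_config()` /
`simulate_cohort()` generate cohorts with known truth that every stage
is tested against. What it emulates, and the defaults:

* **Cohort shape:** 20 cases vs 19 controls; hold-out split 16+12
  training / 4+7 test (explicit per-group counts take precedence over
  the ~0.72 fraction).
* **Coverage:** negative binomial, mean 70 reads per CpG (the design
  target of the emulated study), shape 8 — a long right tail justifying
  the 500x upper filter.
* **Baseline methylation:** a bimodal Beta mixture, 70% of CpGs in a
  methylated mode (Beta(8, 1.5), mean 0.84) and 30% in an unmethylated
  mode (Beta(1.5, 8)) — the standard bimodal landscape of vertebrate
  methylomes.
* **Counts:** beta-binomial with concentration 150, i.e. a
  between-individual standard deviation of about 0.03 at intermediate
  methylation — the stability typical of most CpGs in whole blood of
  healthy individuals.
* **Planted regions:** 50 disease regions of 6 guaranteed CpGs spaced
  50 bp, effect 0.10 by default (0.15 in the power experiments), 80%
  hypomethylated in cases; 10 steroid-responsive regions (effect 0.15 —
  corticosteroids shift leukocyte composition strongly, so the
  confounder is simulated as at least as strong as the disease signal).
  Effects are injected on the logit scale and clipped to [0.01, 0.99].
  A region's effect applies to **every** simulated CpG inside its span,
  not only the guaranteed members — a differentially methylated region
  is a domain, and background CpGs falling inside it shift with it.
  Hypomethylated regions draw their baseline from the methylated mixture
  component (and vice versa), reflecting that disease-associated
  hypomethylation starts from a methylated state; member CpGs share the
  region baseline up to a small logit jitter, mirroring the strong local
  correlation of real methylomes.
* **Covariates:** ages Normal(10.2, 2.02) for cases and
  Normal(7.79, 3.66) for controls, truncated at 1 year; breeds drawn as
  a faithful multiset of the emulated demographics (controls dominated
  by a few breeds, cases spread over ~15, sampled without replacement so
  rare breeds stay rare); steroid treatment in 40% of cases and 10% of
  controls; two collection settings (70/30). A sex effect of +0.15 for
  females applies to chrX only; small age (logit slope 0.02/year on 10%
  of CpGs) and breed (sd 0.3 logit on 5% of CpGs) effects provide
  realistic nuisance structure. Disease and steroid regions are planted
  on autosomes only, since X candidates are censored downstream by
  design.

What it does **not** emulate: read-level data (no FASTQ, no
bisulfite-conversion error), non-CpG contexts, long-range co-methylation
beyond the planted regions, cell-composition shifts (for dogs no
reference methylomes per cell type exist), and CpG-island clustering of
background sites (spacing is uniform at roughly one CpG per 150 bp).
Passing tests therefore demonstrate the statistical machinery under a
faithful noise model, not performance on any real cohort.

## What the synthetic experiments show

Problem sizes were chosen to exercise the full chain at desk scale:
20,000 CpGs, 28 training samples, 100 permutations.

* **Specificity:** on null cohorts (no planted effect), the chain
  produces a handful of DMC candidates per 20,000 sites and essentially
  never assembles six of them within 100 bp: the mean final region
  count over ten seeds is 0.
* **Sensitivity:** with 50 planted regions at a 0.15 effect, about
  85–90% of truth regions are recovered by a final DMR on typical
  seeds. Recovery is limited almost entirely by the all-members rule
  interacting with breed-confounded power: a region whose six guaranteed
  CpGs include one that misses the 10-point or q < 0.05 cut is lost
  whole. Seeds whose breed draw confounds harder recover less — a
  faithful reflection of the cohort design, not an implementation
  artifact.
* **Prediction:** with the same planted strength, both multi-probe
  models reach mean held-out AU-ROC above 0.9 across seeds; the test
  split has 11 samples, so individual-seed AUCs move in steps of 1/28.

# Numerical choices and degenerate inputs

* Internal coordinates are 1-based inclusive everywhere; only BED I/O
  converts to 0-based half-open. Region ids print as
  `chrom:start-end` (1-based inclusive).
* `total = 0` means "not observed" and is never imputed; `compute_beta`
  refuses unfiltered matrices instead of emitting NAs.
* Sites constant across samples are dropped before PCA (unit-variance
  scaling is undefined for them).
* IRLS caps coefficients at ±30 on the logit scale; quasi-separated
  sites plateau instead of diverging, and a non-finite likelihood is
  flagged and reported as $p = 1$.
* k-means restarts share derived seeds; the elbow scan additionally
  seeds k from the k−1 solution plus the farthest point, making the
  WCSS curve non-increasing by construction. Cluster labels are
  renumbered by descending size for stable reporting.
* Empty-input corners (no DMCs, empty region sets, empty truth) produce
  empty outputs of the right shape, not errors; zero-length BED files
  are valid.
* All randomness flows through per-stage seeds derived from one master
  seed; reruns with the same config reproduce byte-identical output
  files (md5-checksummed in the run manifest).

# Design decisions on open points

* "Within 100 bp" is read as inter-DMC distance ≤ 100 inclusive;
  "more than 5" and "more than three" as ≥ 6 and ≥ 4. All three are
  parameters.
* Whether permutation re-calls adjust for covariates is configurable
  (`perm_covariates`), default on, matching the primary call.
* Subtraction uses any-base overlap with no reciprocal-fraction
  requirement — conservative removal of anything touching a confounded
  region.
* Promoters are upstream-only, strand-aware, TSS-exclusive windows of
  1,500 bp; adjacency is nearest-gene distance ≤ 10 kb with lexical
  tie-breaking (all ties behind a flag).
* The bootstrap screen resamples within class and scores in-bag; the
  paper-gap alternatives (unstratified, out-of-bag) are flags.
* CpG sites can be destranded on import (`destrand = TRUE`), but the
  default keeps sites as called, since caller behaviour varies.

# Limitations

Power statements above are specific to the simulated noise model;
real blood WGBS adds cell-composition variation that this package
neither simulates nor deconvolves. The per-CpG test's anti-conservatism
under overdispersion is managed, not removed — interpret single-CpG
q-values only through the region-level rules. Enrichment consumes a
flat gene-to-term map and performs no ontology propagation. With ~30
training samples, perfect training AU-ROCs are expected by chance for
some regions; the held-out evaluation, not the training table, is the
performance claim.
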