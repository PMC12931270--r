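---
title: "Methods: compositional co-occurrence networks and ordinal outcome modelling"
author: "AirwayNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional co-occurrence networks and ordinal outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

AirwayNet implements a pipeline linking the architecture of microbial
co-occurrence networks in the preterm lower airway to an ordinal disease
grade (none, I, II, III of increasing severity of bronchopulmonary
dysplasia). The stages are: ASV count-table preprocessing, alpha/beta
diversity statistics with permutation inference, compositionally robust
correlation inference (SparCC), per-group network construction with
topology profiling and keystone-taxon scoring, permutation-based network
comparison, and a proportional-odds model relating network metrics to the
grade. A synthetic cohort generator with planted basis-correlation
structure makes every stage testable without access to clinical sequencing
data.

The package is organised Bioconductor-style: the central container
`AmpliconExperiment` extends `SummarizedExperiment` (taxa as rows, samples
as columns; taxonomy in `rowData`, sample metadata in `colData`), and
`runPipeline()` orchestrates the stages end-to-end. There is no shell
subcommand binary: the exported functions, `runPipeline()` and the scripts
directory are the interface, which is how analysis packages in this
ecosystem are normally driven.

# Preprocessing

Three filters, applied in this order by the pipeline:

1. **Singletons** — taxa whose grand total count is exactly 1 are removed
   (sequencing-artifact guard).
2. **Organelles** — taxa whose lineage contains "mitochondria" or
   "chloroplast" as a case-insensitive substring at any rank are removed.
   The rule is a substring match on the lineage text, so a hypothetical
   genus that merely resembles the words is retained unless it actually
   contains them.
3. **Abundance/prevalence** — for network analysis, a taxon is retained
   only if its share of the table grand total exceeds 0.01 % (strict
   inequality) *and* it is present in at least `ceiling(0.05 * n)` samples
   (for 98 samples: 5). The abundance clause is interpreted as taxon total
   over grand total; a per-sample-mean variant is available via
   `abundanceMode = "sample_mean"` because the grand-total reading is
   scale-free and matches the 0.01 % magnitude, but the convention is not
   universal.

Rarefaction (`rarefyCounts()`, default depth 22,000) subsamples each
sample without replacement to a common depth before diversity analysis;
samples below the target are dropped with a warning rather than kept
unrarefied, which only matters for synthetic edge cases since realistic
depths exceed the target. The three filters are idempotent, and rarefied
tables have constant column sums by construction.

# Diversity statistics

Alpha diversity reports Chao1, Shannon, Simpson and Good's coverage.
Chao1 uses the bias-corrected form S + F1(F1-1)/(2(F2+1)), which is
defined even when no doubletons are present; the classical F1^2/(2 F2)
form is available by flag. Simpson is reported as the complement 1 - sum
p_i^2 (the common convention in this literature) with the raw
concentration also emitted, since published figures rarely state which was
plotted. Beta diversity uses Bray-Curtis dissimilarity with ANOSIM
(pairwise Bonferroni), PERMANOVA and PERMDISP; these standard tests are
delegated to vegan behind the module surface, with seeds threaded through
so results are reproducible. All permutation p-values use the add-one
estimator (1 + hits)/(permutations + 1), so p is never exactly zero.
Because rank-based effect-size conventions differ, `kruskalEffectSize()`
returns both eta-squared and epsilon-squared and asserts neither against
any published value.

# SparCC correlation inference

Counts are compositional: only relative information survives sequencing,
and naive correlations on relative abundances are distorted by closure
(with exactly two taxa the relative abundances are perfectly
anti-correlated regardless of the truth). SparCC estimates correlations
between latent *basis* abundances from log-ratio variances
T_ij = Var(log(x_i/x_j)), which are invariant to per-sample scaling.

Under the sparsity approximation (most pairs uncorrelated), the basis
variances omega solve M omega = t with t the row sums of T and M the
matrix with D-1 on the diagonal and 1 elsewhere; then
rho_ij = (omega_i + omega_j - T_ij) / (2 sqrt(omega_i omega_j)), clipped
to [-1, 1]. The strongest pair exceeding the exclusion threshold (default
0.1, the original convention) is iteratively removed from the row sums and
the system re-solved, up to 10 rounds. The kernel is implemented in
C++ (RcppArmadillo): the initial M has a closed-form inverse and each pair
exclusion is a rank-1 downdate, so M^-1 is maintained by Sherman-Morrison
with no repeated linear solves; a pure-R direct-solve reference
implementation backs the unit tests. Non-positive basis-variance estimates
are clamped to 1e-6 with a warning. At least 4 taxa are required — below
that the sparsity approximation is unidentifiable.

The full estimator (`sparccCorrelation()`) repeats this over `nOuter = 20`
outer iterations, each drawing per-sample fractions from
Dirichlet(counts + 1) (prior pseudocount 1 by default, 0.5 selectable),
and returns the element-wise median — which always lies in the convex hull
of the per-iteration estimates.

## Edge significance

`edgeSignificance()` offers two resampling modes:

- **permutation** (default): every taxon's counts are shuffled across
  samples independently, the correlation matrix is re-estimated, and
  p_ij = (1 + #{|r_resample| >= |r_obs|}) / (n + 1). This is a proper
  null: its type-I error at nominal 0.05 is verified by simulation in the
  acceptance suite.
- **bootstrap**: samples are resampled with replacement and p scores
  two-sided sign instability. Bootstrap resampling measures stability
  rather than a null distribution, so the permutation mode is the
  default; the bootstrap mode exists because some published workflows
  phrase edge significance this way.

Each resample re-estimates SparCC with `nOuterResample = 5` outer
iterations by default (configurable up to the full 20); this keeps the
default pipeline — 100 resamples for each of four groups at roughly 280
filtered taxa — in the minutes range on a single core without changing the
estimator's structure. Benjamini-Hochberg adjustment of the p matrix is
available but off by default. Note the add-one floor: with n resamples no
p-value can fall below 1/(n+1), so n must exceed 19 for any edge to pass
alpha = 0.05.

# Networks, topology and keystones

`buildNetwork()` retains edge (i, j) iff |r_ij| > threshold (default 0.3,
strict) and p_ij < alpha (default 0.05); isolated nodes are dropped, so
reported node counts are connected vertices — consistent with published
group networks whose node counts vary well below the filtered taxon count.
Before inference, `downsampleGroups()` reduces every grade to the smallest
group's size (16 in the emulated design) so edge support is comparable
across groups.

`networkTopology()` reports node/edge counts, average degree (2E/N),
density, average path length and diameter (over connected pairs only;
a `dissimilarity_weighted` mode uses edge length 1 - |r|, since published
sub-1 "path length" values are impossible for hop counts — no quantitative
claim is tied to that convention), global transitivity (with mean-local
also emitted, as tables rarely say which "clustering coefficient" they
print), Louvain modularity (seeded; determinism verified), Freeman
centralizations (degree uses the (N-1)(N-2) star maximum; closeness and
betweenness use igraph's Freeman forms; for disconnected graphs closeness
follows igraph's reachable-set convention, and eigenvector centralization
follows igraph's normalization), degree assortativity and mean nearest
neighbour degree. Path metrics are validated against a Floyd-Warshall
brute-force oracle, and centralizations vanish on vertex-transitive graphs
as they must.

Keystone taxa display high degree, high closeness, high local
transitivity and low betweenness. Each measure is z-scored within the
network and combined with non-negative weights (equal by default — the
differential weighting used in published work is not recoverable, so the
package requires weights to be explicit and reports them); the top
`ceiling(0.10 N)` nodes are flagged, ties broken by higher degree then
lexicographic identifier. `thresholdSensitivity()` rebuilds networks at
|r| > 0.2/0.3/0.4 and reports topology plus keystone-set Jaccard overlap
across thresholds.

# Network comparison

`permuteCompare()` tests topology-metric differences between two groups:
the null pools both groups' samples, re-splits at the original sizes, and
rebuilds both networks per permutation (default 1,000 permutations;
p-values add-one). Full fidelity inside the loop is prohibitive, so the
loop defaults to 5 outer SparCC iterations and no per-edge significance
resampling (threshold-only construction); both are configurable for a
full-fidelity run. When only count-based metrics (nodes, edges, density,
average degree) are requested the loop skips graph construction entirely.
Permutations in which a metric is undefined (an empty network) are
excluded from that metric's count rather than imputed.

`jaccardCentral()` compares the sets of most-central nodes (above the 0.75
quantile of each network's own centrality distribution, the convention of
the comparison framework this mirrors) with hypergeometric tail
probabilities over the union of node universes. `methodAgreement()`
reports edge counts and edge-set Jaccard between two correlation methods
at identical thresholds — the SparCC-versus-Spearman contrast.

`networkDissimilarity()` implements a D-measure combining (i) the
Jensen-Shannon divergence between mean node-distance distributions, (ii)
the difference in network node dispersion (within-graph heterogeneity of
node-distance distributions normalized by log(diameter + 1)), and (iii)
alpha-centrality profile divergence of the graphs and their complements,
with weights 0.45/0.45/0.10. It is non-negative, symmetric and zero on
identical graphs; the triangle inequality is not asserted. A z-scored
Euclidean distance on topology vectors is a simpler selectable
alternative.

# Ordinal outcome model

`fitProportionalOdds()` maximizes the cumulative-logit likelihood
logit P(Y <= k) = theta_k - x'beta by damped Newton iterations on the
analytic gradient (Hessian by central differences of that gradient), with
step halving whenever a step would decrease the likelihood, break the
cutpoint ordering, or leave the finite domain. Convergence requires
gradient max-norm below 1e-8 within 100 iterations. Wald standard errors
come from the observed information; a reciprocal condition number below
1e-10 flags singularity, and a perfectly predicted outcome (complete
separation) flags non-convergence rather than erroring. Under this
parameterization a positive coefficient — odds ratio above 1 — means
higher odds of a *more severe* grade; this sign convention matters when
reading protective effects (OR < 1). The fitter agrees with an
independent implementation (MASS::polr) to 5-6 significant digits in the
test suite, reduces exactly to binary logistic regression with two
outcome levels, and attains near-nominal Wald coverage in simulation.

`forwardStepwise()` adds candidate covariates one at a time in a supplied
order of clinical priority (default order: gender, gestational age, birth
weight, delivery mode, antibiotic type, antenatal corticosteroids,
meconium-stained fluid, extrauterine growth restriction, intrauterine
distress, length of stay). Gating is on *stability*, not significance: a
candidate causing singular information or non-convergence is recorded as
dropped and skipped; an optional p-value entry gate exists but is off by
default. Because a group-level network metric is not naturally an
individual-level regressor, `sampleNetworkMetrics()` offers two explicit
assignment modes — `"group"` (every sample gets its group network's
metric) and `"loo"` (the group network is recomputed leaving the sample
out) — asserting neither as canonical.

# Synthetic cohort generator

`generateCohort()` emulates the study design the analysis assumes:

- group sizes 31/31/20/16 across the four grades (98 samples);
- per-sample depths uniform on [22,026, 72,630];
- 300 taxa by default (configurable; the desk-scale default keeps runtime
  in minutes while preserving the structure), of which a handful (5) are
  boosted on the log scale to dominate the community, 8 carry
  mitochondrial or chloroplast lineages, and 10 are singletons whose one
  read is carved from an abundant taxon so row sums still equal the drawn
  depths exactly;
- log-normal basis abundances: per sample, exp of a multivariate normal
  whose correlation matrix carries the group's planted blocks (identity
  elsewhere); fractions are the closure of the basis; counts are
  multinomial at the drawn depth. This is the generative model SparCC
  itself assumes, making recovery tests interpretable;
  Dirichlet-multinomial overdispersion is available by flag;
- planted blocks default to densest structure in grade II and a collapsed
  (3-taxon, rho 0.4) structure in grade III, mirroring the reported
  direction of network-density collapse with severity; the true effect
  size is unknown, so it is a free parameter rather than an asserted
  value;
- covariate means linear in grade rank (gestational age 30.6 weeks minus
  0.9 per grade, birth weight 1500 g minus 150 per grade, longer stays at
  higher grades), the simplest structure supporting outcome-model
  recovery tests.

`generateNullCohort()` is the matching no-correlation calibration fixture,
optionally with one taxon given an expected 80 % share to exercise the
closure artifact. With all planted correlations zero the two generators
are distributionally equivalent (checked by Kolmogorov-Smirnov in the
tests).

What the generator does *not* emulate: read-level errors, chimeras,
taxonomic mis-assignment, batch effects, or zero-inflation beyond what
multinomial sampling of log-normal compositions produces. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to every failure mode of real amplicon
data.

# Numerical choices and problem sizes

- Add-one permutation p-values everywhere; seeds thread from a master
  seed through named per-stage sub-seeds, so any stage can be re-run
  reproducibly in isolation and two runs of `runPipeline()` with the same
  configuration are bit-identical (manifest checksums verify this).
- Keystone ties break deterministically (degree, then identifier); the
  eigenvector solver and Louvain both run under fixed seeds.
- Validation battery sizes (chosen to exercise each property on a single
  core in minutes): SparCC recovery at D = 30, n = 200 over 20 seeds;
  null ceiling at D = 50, n = 200; suppression at D = 25 with an 80 %
  dominant taxon over 10 seeds; calibration with 200-resample tests over
  100 replicate null cohorts (D = 10); ordinal coverage at n = 500 over
  100 seeds; determinism on the full default cohort with a reduced
  comparison-permutation count (20), since determinism does not depend on
  the number of permutations.

# Limitations

- SparCC's sparsity approximation biases estimates when many strong true
  correlations exist; the exclusion heuristic mitigates but does not
  remove this.
- With 16 samples per group and hundreds of taxa, noise correlations
  exceeding |r| = 0.3 are common; the significance filter controls the
  error *rate*, not the absolute number of noise edges, so group networks
  at this scale remain noisy — a property shared by the study design this
  emulates, and the reason down-sampling to equal group sizes matters.
- The proportional-odds model assumes common slopes across cumulative
  logits (no formal proportionality test is included).
- Group-level network metrics used as individual-level predictors are a
  modelling convenience; both assignment modes are approximations.
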