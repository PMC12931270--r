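# AirwayNet

Co-occurrence network analysis of the neonatal airway microbiome across
ordinal disease severity.

## The problem

Bronchopulmonary dysplasia (BPD), the most common chronic lung disease of
very preterm infants, is graded ordinally (none, I, II, III). Beyond
asking *which* taxa differ with severity, an ecological view asks whether
the *architecture* of the microbial community — who co-occurs with whom —
changes as disease worsens. Answering that from 16S amplicon counts
requires care: sequencing counts are compositional (only relative
information survives), so naive correlations between relative abundances
are distorted by the closure constraint, and network summaries need
permutation inference rather than parametric tests.

AirwayNet is for microbial-ecology analysts who want that full chain as
tested, reusable R code: count-table preprocessing, diversity statistics,
compositionally robust correlation inference, per-group network topology
and keystone-taxon scoring, permutation-based network comparison, and an
ordinal outcome model — plus a synthetic cohort generator so every stage
is verifiable without clinical data.

## The core methods

**SparCC correlations.** For taxa i, j with latent basis abundances x_i,
x_j, the log-ratio variances T_ij = Var(log(x_i/x_j)) are invariant to
per-sample totals. Under a sparsity assumption the basis variances ω
solve M ω = t (t the row sums of T; M has D−1 on the diagonal, 1
elsewhere) and

    ρ_ij = (ω_i + ω_j − T_ij) / (2 √(ω_i ω_j)),

with iterative exclusion of strongly correlated pairs and re-solution.
The estimator repeats over 20 Dirichlet-resampled outer iterations and
takes the element-wise median; edge significance comes from permutation
resampling with the add-one estimator p = (1 + hits)/(n + 1). Networks
keep edges with |r| > 0.3 and p < 0.05.

**Keystone score.** Within each network, degree, closeness, local
transitivity and betweenness are z-scored and combined as
w₁z(deg) + w₂z(clo) + w₃z(trans) − w₄z(betw); the top 10 % of nodes are
keystones.

**Ordinal model.** Proportional odds, logit P(Y ≤ k) = θ_k − x'β, fitted
by damped Newton iterations with forward stepwise covariate entry gated
on numerical stability (singular-information candidates are dropped, not
forced). OR = exp(β) > 1 means higher odds of more severe disease.

## Worked example

```r
library(AirwayNet)

res <- runPipeline(
  "results/run1",
  synthetic = cohortConfig(),              # 98 samples, 4 grades, 300 taxa
  params = pipelineParams(comparePermutations = 20L, nResamples = 25L),
  seed = 77)

res$topology[, c("group", "nodes", "edges", "density", "modularity")]
#>   group nodes edges    density modularity
#> 1   non   282  1488 0.03755584  0.3494576
#> 2     I   282  1471 0.03712678  0.3614120
#> 3    II   282  1468 0.03705106  0.3664286
#> 4   III   282  1440 0.03634436  0.3596827

res$methodAgreement
#>   group sparcc_edges spearman_edges   jaccard
#> 1   non         1488           1687 0.1878040
#> 2     I         1471           1502 0.2336100
#> 3    II         1468           1492 0.2146081
#> 4   III         1440           1504 0.1856625
```

Each row of `topology` profiles one grade's co-occurrence network after
down-sampling every grade to the smallest group size: `density` is
E/(N(N−1)/2) and `modularity` the seeded Louvain partition quality. With
16 samples per group and ~280 filtered taxa, networks are noise-dominated
(the |r| > 0.3, p < 0.05 filter controls the error *rate*, not the count
of noise edges), so the four groups look similar here; planted-structure
recovery is demonstrated at more favourable sample sizes in the test
suite. `methodAgreement` contrasts SparCC with naive Spearman networks at
identical thresholds: Spearman consistently admits more edges, and the
edge sets overlap only partially (Jaccard well below 1) — the
compositional artifact the SparCC estimator exists to avoid. The run
directory contains per-stage TSV/GraphML artifacts and a `manifest.json`
with parameter and checksum records; rerunning with the same seed
reproduces it bit-for-bit.

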