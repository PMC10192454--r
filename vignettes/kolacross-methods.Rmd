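---
title: "Methods: compatibility, heterosis and cross characterisation in kola trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compatibility, heterosis and cross characterisation in kola trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kolacross)
```

## The problem

Kola (*Cola nitida*) expresses sporophytic self-incompatibility (SI): the
pollen's incompatibility phenotype is set by the diploid genotype of the
pollen-producing tree, and pollinations fail when pollen-parent and stigma
phenotypes share an S-specificity. In orchard terms this means selfs and
many genotype combinations set few or no pods, and breeders must identify
compatible partners and self-compatible lines. The standard field assay is
controlled pollination: a fixed number of flowers is hand-pollinated per
cross (here 20, replicated by 3 pollinators), and pods, pseudo-pods
(unfertilised fruit-like structures) and dropped flowers are counted some
weeks later. This package implements the complete analysis of such trials,
from pedigree-label parsing to heterosis and multivariate characterisation,
plus a simulator that generates trials with known truth.

## Compatibility quantification

Pod set is the percentage of pollinated flowers setting true pods;
pseudo-pod set the analogous percentage of pseudo-pods. Both are undefined
(not zero) when no flowers were pollinated. Crosses are classed on the
0–5 scale: 0 for exactly zero pod set, then 20-point bands up to 100 %.
The printed form of the scale ("1–20 %", "21–40 %", ...) leaves values such
as 20.5 unassigned; we close each band on the right —
class *k* covers (20(*k*−1), 20*k*] — which keeps 100 % in the top class
and partitions [0, 100] exhaustively (property-tested across the range).

Replicate aggregation pools the three pollinators' counts before forming
the percentage (the per-cross single percentages of published tables are
consistent with pooling); `aggregate = "mean"` averages per-replicate
percentages instead. With equal flowers per replicate the two coincide.

Cross types — SCS/SCC for single self/hybrid crosses, DCS/DCC for double
hybrid self/crosses — are contrasted with a binomial GLM (logit link) on
per-cross success/failure counts. We report the likelihood-ratio deviance
against the intercept-only model (1 df) rather than Wald statistics: under
complete separation (a group with no successes) the Wald output is
degenerate while the pooled-table likelihood ratio remains finite; in that
case the statistic is computed directly from the pooled 2×2 table and the
result flagged. With a single cross per group the GLM deviance equals the
classical 2×2 G statistic, which the tests verify numerically.

Class prominence within a cross type is tested by chi-square goodness of
fit against uniform over the six classes (5 df). The pairwise
class-proportion comparisons use Holm adjustment — the most conservative of
the standard stepwise options, chosen because no particular adjustment is
canonical for this design.

## Yield and quality traits

Outturn is the peeled nut weight as a percentage of unpeeled weight.
Published per-cross tables show outturn values slightly below the ratio of
the printed mean weights (e.g. 69.1 vs 61.7/88.7 = 69.6 %), which is what
one gets by computing outturn per replicate and averaging the ratios; the
package therefore treats mean-of-ratios as the default convention and keeps
ratio-of-means available through `outturn_percent()` on the summary means.
Packaged fixtures store printed values verbatim and never recompute derived
columns.

Per-cross summaries report mean, SE and n per trait; SE with n = 1 is
reported missing rather than zero. Group tests run one-way ANOVA first and
switch to Kruskal–Wallis when Shapiro–Wilk rejects residual normality at
0.05 (the trial literature says only "where relevant"; a residual-normality
gate is the common operationalisation). Significant global tests are
followed by pairwise comparisons — LSD on the pooled ANOVA mean square, or
Dunn-style rank-mean z-tests after Kruskal–Wallis — rendered as compact
letter displays. Letters are assigned from the maximal cliques of the
"not significantly different" graph, so letter sharing is exactly
equivalent to pairwise non-difference (verified against a brute-force
pairwise oracle in the tests).

## Heterosis

For hybrid value F1 with parental self-cross values P1, P2:

* mid-parent heterosis: 100 (F1 − MP)/MP, MP = (P1 + P2)/2;
* heterobeltiosis: 100 (F1 − BP)/BP, BP = max(P1, P2);
* economic heterosis: 100 (F1 − S)/S against a standard variety S.

All three scored traits (pod set, outturn, brix) are larger-is-better, so
the better parent is the larger value and no trait-direction flag exists in
this version. Parents of a double cross (A×B)×(C×D) are the component F1
entities, valued by their double-selfs (A×B)×(A×B) and (C×D)×(C×D). The
two default standards are the recommended varieties GX1/46 × GX1/16 and
JX1/5 × JX1/9, looked up as observed dataset means of those crosses; an
override table can supply external values. Zero or missing denominators
(e.g. fully incompatible parent selfs) yield undefined results with
provenance, never numeric sentinels — crosses whose parent selfs were never
made are reported as undefined rather than guessed. When P1 ≠ P2 (both
positive), BP ≥ MP implies BPH ≤ MPH for any F1; this ordering, parent-swap
symmetry and sign coherence are property-tested.

## The simulator

The generator emulates the trial design itself: 20 pollinations × 3
pollinator replicates per cross, selfs plus single and double hybrid
crosses over a germplasm of `n_genotypes` trees.

* **S-locus.** Each genotype carries two of `n_s_alleles` S-alleles drawn
  uniformly; the default model is a strict linear dominance hierarchy (the
  phenotype is the most dominant allele), the simplest mechanism that
  reproduces the observed self-incompatible / mostly-cross-compatible
  pattern. A codominance option expresses both alleles. A cross succeeds
  at rate `p_compat` when the phenotypes are disjoint, else at the leakage
  rate `p_leak`. All selfs are incompatible under strict dominance;
  moderate self pod set (as seen in real tables) is emulated through
  `p_leak` > 0 rather than S-allele loss — one leakage parameter suffices
  at this scale, and the mechanism is recorded in the truth output so
  downstream checks never mistake it for biology.
* **Defaults.** `p_compat = 0.7` places compatible crosses mostly in class
  4 (61–80 %), the class reported predominant among hybrid crosses;
  `p_leak = 0.25` matches the central tendency of printed self-cross pod
  sets (classes 1–3); pseudo-pod probabilities (0.15 incompatible vs 0.03
  compatible) reproduce the elevated pseudo-pod set of selfs. Pseudo-pods
  are drawn after pods from the remaining flowers, so their *count* is also
  mechanically favoured where pod set is low; dropped flowers are the
  remainder, making counts conserve flowers exactly.
* **Traits.** Genotypes carry additive trait values drawn around
  field-realistic means (CV `gen_cv` = 0.2). An F1's expectation is the
  mid-parent value times 1 + `dominance_gain` when the cross is compatible
  and not a self, else the mid-parent value; F1 entities inside double
  crosses inherit one seeded allele from each member and the
  gain-inflated mid-parent additive value. Outturn and unpeeled weight are
  the primary simulated traits and peeled weight is derived from them, so
  outturn itself has the additive-plus-dominance structure and noise-free
  mid-parent heterosis recovers 100 × `dominance_gain` exactly for every
  scored trait. The recorded per-cross trait value is the mean of per-pod
  measurements over all pods harvested across replicates (unit-mean
  lognormal noise, CV `env_cv`) — mirroring how nut and pod traits are
  measured on harvested pods in the field; crosses setting no pods get
  missing traits. With `env_cv = 0.1` this yields a mean absolute MPH
  recovery error around 2 percentage points over hundreds of crosses.
* **Reproducibility.** Every random draw is keyed by (seed, cross label,
  replicate) through a stable string hash, so repeating a simulation is
  byte-identical and *extending a design never perturbs existing crosses*.
  Per-flower uniforms are compared to the success probability, which makes
  pod counts monotone in `p_compat` under a fixed seed.

What the simulator does **not** emulate: pollen-tube growth, multi-locus or
partially dominant SI, flowering phenology, spatial pollinizer layout,
year/site effects, or correlated trait architectures. Passing tests on
simulated data therefore demonstrate the statistical machinery (estimator
correctness, size of tests, recovery of planted effects), not field
validity of any biological parameter.

## Multivariate characterisation

PCA standardizes every trait (unit variance) and eigendecomposes the
correlation matrix; missing cells are mean-imputed with a warning and
zero-variance traits dropped. Component signs follow a deterministic
convention (largest-magnitude loading positive). Clustering is Ward
(`ward.D2`) on the Euclidean distances of the scores reaching 80 %
cumulative variance — published analyses report dimension percentages but
not a retention policy, so 80 % is this package's choice. When `k = "auto"`
the partition is selected over k = 3…6 (bounded there because reported
solutions in comparable trials were 3 or 5 clusters) by the largest
relative loss of within-cluster inertia between successive partitions,
ties toward fewer clusters. On well-separated data this recovers the true
number of groups exactly; on the packaged GX1 table it selects 4 clusters
(the inertia profile genuinely favours 4 over 3 under both this rule and
the common ratio criterion), a reminder that tree-cut counts are not
robustly identified by small printed tables. No k-means consolidation is
applied after the cut.

Clusters are described by the v-test: for cluster c and trait x,
v = (x̄_c − x̄) / sqrt((s² / n_c)·(N − n_c)/(N − 1)) with s² the overall
population variance (denominator N), i.e. the standardized deviation of the
category mean from the overall mean under random allocation, with a
two-sided normal p-value flagged at 0.001 (the conventional reporting
threshold in such analyses; configurable). The identity
Σ_c n_c x̄_c = N x̄ holds exactly and is tested. Correlations are Pearson
on pairwise-complete observations with t-based p-values; pairs with fewer
than 3 observations are reported missing.

## Numerical and design choices

* Pedigree grammar: exactly 2 or 4 ID tokens; `×` binds with or without
  whitespace, bare `x`/`X` only as a free-standing separator (IDs like
  `P2-1B` or `Club` must survive). ID comparison is case-insensitive and
  ignores internal whitespace, since published tables spell the same tree
  both `JB 1` and `JB1`. Member order within an F1 pair is ignored when
  detecting double selfs (selfing direction is meaningless).
* Undefined ratios (0 flowers, zero denominators) are `NA` markers
  propagated with provenance, never sentinel numbers.
* The GLM contrast gates on exactly two cross types and positive
  pollination totals per group; ties in the class-distribution pairwise
  comparisons short-circuit to p = 1.
* Problem sizes in the tests (germplasms of 8–40 genotypes, designs of
  30–200 crosses, 200–1000 resimulations for size checks) were chosen so
  the whole suite exercises every stage, including a full pipeline on a
  100+-cross trial, in a few minutes on one CPU.

## Known limitations

* Heterosis estimates carry no standard errors or tests (point values
  only), matching how such tables are reported; combining-ability analysis
  (GCA/SCA) is out of scope.
* The compatibility GLM ignores pollinator-level overdispersion; with 3
  replicates per cross a quasi-binomial or mixed model would need more
  replication to be stable.
* Cluster counts from small trait tables are sensitive to the retention
  and cut rules (see above); cluster *memberships* should be read
  qualitatively.
* The fixtures are transcriptions of printed, rounded per-cross means;
  raw per-replicate counts are not public, so analyses that need
  replicate-level data (the GLM contrasts, SE columns) apply only to user
  or simulated datasets.
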