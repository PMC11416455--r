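---
title: "EVmiRDyn: models and methods"
author: "EVmiRDyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EVmiRDyn: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EVmiRDyn)
```

# The scientific setting

EVmiRDyn analyses small-RNA sequencing counts of microRNAs carried by
extracellular vesicles (EVs) that brain organoids release into their
culture medium. The study design it models has two genotypes — an
isogenic control line (IC) and a Rett-syndrome line carrying the
MeCP2:R255X nonsense mutation (RTT) — profiled as iPSCs at day 0 and as
dorsal and ventral forebrain organoids at days 13, 40 and 75 of
differentiation, in triplicate. That gives 14 condition cells (the single
iPSC D0 cell per genotype is shared by both regional analyses) and 42
samples at the default design.

Three questions drive the pipeline:

1. Which miRNAs change over developmental time in the healthy (IC)
   organoids, and what temporal profile classes do they form?
2. Which miRNAs differ between RTT and IC at each developmental stage,
   and do genomically clustered miRNAs (such as the chromosome 14 miRNA
   cluster, C14MC, at the imprinted chr14q32 DLK1-DIO3 locus, or the
   pluripotency-associated miR-302/367 cluster at 4q25) move together?
3. Which biological pathways are over-represented among the target genes
   of the interesting miRNA sets, judged against a permutation null that
   respects the structure of the miRNA-target map?

# Count model and normalization

Counts are modelled as negative binomial (NB): for miRNA $i$ in sample
$j$, $y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi)$ with
$\mathrm{Var}(y_{ij}) = \mu_{ij} + \phi \mu_{ij}^2$ and
$\log \mu_{ij} = x_j^\top \beta_i + o_j$, where $o_j$ is the log
effective library size.

Because miRNA libraries are dominated by a few very abundant species,
raw library sizes confound depth with composition. `tmmFactors()`
re-implements the trimmed mean of M-values estimator: for each sample
against a reference column (the one whose 75th-percentile count fraction
is closest to the mean of those fractions), per-miRNA log-ratios
$M_i = \log_2\{(y_{ik}/N_k)/(y_{ir}/N_r)\}$ and average abundances
$A_i$ are formed over miRNAs positive in both columns, doubly trimmed
(30% of $M$, 5% of $A$, each side), and averaged with inverse
delta-method-variance weights
$w_i^{-1} = (N_k-y_{ik})/(N_k y_{ik}) + (N_r-y_{ir})/(N_r y_{ir})$.
Factors are rescaled to geometric mean one. The implementation agrees
with the reference implementation in edgeR to machine precision on
random matrices (see the test suite), but is written from its definition
and is validated in the tests against a separate straight-line oracle.

`logCPMMatrix()` computes
$\log_2\{(y_{ij} + p_j)\,/\,(L_j + 2p_j) \times 10^6\}$ with effective
library size $L_j = N_j f_j$ and prior count $p_j$ scaled to the
relative library size ($p_j = p\,L_j/\bar L$, default $p = 2$). The
prior keeps zeros finite; it is documented prominently because the
ubiquitous-expression rule (log2 CPM $\ge 12$ in every IC sample)
depends on the display convention. This scaling makes the transform
exactly depth-invariant only at $p = 0$; with a prior the invariance is
approximate (the discrepancy is bounded by the prior's relative weight),
which is the convention of the workflow the study used.

The expression filter keeps miRNAs with unnormalized CPM $\ge 1$ in at
least as many samples as the smallest condition cell (3 by default),
jointly over all samples. Filtering thresholds were not reported by the
study; these are the conventional defaults and are configurable.

# Differential expression: quasi-likelihood F-tests

The testing layer is a self-contained NB generalized-linear-model
pipeline:

* **GLM fits.** `fitNBGLM()` fits the log-link NB GLM by iteratively
  reweighted least squares (weights $\mu/(1+\phi\mu)$), to a relative
  deviance tolerance of $10^{-8}$ within 100 iterations. Non-converged
  rows are flagged and their test p-values set to 1 with a warning.
* **Dispersion trend.** `estimateDispersions()` evaluates the Cox-Reid
  adjusted profile log-likelihood (the NB log-likelihood minus half the
  log-determinant of the weighted information) per miRNA on a geometric
  grid of 15 dispersions from $10^{-4}$ to 2, sums it within at least 10
  abundance bins, maximizes per bin with quadratic interpolation on the
  log scale, and smooths the binned estimates against average log2 CPM
  with lowess. Per-miRNA tagwise shrinkage at the NB layer is
  deliberately omitted: the quasi layer below carries the moderation,
  which keeps the two layers' roles separate.
* **Quasi-dispersions.** Each miRNA is refitted at its trended
  dispersion; the quasi-dispersion is residual deviance over residual
  df. An empirical-Bayes step moment-matches the log quasi-dispersions
  to a scaled-F model: the excess of their variance over the
  $\psi_1(d/2)$ sampling variance determines the prior df via the
  inverse trigamma, and values are squeezed as
  $(d\,s^2 + d_0 s_0^2)/(d + d_0)$. Exactly identical inputs are
  returned unchanged with infinite prior df (there is no spread to
  match). With any spread the computation agrees with
  `limma::squeezeVar`, which the tests use as a cross-check.
* **The F-test.** For a contrast $c$, the null model is the full design
  projected onto the orthocomplement of $c$ in coefficient space;
  $F = (\mathrm{dev}_0 - \mathrm{dev}_1)/s^2_{\mathrm{post}}$ is
  referred to $F_{1,\,d_0+d}$ (a chi-square when the prior df is
  infinite). Log2 fold-changes are $c^\top\hat\beta/\log 2$. BH
  adjustment is applied within each tested miRNA set.

`temporalDE()` fits one coefficient per timepoint within one region's IC
samples (the shared iPSC D0 baseline is included in both regions, so
each regional design has four timepoints) and tests the six pairwise
timepoint contrasts. `genotypeDE()` tests RTT minus IC separately in
each of the seven region/timepoint cells, with dispersions estimated on
that cell's six samples — matching the study's "at each time point,
separately per region" analysis; BH is applied within each comparison.
Dispersion estimation is per analysis subset because the study ran its
tests separately per region; a global estimate is not attempted.

# Temporal dynamics, clustering, and the ubiquitous rule

`dynamicMiRNAs()` forms the union of miRNAs with BH q below 0.05 in at
least one of the six contrasts of at least one region. The union of
many FDR-controlled lists does **not** control FDR at the same level:
each table contributes on the order of $\alpha$ times its discovery
count of false positives, and these only partially overlap across the
twelve tables. On synthetic data with 20 planted monotone miRNAs the
union's realized precision is typically 0.7-0.9 — the same range the
reference edgeR pipeline attains on identical data — while sensitivity
is 1.0. This is a property of the selection rule, not of the test, and
is worth remembering when interpreting the size of the dynamic set.

Profiles of the dynamic miRNAs are standardized per miRNA to mean zero
and unit variance over all IC samples of both regions jointly (one
heatmap spans both regions). The sample (n-1) standard deviation is
used; "unit variance scaled" does not pin down the convention, so it is
configurable, and constant rows map to zero profiles with a warning.
`wardCluster()` clusters standardized profiles with Euclidean distance
and Ward's minimum-variance linkage via `stats::hclust(method =
"ward.D2")` — the canonical implementation operating on distances —
cut at $k = 3$ by default to mirror the three temporal classes of the
study (a decreasing, an increasing, and a mixed group). A bespoke
agglomerator with a lexicographic tie-break was considered and
rejected: `hclust` is already deterministic for a given input, and
exact merge-cost ties are measure-zero events for continuous profiles.
Each cluster receives a monotonicity call from the sign pattern of the
consecutive timepoint differences of its mean profile within each
region.

`ubiquitousMiRNAs()` applies the study's rule verbatim: normalized log2
CPM at least 12 in **every** IC sample. Note this is an extreme-value
statistic: a miRNA whose true level sits just above the threshold will
miss the set whenever a single replicate dips below, so the called set
is conservative near the boundary.

# Genomic cluster summarization

`clusterSummary()` takes cluster membership from the annotation's
`cluster_id` column (membership is an input, not a constant — the study
implies 50 C14MC members but does not list them; `assignClusterByLocus()`
can label members by interval containment in a named window instead).
It reports members tested, members significant in at least one
RTT-vs-IC comparison, the fraction significant, mean member log2
fold-change per comparison, and per-condition mean log2 CPM of each
member ordered along the genome — the data behind a cluster-wide
expression profile plot.

# The synthetic-data generator

`simulateCounts()` emulates the study: NB counts with
$\mu = \text{library size} \times \text{relative abundance}$, log-normal
library sizes (default mean $10^6$, CV 0.2 — depths were not reported,
so these are conventions), NB dispersion 0.1, and log-normal baseline
abundances (log2 mean 6, sd 2) reflecting the strong skew of miRNA
libraries. Planted classes, all configurable through `EffectSpec`:

* monotone **increasing/decreasing** miRNAs (default 10 + 10, echoing
  the study's 20 dynamic miRNAs) with a 1 log2 step per timepoint;
* a **genotype-elevated** block of 50 miRNAs (+1 log2 in every RTT
  sample) laid out contiguously by `simulateAnnotation()` inside a
  chr14q32-style locus, emulating the C14MC observation;
* **ubiquitous** miRNAs whose abundance weight is anchored to the mean
  non-ubiquitous composition so their normalized level stays near the
  target log2 CPM of 13 in every condition — one unit above the calling
  threshold. With NB noise the all-samples minimum can still dip below
  threshold occasionally, which is faithful to how the rule behaves on
  real data;
* **composition-biased** null miRNAs (5% by default, +2 log2 in dorsal
  samples) that exercise the TMM correction. Note that in the temporal
  analysis a dorsal-specific shift is indistinguishable from a
  D0-to-D13 change, because the D0 baseline lives in the iPSC region —
  an inherent confound of the design that recovery tests avoid by
  setting this fraction to zero.

Relative abundances are renormalized to proportions within each
condition, decoupling depth from composition. The planted "true" TMM
factor for sample $j$ is $s_j/(N_j S_{c(j)})$ (realized depth times
total condition composition), rescaled to geometric mean one. Under
biological overdispersion ($\phi = 0.1$) any correct TMM estimator —
ours and edgeR's give bit-identical values — scatters 5-12% around the
planted factor, because a handful of high-weight abundant miRNAs
dominate the trimmed weighted mean. The normalization-recovery test
therefore runs at Poisson (sequencing) noise with planted depth
variation (CV 0.4) and 20% composition bias, where recovery is within
2%; the vignette states this so the test's scope is clear: it verifies
the estimator, not the identifiability of factors under arbitrary
biological noise.

`simulateTargetMap()` and `simulatePathways()` complete the resource
set: Poisson-sized target sets (mean 25) over a 2000-gene universe, the
genotype-elevated class drawing 80% of its targets from a designated
100-gene block, and that block plantable as a pathway — so enrichment
recovery is testable end to end. All stochastic steps derive sub-seeds
deterministically from one global seed (`deriveSeed()`), keeping every
fixture bit-reproducible.

What the generator does **not** emulate: sequencing reads and mapping,
miRNA families with correlated sequences, sample-to-sample correlation
beyond library size, batch structure, or the proteomics arm of the
study. Passing recovery tests on this generator therefore demonstrates
correctness of the statistical machinery under the stated model, not
performance on real libraries.

# Pathway enrichment and the permutation null

`ora()` is the upper-tail hypergeometric test
$P(X \ge k)$ with population $N$ (the gene universe — by default all
genes in the pathway collection, configurable to the union of mapped
targets), $K$ pathway genes, and $n$ query genes, where the query is the
**union** of the target sets of a miRNA set (`targetUnion()`).

Because target unions of correlated miRNA sets violate the
independent-sampling assumption of the hypergeometric model,
`permutationPvalues()` recalibrates each pathway against size-matched
random miRNA sets: `nPerm` (default 10,000) draws without replacement
from the sampling pool — all measured miRNAs, including target-less
ones, since an observed significant set may contain them — each
evaluated on the same permuted set for every pathway, preserving
cross-pathway correlation. The permutation p-value is $(b+1)/(n+1)$
with ties counted as "at or below" (conservative, never zero, a valid
p-value and hence super-uniform under the null); `paperParity = TRUE`
reports $b/n$, the convention whose granularity matches permutation
p-values like $5\times10^{-4}$ at 10,000 permutations. Whether the
calibrated quantity is the raw or the FDR-adjusted ORA p does not
affect ranking within a fixed collection; the raw p is used.

# Numerical choices and degenerate inputs

* GLM convergence $10^{-8}$ (relative deviance), 100 iterations;
  linear-predictor values capped at 700 before exponentiation.
* Dispersion grid $[10^{-4}, 2]$, 15 points, quadratic interpolation in
  log-dispersion; fewer than 4 bins fall back to a constant trend.
* Quasi-dispersions are floored at $10^{-10}$ before the log-moment
  step; zero-residual-df designs are rejected with an instructive
  error.
* TMM pairs with fewer than two usable miRNAs (or fewer than two after
  trimming) return factor 1 with a warning; all-zero columns are an
  error.
* Empty filter results are a warning, not an error; downstream stages
  handle empty sets (empty dynamic set skips clustering, empty observed
  miRNA set yields permutation p of 1 with a warning).
* Pipeline manifests exclude the output directory path, so equal-seed
  runs are byte-identical wherever they are written.

# Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make sampling
behaviour visible while keeping the default run quick: 2000 miRNAs for
null calibration of the F-test, 600-800 miRNAs for recovery studies, 42
samples (the study design), 10,000 permutations where exactness against
full enumeration is asserted and 99-500 where distributional behaviour
across hundreds of replicates is measured. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch at
these sizes for any seed.

# Known limitations

* Tagwise NB dispersion shrinkage is omitted by design; data with
  strong dispersion outliers are better served by robustified
  variants.
* The union-of-contrasts selection rule does not control the FDR of the
  union (see above).
* The permutation null conditions on the target map; it does not model
  uncertainty in the map itself.
* Exact NB tests, ranked GSEA, and topology-aware pathway analysis are
  out of scope.

# Session info

```{r}
sessionInfo()
```
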