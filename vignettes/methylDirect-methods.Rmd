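---
title: "Inferring direct methylation-expression regulation: models and choices"
author: "methylDirect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring direct methylation-expression regulation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDirect)
```

## The problem

Tumor methylomes contain thousands of CpG sites whose methylation
correlates with the expression of nearby genes, but most of those
correlations are consequences of shared upstream drivers (global
hypermethylation programs, copy-number-driven expression blocks,
cell-type composition) rather than regulation. methylDirect asks, for a
target gene, which CpG probes within a genomic window of its TSS are
*directly* connected to its expression once all other genes and probes in
the window are allowed to explain the correlation away. Probes that
survive are called direct regulatory elements (DREs), and a (probe, gene)
call is a DRE-target pair.

## The dependence model

All estimators operate under a multivariate-Gaussian working model, where
entropy and (conditional) mutual information reduce to determinants of
sample covariance matrices:

* entropy: `H(X) = d/2 ln(2*pi*e) + 1/2 ln|C|`
* MI: `I(X,Y) = 1/2 ln( |C(X)| |C(Y)| / |C(X,Y)| ) = -1/2 ln(1 - r^2)`
* CMI: `I(X,Y|Z) = 1/2 ln( |C(X,Z)| |C(Y,Z)| / (|C(Z)| |C(X,Y,Z)|) )`,
  which equals `-1/2 ln(1 - rho^2)` for the partial correlation `rho` of
  X and Y given Z.

A CMI near zero given some third variable Z means the X-Y dependence is
mediated: the pair is connected only through Z.

Two numerical choices matter here:

* **Correlation-form determinants.** The MI/CMI ratios are evaluated on
  correlation (not covariance) submatrices. The variance factors cancel
  analytically, and the correlation form is scale-invariant and stable.
  Entropy keeps the covariance form, since absolute entropy depends on
  scale.
* **Adaptive ridge.** Log-determinants go through a Cholesky
  factorization; if and only if that fails, a ridge of
  `1e-8 * mean(diag)` is added and the factorization retried, after
  which a failure is a hard "degenerate input" error naming the
  variables. Applying a ridge unconditionally would perturb every MI
  value at the 1e-8 level; applying it adaptively keeps well-conditioned
  inputs bit-faithful to the closed forms (the test suite requires
  agreement with `-1/2 ln(1 - r^2)` to 1e-10) while still catching
  collinear windows.

### Normalization

MI of perfectly dependent continuous variables is infinite, so normalized
MI is computed against a saturation value: the MI at correlation
`1 - epsilon`, i.e. `-1/2 ln(2*epsilon - epsilon^2)` with
`epsilon = 1e-6` (about 6.56 nats). Weakly dependent pairs sit near 0,
near-deterministic pairs near 1, and the result is clamped to [0, 1].
`epsilon` is exposed as `epsilonMax` in `pcParams()`.

### Permutation significance

Edge significance uses random permutation plus Fisher's Z statistic: the
sample order of both variables is shuffled `nPerm` times (default 100),
the statistic is computed per shuffle, and both observed and null values
are Fisher-transformed, `z' = 1/2 [ln(1+r) - ln(1-r)]`. The Z-score is
`(observed - null mean) / null sd` and the p-value the two-sided normal
tail, `2 * pnorm(-|Z|)`.

The test statistic is the **signed (partial) correlation**, not the
folded normalized MI. This is a deliberate numerical choice: the Gaussian
MI is a monotone function of `|r|`, so both statistics order edges
identically, but the folded statistic's permutation null is
chi-square-skewed and the normal-tail recipe then over-rejects by roughly
a factor of three at p < 0.01 — enough to leave one spurious leaf-leaf
edge in a five-node hub system every few runs. The signed correlation is
the Fisher transform's natural domain; its permutation null is symmetric
and near-normal, and the reported p-values are calibrated (the suite
checks the empirical type-I rate on independent data). Every permutation
stream is keyed by the master seed plus the sorted variable ids involved,
so results are independent of edge iteration order, variable order, and
scheduling.

## The pruning cascade

`inferNetwork()` composes four stages over the merged window matrix:

1. **Complete graph** over all genes and probes in the window.
2. **MI pruning**: every edge is scored; edges with permutation
   `p >= pCutoff` (default 0.01) are removed.
3. **Conditional pruning**: for each surviving edge (i, j), every common
   graph neighbor k is tried singly; if CMI(i, j | k) loses significance
   for any k, the edge is indirect and is removed. Removals are deferred
   to the end of the sweep, so the output does not depend on the order
   edges are visited. Conditioning sets are limited to single variables
   (order-1), matching the sparse-network regime the cascade targets;
   `iterateCmi = TRUE` repeats sweeps to a fixed point (default is a
   single pass — in the linear-chain and hub systems the suite covers,
   one pass already reaches the fixed point, and a single pass keeps the
   cost predictable).
4. **MI floor**: edges must carry MI strictly above `miFloorBits`
   (default 0.1 bits) — a pure effect-size filter that removes
   statistically significant but weak connections.

Defaults live in `pcParams()`: `pCutoff = 0.01`, `miFloorBits = 0.1`,
`nPerm = 100`, `maxConditioning = 1`.

## From networks to DRE-target pairs

`assembleWindow()` collects the target gene, all annotated genes with TSS
within ±300 kb (closed interval) of the target TSS, and all probes in the
same window, merging expression and methylation over shared samples.
Probes directly connected to the target after pruning become DRE-target
pairs with:

* `pcc` — Pearson correlation between probe beta and target expression;
* `distance_bp` — signed probe-TSS distance measured 5'→3' relative to
  the gene's strand (BED input is 0-based half-open and converted to
  1-based; probes anchor at their interval midpoint, genes at the
  strand-resolved TSS);
* `locus_class` — promoter iff `|distance| <= 2000` bp (closed
  boundary), else distal;
* `corr_sign` — negative iff `pcc < 0`; an exact zero is tie-broken to
  positive and logged;
* `target_direction` — filled only when a differential-expression table
  is supplied, applying the `|log2FC| > 0.58`, adjusted `p < 0.01`
  filter. Differential expression itself is consumed, not computed; a
  Welch t utility (`rankSignature()`) is provided as plumbing.

Overlapping windows can re-call the same (probe, gene) pair; duplicates
are collapsed keeping the smallest p-value. A probe may legitimately pair
with several genes, so no cross-gene deduplication is done.

`classifyDynamics()` compares initiation (tumor - normal) and progression
(late - early) beta deltas with a tolerance of 0.05 beta units by
default — below typical differential-methylation reporting thresholds,
so only clear changes flip categories. Opposite signs with both deltas
above tolerance give "reversed"; otherwise magnitudes within tolerance
are "consistent", larger progression changes "stronger", smaller
"weaker".

`pairPrecision()` evaluates only negatively correlated pairs against
chromatin-interaction anchor pairs: a pair is confirmed when the probe
falls in one anchor and the target promoter (TSS ± 2 kb, the package's
gene-end proxy, since an interaction "touching the gene" needs a finite
gene interval) overlaps the mate anchor, in either orientation.

## Master regulators

`inferRegulon()` builds a TF's regulon from permutation-significant MI to
the TF, then applies the data-processing inequality: in every triangle of
significant edges the weakest edge is removed when it is below
`(1 - dpiTolerance)` times the smaller of the other two (tolerance 0.1 by
default — the conventional setting for DPI filtering of coexpression
triangles). Members split into regulon(+) and regulon(-) by the sign of
the Spearman correlation with the TF.

`masterRegulatorTest()` runs two enrichment passes against a ranked
t-statistic signature: run 1 tests regulon(+) on the upregulated side and
regulon(-) on the downregulated side; run 2 reverses the sides. Each side
uses a rank-sum (Mann-Whitney) test of members against non-members —
chosen over a running-sum GSEA because it is deterministic with a
closed-form null; a two-sample Kolmogorov-Smirnov alternative sits behind
`method = "ks"`. Side p-values combine by Fisher's method
(`-2 sum(ln p)` against chi-squared, 4 df), q-values are
Benjamini-Hochberg across TFs, and the TF is oncogenic when run 1 wins,
tumor-suppressive when run 2 wins, provided the better q passes the
threshold.

## Enrichment statistics

TF binding associates with a DRE when a motif hit falls within ±250 bp of
the probe (closed interval). Category enrichment uses the ratio
`OR = (a/c)/(b/d)` with `a`/`b` the category DREs with/without the site
and `c`/`d` the same over all DREs, CI
`exp(ln OR ± 1.96 sqrt(1/a+1/b+1/c+1/d))`, and an `OR > 1.05` call. Zero
cells are a hard error because the formulas are undefined there; an
opt-in Haldane correction adds 0.5 to every cell. Chromatin-state style
enrichment is the upper-tail hypergeometric `P(X >= x)` with fold change
`(x/n)/(K/N)`. The four DRE subgroups (negative/positive ×
up/down) are treated as a union for the background, and
`rankTfsByMethylation()` orders TFs ascending by the correlation between
TF expression and the mean methylation of its bound sites, so the most
anti-correlated TFs rank first.

## Circuitry and motifs

`assembleCrc()` keeps distal DREs overlapping a super-enhancer; a TF
auto-regulates when its own motif sits within the flank of such a DRE
targeting it, and TF1 regulates TF2 when TF1's motif sits on TF2's
SE-overlapping DRE. `triadCensus()` classifies every weakly connected
node triple by isomorphism into one of the 13 connected three-node
directed motif classes — the classifier canonicalizes the 6-bit
adjacency code over all vertex permutations, and `triadClasses()`
documents the code-to-label table (021D ... 300). Triples are counted
once each (census semantics), not once per embedding, so class counts
sum to the number of connected triples. `motifZscores()` compares the
census against 200 degree-preserving randomizations by default (directed
double-edge swaps, 10|E| attempts each — the standard motif-analysis
null; an Erdős–Rényi same-size alternative is available), with
`Z = (obs - mean)/sd` per class, `Z = 0` where a zero-variance null
matches the observation, and the conventional `|Z| > 2` reading.
Self-loops are ignored by the census and non-TF nodes should be removed
before calling it.

## What the synthetic scenes emulate — and what they do not

`simulateScene()` produces the study conditions the calibration
experiments run under: continuous expression, beta-valued methylation
produced by a logistic squash of standard-normal latents (slope 1.5,
per-probe baseline in ±1 logit), direct edges contributing
`effectSize * latent` to the target expression (default 0.8 times the
noise scale, giving per-edge detection power around 0.9 at n = 300),
confounders correlating probe pairs, and — when gene slots exist —
indirect probe-target chains through a mediator gene whose conditional
independence the pruning must discover. Coordinates are drawn uniformly
within ±300 kb of the target TSS. Everything is bit-reproducible from
the seed.

The scenes deliberately do not model array chemistry (type I/II probe
bias), batch effects, copy-number confounding, cell-type mixtures, or
non-linear regulation. Passing the recovery and FDR suites therefore
shows the inference machinery is correct and calibrated under its own
working model, not that real-cohort error rates will match.

`fdrExperiment()` mirrors the pipeline's error-control simulation: per
replicate it calls DREs on a scene and on a label-shuffled null (the
methylation sample order is permuted against expression — dependence is
destroyed, marginals and probe-probe structure kept), reporting true,
false and chance calls and `FDR = false / (false + true)` aggregated over
replicates. At the default conditions (20 scenes, 1 target gene, 30
probes, 3 direct edges, n = 300, p < 0.01, 0.1-bit floor) the acceptance
suite requires the aggregated FDR to stay within two binomial standard
errors of 0.05; the MI floor makes chance calls at n = 300 vanishingly
rare, so the realized FDR is typically 0.

## Problem sizes and runtime

The shipped suites run at desk scale, chosen so the full test run stays
in single-digit minutes on one core: 20-scene FDR experiments with
31-node windows, 50-replicate chain/collider/star recovery at n = 1000,
100-fixture closed-form checks, exhaustive enumeration for the triad
classifier (64 graphs) and the hypergeometric oracle (all instances with
N ≤ 12). Per-gene windows are independent, so genome-scale runs
parallelize trivially; permutation streams are keyed by (seed, edge), so
results never depend on worker count.

## Known limitations

* The Gaussian working model captures monotone, roughly linear
  dependence; strongly non-linear regulation would need the
  kernel-density estimators this package intentionally does not
  implement.
* Order-1 conditioning cannot separate edges that are only rendered
  independent by conditioning on two or more variables jointly.
* The MI floor is an effect-size filter: true but weak regulation below
  0.1 bits is invisible by design.
* Methylation beta values near 0 or 1 compress the latent scale; the
  estimators see the attenuated correlation.
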