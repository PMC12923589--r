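---
title: "Methods: marker-set enrichment and key-driver analysis on tissue networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-set enrichment and key-driver analysis on tissue networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasnet)
library(dplyr)
```

# Overview

`gwasnet` asks, tissue by tissue, which gene sets carry more
genome-wide-association signal than size-matched random gene sets, and
which regulatory-network hubs sit upstream of those disease-associated
genes. It deliberately consumes *full* summary statistics — every marker's
p-value, not only genome-wide-significant hits — because under an
omnigenic view much of the heritability of complex traits is spread over
weak and moderate signals acting through networks.

The pipeline has three stages plus a convergence layer:

1. **Marker dependency filtering (MDF)** — remove LD-redundant markers,
   then map retained markers to genes per tissue.
2. **Marker-set enrichment analysis (MSEA)** — the chi-like quantile
   statistic with a random-gene-set permutation null.
3. **Key-driver analysis (KDA)** — hub selection and neighborhood
   enrichment for the disease gene set on a directed network.
4. **Variant overlap** — hypergeometric enrichment of rare/common-variant
   genes in key-driver subnetworks, normalized counts, group comparisons.

# Marker dependency filtering

Correlated markers would otherwise be counted repeatedly by any
marker-pooling statistic. Markers are processed in descending association
score (`-log10` p); a marker is retained unless its r² with an
already-retained marker exceeds the threshold (default **0.5**), in which
case it is recorded as removed with the earliest-retained dependent marker
as its representative. This greedy score-ordered rule guarantees the two
properties that matter downstream: the retained set has no pairwise
dependency above the threshold, and every removed marker is dominated by a
retained representative at least as strong. Explicit LD-block assignments
are supported as an alternative input; there the rule reduces to "keep the
top scorer of each block". Clumping is idempotent, and raising the
threshold can only grow the retained set.

Two conventions were genuinely open and are fixed as follows: missing LD
entries are treated as r² = 0 (absence of evidence of dependency — markers
with no LD information are always retained), and score ties break by
ascending marker ID for determinism. Clumping operates on whatever LD
table is supplied; per-chromosome versus genome-wide clumping is therefore
the caller's choice of input.

Gene mapping unions the selected sources (eQTL, sQTL, distance) per
tissue, deduplicates markers within genes, and drops genes with no
retained marker. Distance mapping uses 1-based inclusive coordinates with
a ±20 kb default window on both gene ends; a BED reader converts 0-based
half-open input and says so.

# The enrichment statistic

For a module whose genes pool `m` distinct retained markers, with
background the union of all mapped retained markers in the tissue:

$$\chi = \sum_{i=1}^{n} \frac{O_i - E_i}{\sqrt{E_i} + \kappa}$$

* `t_i` — empirical `q_i`-quantile of background scores,
* `O_i` — module markers with score **strictly** above `t_i`,
* `E_i = m (1 - q_i)` — expectation if module markers were exchangeable
  with the background,
* `κ = 1` — stabiliser for small expected counts.

Quantile levels run from 0.5 to `q_upper = 1 − 1/μ`, with `μ` the median
module size of the scored collection; `n = 10` levels by default. Summing
over the ladder frees the statistic from any single significance cutoff.
Three numerical choices are fixed and documented because results depend on
them:

* **Quantile type.** All empirical quantiles package-wide (score
  thresholds, hub-degree cutoffs) use the inverse empirical CDF with
  averaging at discontinuities (`quantile(type = 2)`), so thresholds never
  interpolate between observed values except at exact jumps and are
  reproducible across implementations.
* **Ladder spacing.** Levels are equally spaced and include both
  endpoints — the plainest reading of "levels ranging from 0.5 to an upper
  limit". When `μ ≤ 2` the ladder degenerates to the single level 0.5 and
  a warning is raised.
* **Ties at a threshold.** A marker counts as positive only with score
  strictly above `t_i`; ties count as non-positive. This is deterministic
  and conservative.

`μ` is computed per scored collection (after intersecting modules with the
tissue's gene universe), with an override argument for users who want a
collection-external value.

# The permutation null

The null hypothesis is that the distinct markers of `N` genes carry the
same proportion of positive associations as the distinct markers of `N`
random genes. Each draw samples `N` genes uniformly without replacement
from the tissue's mapped gene universe, pools their distinct markers, and
computes χ against the *fixed* background thresholds. Sampling genes (not
markers) preserves the gene-level clustering of markers, which is what
makes module sizes comparable; a marker-permutation null is deliberately
not implemented.

Z-scores use the sample (n−1) standard deviation; p-values are one-sided
upper-tail Gaussian (enrichment is directional, and ranking is the use
case); FDR is Benjamini–Hochberg across the modules scored in one call —
the multiple-testing family is one invocation, typically one tissue, and
this is the package's documented default rather than a global cross-tissue
family. Modules with fewer than `min_genes = 5` intersected genes are
skipped: below that the pooled marker count is so small that the statistic
is dominated by single markers. A degenerate null (zero spread) flags the
module and reports p = 1 rather than an undefined Z.

Null draws are cached per distinct module size and generated in ascending
size order under one seeded stream, so results are independent of module
order and fully reproducible; `n_perm = 2000` by default (minimum 100
enforced), chosen so that the Gaussian tail approximation, not the draw
count, limits resolution.

# Key-driver analysis

Hub candidates are nodes whose degree reaches the 0.75 quantile of the
positive-degree distribution. Degree is in-degree plus out-degree by
default — hubness as total connectivity — with an out-degree-only mode for
users who equate drivers with regulators. Each candidate's subnetwork is
its neighborhood within `depth` steps (default 1, matching the
visualisation convention of first-degree neighbors; exposed as a
parameter), following edges both ways by default, or only downstream /
upstream.

The score is the overlap between subnetwork and disease gene set. The
null reshuffles subnetwork membership: node sets of the same size drawn
uniformly from the node universe. This topology-free null is the literal
reading of "reshuffled subnetworks of the same size", and its mean
provably matches the hypergeometric expectation `|s|·|D|/|V|` — which the
test suite checks by Monte-Carlo. A topology-preserving alternative
(random same-size neighborhoods) is available behind `null_method =
"neighborhoods"` but is not the default, since it conflates degree
structure with disease-gene placement. One-sided Gaussian p-values, BH
across candidates, ranking by p then fold over null mean then gene ID.

The disease gene set for the pipeline is the union of genes in modules at
FDR < 0.05 (threshold configurable), intersected with the mapped gene
universe.

# Variant convergence

Rare-variant genes come from a four-tier catalog (1 > 2 > 3 > syndromic in
confidence; conflicts keep the highest tier, reported). "Common-variant
gene" has no canonical definition at the gene level; the package
operationalises it as best mapped-marker score above a configurable
threshold, default `-log10(0.05)` (marker p < 0.05 before correction), and
echoes the threshold in outputs rather than claiming it as canonical.

Subnetwork enrichment uses the upper-tail hypergeometric test — identical
to the one-sided Fisher exact test, so one implementation serves both
names. Fold enrichment `(k/n)/(K/N)` is reported as `NA` (never infinity)
when a margin is empty. The enrichment background defaults to the network
node universe; an explicit background gene list (e.g. all expressed genes)
is accepted instead. Brain-versus-periphery style group comparisons use
Wilcoxon rank-sum tests (two-sided or one-sided), with optional
Shapiro–Wilk normality p-values reported alongside as the rationale for a
rank test — informational only.

# The synthetic-data generator

The generator exists so that every stage can be tested against known
truth; its defaults are the package's study conditions and are not tuned
per test.

* **GWAS scores.** Null markers: `p ~ Uniform(0,1]`. Signal markers:
  `-log10 p ~ Exponential(rate = ln 10) + effect_shift`. At shift 0 this
  is exactly the null distribution, so the shift is the entire effect; the
  exponential gives the heavy upper tail characteristic of association
  scans. Default `effect_shift = 1.5`.
* **LD.** Block-constant r² (default 0.8 within blocks of ~2 markers,
  4000 markers in 2000 blocks): clumping only consumes thresholded r², so
  blocks suffice; roughly half the markers survive filtering, as in a
  typical dense panel.
* **Modules and map.** 400 genes, 20 modules of 10–25 genes, 8 markers
  per gene drawn without replacement; planted modules (default 3) draw
  exclusively from the signal-marker pool. Marker sharing between genes is
  not modelled.
* **Network.** Preferential attachment (2 edges per node), each edge
  oriented old-to-new with probability 0.8 (hubs become out-hubs, like
  regulators). Planted key drivers are rewired to an upper-tail degree
  with 80% of their neighborhood drawn from the disease genes; half the
  key-driver neighborhood genes carry rare-variant labels versus a 2%
  background rate, emulating rare/common convergence around drivers.

Scenario profiles: `null` (nothing planted — type-I suites), `enriched`
(modules only), `full` (modules + key drivers + rare convergence). Bundles
written to disk regenerate byte-identically from the seed.

What the generator does **not** emulate: realistic human LD decay, allele
frequencies, marker sharing across genes, gene-length biases, correlated
module memberships, or expression data. Passing tests therefore
demonstrate correctness and calibration of the statistics under the
package's assumptions, not performance on real GWAS/eQTL data, where LD
structure and annotation biases can be adversarial.

# Problem sizes and verification

The test suite and the acceptance script verify, among others: the χ
statistic against direct summation on a fixed 20-marker instance (to
1e-12); type-I error of the enrichment test in [0.03, 0.07] on a null
scenario with 500 modules at 1000 permutations; recovery of all planted
modules (FDR < 0.05 and top-ranked) and of all planted key drivers (top
5% of candidates) in at least 18 of 20 seeded replicates at 2000
permutations; exhaustive agreement of LD clumping with a step-by-step
greedy reference on 1000 random instances of up to 12 markers; exact
agreement of the hypergeometric tail with combinatorial enumeration and
one-sided Fisher for every configuration with backgrounds up to 15; BH
agreement with an independent step-up implementation on 1000 random
vectors; the key-driver null mean within Monte-Carlo error of its
hypergeometric expectation at 5000 permutations on a 500-node network;
and byte-identity of repeated pipeline runs. These sizes were chosen as
the smallest at which the Monte-Carlo bounds are sharp enough to be
meaningful.

# Known limitations

* The Gaussian tail on permutation Z-scores extrapolates beyond the
  permutation resolution; extremely small p-values are approximations,
  appropriate for ranking.
* Greedy clumping is order-dependent by design; it matches standard
  practice but is not a globally optimal independent-set solver.
* The per-invocation BH family means cross-tissue comparisons should
  adjust externally if a global family is desired.
* Gene and marker identifiers are opaque case-sensitive strings; no ID
  translation or liftover is attempted.
* Second-stage meta-analysis across tissues and merged-module rescoring
  are out of scope.
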