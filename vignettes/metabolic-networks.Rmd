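---
title: "Metabolic covariance networks from regional FDG-PET SUVR"
author: "FDGnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance networks from regional FDG-PET SUVR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Glucose metabolism, measured with FDG-PET, covaries between brain regions:
across subjects of a diagnostic group, regions that participate in the same
functional systems have correlated standardized uptake value ratios (SUVR =
regional uptake divided by the subject's mean cerebellar uptake). FDGnet
estimates this *metabolic connectivity* at the group level: for a group
with $n$ subjects and $N$ atlas regions, entry $(i,j)$ of the connectivity
matrix is the Pearson correlation $r_{ij}$ between region $i$'s and region
$j$'s SUVR values over the $n$ subjects. This is a group-level construct —
there is one network per diagnostic group, not per subject — and it needs
at least 3 subjects per group to be defined (more for stability; the
sampling error of $r$ scales as $1/\sqrt{n}$).

The correlation matrix becomes a weighted undirected graph over the atlas
regions by zeroing the diagonal and handling negative correlations with a
configurable rule:

* `negativeRule = "zero"` (default): negative correlations are removed.
  This is the conventional construction for weighted covariance networks,
  and it is the only rule consistent with nodal degrees below $N-1$
  coexisting with degrees of exactly $N-1$ in published group tables.
* `negativeRule = "absolute"`: magnitudes are kept, for sensitivity
  analyses.

No further edge thresholding is applied by default (`threshold = 0`):
every positive correlation is an edge. A Fisher-z rescaling of the weights
(`fisherZ = TRUE`) is available as a sensitivity option and off by default.
SUVR values enter the correlation unadjusted; if groups differ in age or
sex, that covariance is part of what the network measures — users who need
covariate adjustment should residualize before building the cohort table.

## The sixteen measures

With weights $w_{ij} \in [0,1]$, strength $s_i = \sum_j w_{ij}$, degree
$k_i = \#\{j : w_{ij} > 0\}$, and shortest-path distances $d_{ij}$ computed
by Dijkstra's algorithm on edge lengths $1/w_{ij}$ (the standard mapping
from connection strength to distance; absent edges are not traversable):

* **nodal degree, strength** — as above.
* **triangles** $t_i = \tfrac12 \sum_{j,h} (w_{ij} w_{ih} w_{jh})^{1/3}$ —
  the geometric-mean weighted triangle count, which reduces to the plain
  count on 0/1 weights. Published group tables report non-integer triangle
  values, consistent with this weighted form.
* **clustering** $C_i = 2 t_i / (k_i (k_i - 1))$, 0 when $k_i < 2$.
* **transitivity** $T = \sum_i 2 t_i / \sum_i k_i (k_i - 1)$, 0 when the
  denominator vanishes.
* **path length** — mean of the finite $d_{ij}$ per node; unreachable
  pairs are excluded from the mean, and a fully isolated node reports
  $\infty$. **Eccentricity** is the maximum finite $d_{ij}$.
* **global efficiency** — mean of $1/d_{ij}$ with $1/\infty = 0$
  (denominator $N-1$), so disconnection lowers efficiency instead of
  breaking the average.
* **closeness** — $1/$path length, 0 for isolated nodes.
* **local efficiency** — the global efficiency of the weighted subgraph
  induced on a node's neighbors; 0 with fewer than 2 neighbors.
* **modularity** — weighted Newman quality
  $Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} - \gamma \frac{s_i s_j}{2m}\right]
  \delta(c_i, c_j)$ at resolution $\gamma = 1$, maximized by a seeded
  Louvain heuristic.

Global summaries are arithmetic means of the finite nodal values (average
strength, average eccentricity, characteristic path length, global
efficiency, local efficiency, clustering coefficient) plus transitivity and
modularity. The dense graphs that arise from all-positive correlation
matrices make the infinite-distance conventions mostly moot, but sparse
synthetic graphs exercise them, so they are fixed rules, not afterthoughts.

### Numerical choices in the Louvain optimizer

`graphModularity()` runs 100 restarts (configurable) and keeps the best Q,
ties resolved by first encounter; the whole procedure is bit-deterministic
given `(seed, restarts)` because shuffling uses a package-internal
generator rather than platform-dependent library calls. Greedy
agglomeration from singletons follows the strongest edges and can never
reach an optimum that cuts a strong edge, so half the restarts start the
first level from a random partition, and every run ends with a
finest-level refinement sweep (single-node moves on the original graph,
including escape to an empty community). On all exhaustively enumerable
test graphs ($N \le 8$) this matches the true optimum; for larger graphs Q
remains a heuristic lower bound of the optimal quality, as with every
Louvain implementation.

## Group comparison

`permutationTest()` compares any subset of the 16 measures between two
groups. The permutation unit is the subject: pooled subjects are relabeled
preserving group sizes, and the full pipeline — correlation, graph,
measures — is recomputed from scratch on every relabeling, which is the
only null consistent with group-level correlation networks. Two-tailed
p-values use absolute differences (group B minus group A) with the add-one
correction $p = (1 + \#\{|\Delta^\ast| \ge |\Delta|\})/(B+1)$, so $p = 0$
is impossible.

Family-wise error control is max-statistic (Westfall–Young): within each
nodal measure, the null distribution of the maximum $|\Delta^\ast|$ over
all nodes calibrates every node's corrected p-value; the 8 global measures
form their own family, corrected the same way. Two caveats are worth
stating plainly. First, across-node correction within each measure is a
choice — correcting across measures, or jointly, would be stricter; the
per-measure family matches how nodal results are conventionally reported.
Second, the global-measure family mixes scales (average strength is tens,
efficiency is below one), so an unstudentized max statistic is dominated by
the largest-scale measure and is conservative for the others; a Bonferroni
option (`fweMethod = "bonferroni"`) avoids this at the price of ignoring
dependence. Differences are not studentized, matching the plain two-tailed
permutation convention.

Zero-variance regions cannot arise from continuous SUVR data, but a
permuted subgroup could in principle produce one; such regions have their
correlations set to zero and are counted, and the test errors only if more
than 1% of permutations are affected.

Swapping the two cohorts negates every difference and leaves every p-value
unchanged at the same seed: permutation draws are made over the pooled
subjects in a canonical id-sorted order, and all internal seeds attach to
group names, not argument positions.

## The synthetic cohort generator

No patient-level SUVR tables are publicly deposited for this kind of
study, so the package ships a generator whose output exercises every
downstream stage. It is a block latent-factor model: regions are
partitioned into blocks; subject $i$'s value in region $j$ of block $b$ is

$$x_{ij} = \mu_j + \sigma\left(\lambda_b f_{ib} +
\sqrt{1-\lambda_b^2}\,\varepsilon_{ij}\right)$$

with standard-normal factors and residuals. The expected cross-subject
correlation is exactly $\lambda_b^2$ within a block and 0 across blocks —
a closed-form oracle the tests compare empirical correlations against.
Because residual variance is $1 - \lambda_b^2$, marginal variance is
constant across regimes: groups differ only in correlation structure,
which is precisely what the pipeline measures.

Defaults: baseline $\mu = 1.2$ (a typical cortical-to-cerebellar SUVR
level), $\sigma = 0.1$ (about 8% coefficient of variation, a plausible
between-subject spread for cortical SUVR), and a clipping floor of 0.01
that enforces positivity while keeping determinism (at default scales the
clip essentially never fires). The reference three-group design
(`defaultDesign()`) encodes the three observed correlation regimes:

* **CN analog** — one whole-atlas block, $\lambda = 0.85$
  ($r \approx 0.72$): dense homogeneous connectivity, $n = 142$.
* **AD analog** — one block, $\lambda = 0.55$ ($r \approx 0.30$): diffuse,
  globally attenuated connectivity, $n = 45$.
* **DLB analog** — four contiguous 17-region blocks with $\lambda$ = 0.85,
  0.30, 0.85, 0.20: a "patchy" matrix with some systems preserved and some
  severely reduced, $n = 18$.

Group sizes follow the reference clinical cohort (45 AD / 18 DLB / 142
CN). The $\lambda$ values themselves are plausible placeholders — the
magnitudes of real inter-regional SUVR correlations are not published as
numbers — chosen once so that the three regimes are qualitatively distinct;
they are not calibrated to data. Under these defaults the pipeline
reproduces the clinical orderings: strength, efficiencies, clustering and
transitivity lower — and eccentricity, path length and modularity higher —
in both disease analogs than in the CN analog.

What the generator does **not** emulate: age/sex composition differences,
scanner and smoothing effects, regional mean hypometabolism (group means
are equal by design — only covariance differs), non-Gaussian tails, and
spatial autocorrelation beyond the block structure. Passing tests
therefore demonstrate that the pipeline recovers known covariance
structure, not that it handles every artifact of real PET data.

One consequence of the independent-block construction deserves emphasis:
splitting a dense one-block group into independent blocks removes
cross-block edges, which lowers *every* node's strength, not only the
attenuated blocks'. Specificity tests therefore compare designs with
matched block layouts that differ only in one block's loading, making
preserved-block nodes exact nulls.

## Problem sizes and runtimes

The test suite and the acceptance script size their simulations for a
single desktop core: oracle equivalence uses 500 random graphs with
$N \le 9$ against exhaustive Floyd–Warshall/triple-enumeration oracles
(modularity against exhaustive partition search where the Bell number
permits, $N \le 7$ routinely and $N = 8$ in spot checks); synthetic
recovery runs the default 205-subject design with 1000 permutations;
error calibration repeats an identical-profile comparison 200 times at 500
permutations. Larger cohorts or permutation counts scale linearly.

## Limitations

* The pipeline starts from per-region scalar SUVR values; how those
  scalars were aggregated from voxels (mean over ROI, smoothed or not) is
  upstream and unmodeled — whatever aggregate is supplied is what gets
  correlated.
* Group-level networks mean no subject-level inference: all statistical
  resolution comes from the permutation test.
* Pearson correlation captures bivariate linear association only; partial
  correlation or sparse inverse covariance constructions are out of scope.
* With very unequal group sizes the permutation null mixes the two
  correlation regimes asymmetrically; p-values remain valid by
  exchangeability, but power is driven by the smaller group.
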