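---
title: "Methods: network-based disease-gene prioritization in netprio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based disease-gene prioritization in netprio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprio)
```

## The problem

Given a set of genes already annotated to a disease (the *seed* genes)
and one or more weighted functional gene networks — graphs whose edge
weights encode evidence that two genes are functionally related —
disease-gene prioritization ranks every other gene by its predicted
association with the disease. netprio implements a family of
network-propagation and kernel-based rankers, operators for fusing
heterogeneous networks into one, and the evaluation protocol needed to
compare them honestly.

Throughout, a network is a symmetric nonnegative adjacency matrix
$W$ over a fixed, ordered gene universe $V$ of size $n$; the seed set
of disease $M$ is $V_M \subset V$.

## Ranking methods

**Random-walk kernels.** The one-step kernel is
$K = (a-1)I + D^{-1/2} W D^{-1/2}$ with $D$ the diagonal of row sums.
The normalized adjacency has spectrum in $[-1, 1]$, so any $a \ge 2$
makes $K$ positive semidefinite; the package requires $a > 1$ and
defaults to $a = 2$, the smallest PSD-guaranteeing choice. The $q$-step
kernel is the matrix power $K^q$: two genes become similar when joined
by paths of up to $q$ edges, so $q$ trades locality against depth of
topology exploitation. Genes with zero degree get a normalization entry
of 0 rather than a division by zero; they keep only the $(a-1)$
self-similarity.

**Kernelized score functions** rank gene $i$ by its kernel-space
proximity to the seed set:

* $S_{NN}(i) = \max_{j \in V_M} K(i,j)$ — nearest seed;
* $S_{kNN}(i) = \sum_{j \in I_k(i)} K(i,j)$ — sum over the $k$ most
  similar seeds (reduces to $S_{NN}$ at $k = 1$, saturates at
  $k \ge |V_M|$);
* $S_{AV}(i) = -\tfrac12 K(i,i) + \tfrac{1}{|V_M|}\sum_{j \in V_M}
  K(i,j)$ — average similarity penalized by self-similarity. When the
  kernel diagonal is constant the self term shifts every score equally,
  and `drop_self_term = TRUE` omits it without changing the ranking;
  $q$-step kernel diagonals are generally unequal, so the full form is
  the default.

**Random walks.** With the row-stochastic transition matrix
$Q = D^{-1}W$ and $p_0$ uniform on the seeds, RW iterates
$p_{t+1} = Q^T p_t$ for a fixed small number of steps — run long, the
walker forgets the seed information, which is why only a few steps are
useful. RWR restarts at the seeds with probability $\theta$ each step,
$p_{t+1} = (1-\theta) Q^T p_t + \theta p_0$, iterated to an L1
fixed-point tolerance of $10^{-10}$ (cap 1000 iterations). Zero-degree
rows of $Q$ get a self-transition of 1, so probability mass is
conserved exactly even on disconnected or aggressively filtered
networks — single pre-processed networks are connected by construction,
but integrated or intersected ones need not be.

**Guilt by association** is the baseline:
$S(i) = \max_{j \in V_M,\ (i,j) \in E} w_{ij}$, the strongest direct
edge into the seed set; it is applied to whatever network it is given,
raw or rescaled.

## Network pre-processing

Networks from different sources disagree in gene coverage, density and
weight scale. The pipeline addresses each in turn:

1. **Threshold filtering.** The automatic threshold is the minimum over
   nodes of each node's maximum incident weight; filtering keeps edges
   *at or above* the threshold, inclusively — the inclusive keep is
   what guarantees that no node loses its last edge. A network with an
   already isolated node has no defined threshold; callers choose
   between an error (default) and ignoring such nodes.
2. **Linear rescaling.** Surviving edge weights are mapped affinely
   onto $[0, 1]$. The minimum and maximum are taken over edges only:
   structural zeros mean "no evidence", not "evidence of weight 0",
   and including them would pin the minimum at 0 and defeat the purpose
   of cross-network comparability. If all edges share one weight the
   map is degenerate and all edges are set to 1, so binary networks
   pass through unchanged.
3. **Universe alignment.** Missing genes get zero rows/columns, and the
   set of genes each source actually covered is kept as a coverage
   mask — the per-edge average below needs it.

Filtering precedes rescaling; both steps are optional and
independently controllable in `preprocess_network()`.

## Network integration

Unweighted operators need no training:
UA, $\bar w_{ij} = \tfrac1n \sum_d w^d_{ij}$ (zeros included); PUA, the
same sum divided only by $|D(i,j)|$, the number of networks whose
coverage contains *both* genes — so a gene is not penalized for sources
that never measured it; MAX, the elementwise union; and MIN, the
intersection, in a drastic (plain minimum) and a soft (minimum over
nonzero weights) flavour. Coverage is gene-level, not edge-level,
exactly matching $D(i,j)$'s definition.

Weighted operators learn a reliability weight per network from the AUC
the prioritizer attains on each network alone:
$\gamma^d(k) = M^d(k) / \sum_j M^j(k)$ per disease $k$ (linear
transform, the default), or a logarithmic variant
$\log(1 - \min(M, b)) / \sum_j \log(1 - \min(M^j, b))$ with $b = 0.99$
bounding the metric away from 1, which emphasizes the strongest
networks. WAP fuses with per-disease weights (one network per disease;
flexible but overfit-prone with small seed sets); WA averages the
weights across diseases first, acting as a regularizer and producing a
single integrated network. All operators apply verbatim to kernel
matrices in place of adjacencies (`kernel_as_network()`), since only
the entries $w_{ij}$ are touched.

Integrated weights are not re-rescaled after combination: every
operator maps $[0,1]$ inputs into $[0,1]$ (weighted sums because the
$\gamma$ sum to 1), so a second rescaling would only re-stretch the
scale without changing comparability.

## Evaluation protocol

Disease sets are first filtered to sizes 5–200 inclusive: below 5 there
is too little prior information to learn from, above 200 the class is
too heterogeneous to be one ranking task.

**Cross-validation** is node-wise: the genes are randomly partitioned
into 5 folds; in turn one fold's labels are removed, the remaining
positives act as seeds, and the test fold's genes keep the resulting
scores. After all folds every gene has been scored exactly once as a
test gene, and the assembled ranking is evaluated with the AUC
(Mann–Whitney form, ties credited ½) and the precision at fixed recall
levels (default grid 0.1–1.0 in steps of 0.1), which matters because
many diseases have very few positives. Fold assignment is plain uniform
by default; an optional stratified mode spreads a positive set across
folds when sets are tiny. A fold that happens to contain every positive
gets zero scores with a warning rather than an error.

**Weighted-integration CV** nests a second, *internal*
cross-validation: within each external training split, the per-network
per-disease AUCs are estimated using only training genes (internal
5-fold by default; exact leave-one-out is supported at quadratic cost),
converted to $\gamma$, and the fused network rebuilt — so the weights
never see test-fold labels. A sentinel-label test in the suite asserts
this literally: replacing all labels outside the training split with
random genes leaves the estimated $\gamma$ bit-identical. Diseases with
fewer than two training positives cannot be internally validated and
contribute uniform weights.

**Permutation test.** Robustness per disease is assessed by redrawing
the positive set uniformly at random (equivalent to permuting labels)
1000 times on the *fixed* cross-validated score vector and counting the
times $m$ the shuffled AUC exceeds the true one; $p = m/1000$ exactly,
with the add-one estimator $(m+1)/(n+1)$ behind a flag. Reusing fixed
predictions rather than re-running the CV per shuffle keeps the null
conditional on the scores, which is the quantity actually reported.

**Candidate analysis.** For diseases ranked both accurately
(AUC $\ge$ 0.975) and robustly ($p < 0.01$), let $c$ be the lowest
score of an annotated gene; the empirical cumulative distribution of
all scores $\ge c$ (annotated and unannotated pooled) positions each of
the top 3 unannotated genes as a percentile,
$100 \cdot \#\{s \le s_i\} / \#\{s \ge c\}$. Percentiles near 100 mark
unannotated genes scoring on par with the best annotated ones. A top
unannotated gene scoring below $c$ lies outside the support; it is
assigned percentile 0 and flagged rather than extrapolated.

Ties anywhere in a ranking are broken lexicographically by gene
identifier, so all outputs are deterministic given a seed.

## The synthetic benchmark

`generate_fixture()` builds a fully synthetic, seed-deterministic
multi-network benchmark: diseases are random, possibly overlapping gene
subsets (overlap is deliberate — real annotation vocabularies overlap
heavily); each network plants edges between genes sharing a disease
with probability $p_{in}\iota + p_{out}(1-\iota)$ and between all other
pairs with $p_{out}$, where the per-network informativeness $\iota$
interpolates from pure noise ($\iota = 0$) to maximal signal
($\iota = 1$). Edge weights are lognormal jitter around 1
($\sigma = 0.25$), which makes linear rescaling non-trivial; an
optional coverage fraction removes genes from a network to exercise
PUA. Defaults — 500 genes, 20 diseases of 5–40 genes,
$p_{in} = 0.3$, $p_{out} = 0.02$, $\iota = (0.9, 0.5, 0.0)$ — are sized
so a full replicate (three single-network CVs, five unweighted
integrations, and the nested weighted CV) runs in seconds on one core;
the shipped end-to-end study (`planted_benchmark()`) uses 10 such
replicates.

One pipeline choice follows from the generator's design: on the
synthetic benchmark, pre-processing applies rescaling only, no
threshold filtering. The weight jitter exists to exercise rescaling and
is by construction independent of the planted signal, so filtering on
it removes signal and noise edges indiscriminately (and measurably
degrades every ranker). On real networks, where a weak weight encodes
weak evidence, threshold filtering is the appropriate default and
remains so in `preprocess_network()`.

What passing on this benchmark does — and does not — show: it
demonstrates that the rankers exploit planted topology, that the
weighted integration recovers the planted informativeness ordering,
and that intersection-style fusion collapses when one member is noise.
It does not emulate the degree heterogeneity, weight distributions or
correlated errors of real functional networks, so absolute AUC values
on the fixture say nothing about absolute performance on real data.
Retrospective benchmarks on real annotations are, in addition,
optimistic by circularity; only prospective validation settles a
candidate.

## Numerical choices and edge cases

* Duplicate edge records in input files keep the maximum weight
  (conservative union); self-edges are dropped; identifiers are opaque
  case-sensitive strings.
* Kernel powers use exponentiation by squaring; Gram matrices are
  symmetrized ($\tfrac12(K + K^T)$) on construction to absorb float
  asymmetry.
* RW/RWR conserve $\sum p = 1$ to $10^{-9}$ at every step (asserted in
  the suite); the RWR fixed-point residual is below its tolerance on
  return.
* $\gamma$ rows sum to 1 to $10^{-9}$; an all-zero metric row falls
  back to uniform weights with a warning.
* AUC is undefined (NA) when a class is empty; precision at recall uses
  the smallest cutoff whose recall reaches the level.

## Known limitations

* Dense $n \times n$ kernels bound practical universes to roughly
  $10^4$ genes on desktop memory; the adjacency side is sparse
  throughout.
* WAP materializes one integrated network per disease; with hundreds of
  diseases prefer WA (which is also the better-regularized method).
* The permutation test reuses fixed predictions; it quantifies label
  robustness of a given ranking, not variability of the training
  pipeline.
* No identifier mapping: callers must harmonize gene symbols before
  loading networks.
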