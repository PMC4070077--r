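# netprio

Network-based disease-gene prioritization: given the genes already
annotated to a disease ("seed" genes) and one or more weighted
functional gene networks, rank every other gene by its predicted
association with that disease. The package is aimed at computational
biologists who have heterogeneous gene-network evidence (physical
interactions, co-expression modules, shared chemical interactors,
semantic similarity, ...) and want both a ranking and an honest measure
of how much each evidence source contributes.

## What it implements

**Ranking methods.** Kernelized score functions on the q-step
random-walk kernel `K = ((a-1)I + D^(-1/2) W D^(-1/2))^q`:

* `S_NN(i) = max_{j in V_M} K(i,j)` (nearest seed),
* `S_kNN(i)` = sum of the k largest `K(i,j)` over seeds,
* `S_AV(i) = -K(i,i)/2 + mean_{j in V_M} K(i,j)` (average similarity);

random-walk label propagation `p <- t(Q) p` with `Q = D^(-1) W` (RW),
random walk with restart `p <- (1-theta) t(Q) p + theta p0` (RWR), and a
guilt-by-association baseline `S(i) = max_{j in V_M, (i,j) in E} w_ij`.

**Network integration** over a shared gene universe: unweighted
average (UA), per-edge average over covering networks only (PUA),
elementwise maximum (MAX), drastic/soft minimum (MIN), and AUC-weighted
averaging with per-disease (WAP) or class-averaged (WA) weights
`gamma_d(k) = M_d(k) / sum_j M_j(k)` estimated by internal
cross-validation, so the weights never see test labels. All operators
apply to kernel matrices as well as adjacencies.

**Evaluation protocol**: 5-200 disease-set size filter, node-wise
5-fold cross-validation, Mann-Whitney AUC and precision at recall,
1000-shuffle label-permutation p-values (`p = m/1000`), and an
ECDF-percentile analysis of the top unannotated candidates for
diseases with AUC >= 0.975 and p < 0.01.

**Infrastructure**: edge-list / bipartite-table / GMT / ranking readers
and writers, bipartite binary and SUM projections with cutoff
binarization, network pre-processing (degree-preserving threshold,
linear rescaling to [0, 1], universe alignment with coverage masks), a
deterministic planted-module benchmark generator, and a command-line
front-end (`exec/netprio`).

## Worked example

Generate a three-network benchmark (planted informativeness 0.9 / 0.5 /
0.0 over 300 genes and 8 diseases), estimate per-network reliability
weights, fuse with WA, and cross-validate the `S_AV` ranker:

```r
library(netprio)

fx   <- generate_fixture(fixture_spec(n_genes = 300, n_diseases = 8, seed = 42))
nets <- lapply(fx$networks, preprocess_network, threshold = NA)
col  <- network_collection(nets, attr(fx$networks, "universe"))

gamma <- estimate_internal_weights(col, fx$sets, method = "sav",
                                   params = list(a = 2, q = 3), seed = 42)
gamma
#> <gamma_weights> 8 class(es) x 3 networks (linear transform)
#> class-averaged gamma:
#> net1_iota0.90 net2_iota0.50 net3_iota0.00
#>        0.4049        0.3296        0.2655

fused  <- integrate_wa(col, gamma)
scorer <- make_scorer("sav", fused, list(a = 2, q = 3))
set.seed(42)
report <- cross_validate(scorer, fx$sets, cv_folds(attr(col, "universe"), f = 5))
report <- add_permutation_pvalues(report, fx$sets, n_shuffles = 1000, seed = 43)
report[, c("disease", "n_pos", "auc", "P@0.2", "m", "p_value")]
#>   disease n_pos   auc P@0.2 m p_value
#> 1     D01     5 0.854 1.000 0   0.000
#> 2     D02    29 0.993 1.000 0   0.000
#> 3     D03    14 0.886 1.000 0   0.000
#> 4     D04    40 0.998 1.000 0   0.000
#> 5     D05    22 0.926 1.000 0   0.000
#> 6     D06    28 0.999 1.000 0   0.000
#> 7     D07    11 0.777 0.143 1   0.001
#> 8     D08    40 0.996 1.000 0   0.000
```

The estimated `gamma` recover the planted ordering (the fully noisy
third network gets the smallest weight), and the fused network ranks
held-out disease genes nearly perfectly for the well-supported sets
(`auc` is the cross-validated area under the ROC curve; `P@0.2` the
precision at 20% recall; `m` counts how often 1000 random label
shuffles beat the true-label AUC, so `p_value = m/1000`). Candidate
genes for the robustly ranked diseases come from
`candidate_analysis(report, fx$sets)`: it reports each top unannotated
gene's percentile within the score distribution at or above the lowest
annotated-gene score — percentiles near 100 are the strongest
candidates.

The same pipeline runs from the shell:

```sh
Rscript exec/netprio simulate --out bench/ --seed 42
Rscript exec/netprio cv --nets bench/net1_iota0.90.tsv \
    --seeds bench/disease_sets.gmt --method sav --q 3 \
    --seed 7 --out report.tsv --rankings rankings/
Rscript exec/netprio candidates --report report.tsv --rankings rankings/
```

## Documentation

Every exported function carries roxygen documentation;
`vignettes/network-gene-prioritization.Rmd` describes the models, the
protocol, the synthetic benchmark's semantics and the package's design
and numerical choices in detail.
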