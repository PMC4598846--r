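---
title: "Ranking drug pairs for anticancer synergy: model and methods"
author: "racs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug pairs for anticancer synergy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racs)
```

# The problem

Known synergistic anticancer drug pairs are rare (a few dozen curated
pairs), while the candidate space is huge: even 118 agents yield 6,877
untested combinations. `racs` treats this as a semi-supervised ranking
problem: the known synergistic pairs act as labelled *bait*, every other
combination is unlabelled, and pairs are ranked by how close they sit to
the bait in a feature space that encodes how the two drugs jointly engage
a cancer-relevant protein-interaction network. A second, independent
stage then removes pairs whose transcriptomic responses show no
significant functional correlation.

This vignette describes the model, every tunable that matters, the
numerical conventions, and what the synthetic fixtures do and do not
establish.

# Stage 1: the seven pair features

Each drug contributes a target protein set; the network context is an
undirected background PPI graph `BD` with a designated cancer-network
node subset `CN` (supplied as an input — its construction from pathway
databases is upstream curation, not reproducible from first principles)
and the complement `NCN = BD \ CN`.

For a pair (x, y) with target sets M, N:

* **MI** — GO-based mutual information. Each drug's targets are mapped
  onto a fixed universe of cancer-related GO biological-process terms to
  give a binary fingerprint; with P(x), P(y) the mapped-term fractions
  and P(x, y) the jointly mapped fraction,
  `MI = P(x,y) log(P(x,y) / (P(x) P(y)))` (natural log, `0 log 0 = 0`).
  This pointwise form can go negative when two drugs share fewer terms
  than independence predicts.
* **Dis** — mean shortest-path distance in `BD` between all target
  pairs (i in M, j in N).
* **DCI** — drug-combination interference. With `E` the mean internode
  shortest-path distance of the CN ("information-sending efficiency")
  and `dE(T) = (E_after_removing_T - E) / E` the relative change caused
  by deleting target set T, `DCI = dE(M u N) - dE(M) - dE(N)`: positive
  when the combination perturbs the CN more than the two drugs added
  independently. The signed (not absolute) difference is used, since
  unlabelled pairs average below zero.
* **Eff.D / Eff.B / Eff.E** — efficacy under degree, betweenness and
  eigenvector centrality. For the union T of targets,
  `Eff = sum_{i in T n CN} W_i - lambda sum_{i in T n NCN} W_i`, with
  `W` the chosen centrality normalized to sum 1 over its scope: CN
  weights are computed on the CN-induced subgraph (therapeutic value is
  judged within the disease network), NCN weights on the full background
  graph (off-target liability is judged against the whole interactome).
  `lambda` balances benefit against liability; its default 0.1 is the
  operating point that best separates known synergistic pairs from the
  background.
* **MP.U** — the fraction of cross pathway pairs (one pathway hit by
  each drug) that are *unrelated*: not identical, not cross-talking,
  not interacting, per a symmetric relation table supplied as input
  (the cross-talk definitions live in upstream curation). Absent pairs
  default to unrelated; (p, p) is always identical.

**Disconnected graphs.** Shortest-path features need a convention for
unreachable node pairs: they contribute `Dmax + 1`, where `Dmax` is the
largest finite shortest-path length of the graph being measured,
recomputed on the perturbed graph after node deletion. This keeps means
finite without discarding information; the alternative (dropping
unreachable pairs) would silently reward fragmenting the network.

**Eigenvector centrality** is computed on the largest connected
component of each scope (convergence tolerance 1e-8); nodes outside it
get weight 0.

**Normalization and screening.** All features are min-max normalized to
[0, 1] using pooled labelled + unlabelled bounds (constant features map
to 0 with a warning). A two-sample Z statistic
`(mean_L - mean_U) / sqrt(s2_L/n_L + s2_U/n_U)` — a Welch-style standard
error, appropriate because the labelled group is tiny relative to the
unlabelled one — screens features; those with `|Z| > 3` (configurable)
enter the ranking.

# Stage 1: manifold ranking and the ensemble

Points (pairs) live in the normalized selected-feature space. A Gaussian
affinity `W_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))` with zero diagonal
is built; `sigma` defaults to the median pairwise distance (the median
heuristic: scale-free and deterministic). Scores solve the diffusion
fixed point

```
f = alpha S f + (1 - alpha) y,   S = D^{-1/2} W D^{-1/2}
```

with `y` the bait indicator and `alpha = 0.99` (the canonical value for
this family of ranking methods; configurable). The closed form
`f = (1 - alpha)(I - alpha S)^{-1} y` is used up to 5,000 points; larger
problems switch to fixed-point iteration (tolerance 1e-10), which the
test suite holds to within 1e-8 of the closed form. Baits are removed
from the output, and ties break lexicographically by pair id so the
ranking is a pure function of the inputs.

**kNN sparsification (a design decision made here).** On a *dense*
Gaussian affinity with `alpha` near 1, the diffusion score is dominated
by each point's global affinity degree: a large diffuse cloud of
unlabelled pairs accumulates more mass than a tight cluster around the
baits, and proximity to the baits stops mattering. We observed exactly
this on planted fixtures (the planted cluster, though nearest to the
baits, ranked near the bottom). The standard remedy in the
manifold-ranking literature is to restrict the graph to each point's k
nearest neighbours; `preliminaryRank()` therefore sparsifies the
affinity to the symmetrized k = 7 nearest neighbours by default
(`knn = NULL` restores the dense graph). k = 7 sits in the flat region
of the enrichment-vs-k curve on fixtures (k = 5..15 behaves similarly);
it was fixed once and not tuned per experiment.

**Ensemble and consensus.** Because the bait set is small and noisy, the
ranking is repeated `n_runs = 30` times, run r drawing a bait subsample
whose size cycles through 50%, 60%, ..., 100% of the positives (drawn
without replacement, seeded by `master_seed + r`; held-out baits are
excluded from the run — they are known positives, not queries). Pairs
that appear in the top fraction of at least a quorum of runs are kept,
and their consensus order minimizes the total Spearman footrule distance
`sum_runs sum_pairs |pos_consensus - pos_run|`. The minimization is
exact: assigning pairs to positions is a minimum-cost bipartite
assignment (costs `sum_runs |position - pos_run|`), solved by a
Hungarian/shortest-augmenting-path algorithm, which is cheap at
consistency-screen survivor counts. Ties among equal-cost optima resolve
by mean rank, then pair id.

At full scale the screen takes the top 1% of 6,877 pairs with a
unanimous quorum. At the desk-scale fixture (18 drugs, 143 unlabelled
pairs) a 1% slice is 2 pairs and unanimity over 30 subsampled runs is
degenerate, so the package's fixture studies use `top_fraction = 0.1`
(the top decile) with `quorum = 0.8`; both remain configurable and the
full-scale values stay the defaults.

# Stage 2: transcriptomic filtering

For drug pairs whose single-drug differential-expression gene (DEG) sets
A and B are both available:

* `DEG_Overlap = |A n B| / |A u B|` (Jaccard), and
* `Pathway_Coverage = |(A u B) n N| / |N|`, with `N` the gene set of the
  designated cancer pathway.

Each statistic gets a right-tailed permutation p-value: `n_perm`
(default 1,000) random gene-set pairs of the observed sizes are drawn
uniformly from the measured gene universe and the statistic recomputed;
`p = (1 + #(null >= observed)) / (n_perm + 1)` (pseudo-count form, so p
is never 0). A pair is retained only if **both** p-values fall below
0.05. Pairs with at most one DEG profile cannot be tested and are
retained with a `single_profile` flag, mirroring how such pairs are
handled in practice. Survivors keep their consensus order. The
permutation draws are independent across genes; preserving gene-gene
correlation would need the raw expression matrices, which are outside
this package's inputs. DEG derivation itself (thresholding fold
changes, microarray preprocessing) is likewise upstream: DEG sets are
inputs.

# Experimental synergy mathematics

Dose-response series follow the median-effect model
`fa / (1 - fa) = (D / Dm)^m`; the fit is the least-squares line of
`logit(fa)` on `log D`, which recovers `(Dm, m)` exactly on model data.
Points with `fa` outside [0.01, 0.99] — where MTT readouts saturate and
the logit explodes — are dropped with a warning rather than clamped
(clamping would bias otherwise exact fits).

For a fixed-ratio combination the combination index at effect level
`e` (default 0.5, the IC50) is `CI = d1/Dx1 + d2/Dx2`: the combination's
fitted total dose at `e` split by the mixing ratio, over the single-agent
doses achieving `e`. A pair is called **synergistic** only when all four
standard ratios (4:1, 3:2, 2:3, 1:4) give CI < 0.9, **strongly
synergistic** when all four are < 0.3, additive when all lie in
(0.9, 1.1), antagonistic when all exceed 1.1, and mixed otherwise.

Ranking quality is evaluated by:

* **PC-index** — probabilistic concordance with a noisy experimental
  ordering: pair-of-pairs (i, j) contributes
  `Phi(|s_i - s_j| / sqrt(sd_i^2 + sd_j^2))` when the predicted order
  matches the experimental mean order, the complement otherwise, 0.5
  for prediction ties. Gaussian independent replicate noise is assumed;
  this symmetric form guarantees an expectation of 0.5 under random
  ranking, which the calibration studies confirm.
* **ROC AUC** (Mann-Whitney form, ties 0.5) and the **true-positive
  rate** of the top-k predictions.
* **Fisher's exact test** (two-sided, probability-mass rule) comparing
  confirmed/failed counts between predicted and randomly selected
  pairs — the pick-up-rate comparison.

# Synthetic fixtures: what they emulate

`simulateRacsInputs()` materializes a complete study: a
preferential-attachment background network (heavy-tailed degrees, as in
real PPI data — this matters because two of the efficacy weights are
centrality-based), a cancer network grown greedily around the top hub, a
drug library in which a designated cluster of drugs draws targets from
CN hubs and pathways from a shared pool, bait pairs inside that cluster,
DEG sets in which planted pairs share a common core drawn from the
cancer pathway, and median-effect dose-response curves built under Loewe
additivity with a potency multiplier (1 = additive ground truth, 2 =
planted CI 0.5).

Defaults (chosen once as a realistic desk scale): 100 proteins, CN of
30, 18 drugs with 3 targets each, cluster of 8, 10 bait pairs, 60 GO
terms, 20 pathways, 1,000-gene universe, DEG sets of 50, overlap boost
0.5, plant strength 0.9. Every generator is a pure function of its
arguments and seed.

What passing fixture tests shows: each stage recovers structure it was
built to detect, end to end, at the stated noise levels. What they do
not show: performance on real pharmacology — real target annotations
are incomplete and biased, real DEG sets are correlated across genes
and cell-line specific, and real synergy labels are noisy in ways no
multiplier emulates. The fixtures validate the machinery, not the
biology.

# Numerical choices and degenerate inputs

* Unreachable distances: `Dmax + 1` convention (above), configurable by
  preprocessing the graph instead.
* Affinity: zero diagonal; isolated points receive `(1 - alpha) y`.
* Permutation p-values: pseudo-count `(b + 1)/(n + 1)`.
* Footrule ties: mean rank then lexicographic id, implemented as an
  epsilon perturbation (< 1 total over integer costs) of the assignment
  problem, so determinism never trades against optimality.
* Degenerate inputs fail loudly: empty term universe, CN smaller than 2
  nodes after target removal, zero-variance features in both groups,
  single-class labels, all-equal truth scores with zero SD.
* Drugs with no targets, pairs with unmappable targets or empty pathway
  sets are excluded with explicit warnings naming the item; exclusion
  is never silent.

# Problem sizes used in the shipped studies

The bundled tests and the reproduction script run at deliberately
modest sizes — 18-drug / 100-protein fixtures, ensembles of 10-30 runs,
permutation nulls of 200-1,000 draws, Monte-Carlo calibrations of
10,000 draws — chosen so the whole suite completes in minutes on one
core while leaving every statistical check comfortably powered.

# Known limitations

* The CN is an input; no attempt is made to derive it from pathway
  databases.
* Identifier namespaces are taken at face value (case-sensitive string
  match); cross-database mapping is the caller's responsibility.
* The dense-affinity behaviour at `alpha` near 1 (degree domination) is
  inherent to the method; the kNN default mitigates it but k is a
  genuine tunable.
* The PC-index's replicate-noise model is Gaussian and independent;
  replicate distributions with heavy tails would need a different
  kernel.
* DCI recomputes CN shortest paths per pair; at tens of thousands of
  pairs with a large CN this is the dominant cost and would benefit
  from incremental all-pairs updates, which are not implemented.
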