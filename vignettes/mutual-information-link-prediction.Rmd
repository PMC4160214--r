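---
title: "Link prediction from the mutual information of network structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link prediction from the mutual information of network structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milink)
```

## The problem and the model

Given the observed links of an undirected simple network — a protein–protein
interaction map, a router topology, a citation graph — which of the
non-linked node pairs are most likely to be missing links? Neighbourhood
indices answer by scoring each candidate pair from local topology. The
mutual-information (MI) index treats this as an information-theoretic
question: a link's plausibility is the negation of its conditional
self-information given what the pair's common neighbours reveal,

$$ s_{xy} = \sum_{z \in O_{xy}} I(z) - I(L^1_{xy}), $$

with all logarithms base 2 (scores in bits).

**The prior term.** Assuming no degree–degree correlation, the probability
that a pair with training degrees $k_x, k_y$ is *disconnected* is the
hypergeometric-style ratio
$p(L^0_{xy}) = \binom{M-k_x}{k_y}/\binom{M}{k_y}$, where $M$ is the number
of links in the training graph; it is symmetric in the two degrees and
non-increasing in each. Then $I(L^1_{xy}) = -\log_2(1 - p(L^0_{xy}))$.
Binomial coefficients are evaluated in log-space (`lchoose`) so large $M$
cannot overflow; the values are unchanged.

**The mutual-information term.** Each common neighbour $z$ contributes its
*average* mutual information over its neighbour pairs,
$I(z) = \mathrm{mean}_{\{m,n\} \subseteq \Gamma(z)}
 \left[ I(L^1_{mn}) + \log_2 C_z \right]$,
where $C_z = N_{\Delta z}/(N_{\Delta z} + N_{\Lambda z})$ — the fraction of
$z$'s neighbour pairs that are themselves linked, i.e. its local clustering
coefficient — estimates the conditional probability that a pair is linked
given $z$ is a common neighbour. Contributions from different common
neighbours are assumed independent and added.

$I(z)$ can be negative: a node whose neighbourhood almost never closes into
triangles is *evidence against* links among its neighbours. And with
$O_{xy} = \varnothing$ the score degrades gracefully to the prior term, so
the index still orders zero-common-neighbour pairs by their degrees — the
regime responsible for most of its advantage on very sparse networks, where
the counting indices tie all such pairs.

## Numerical conventions and degenerate inputs

* **Stipulation at $C_z = 0$.** If none of $z$'s neighbour pairs is linked,
  the conditional self-information $-\log_2 C_z$ is infinite. The package
  stipulates that such a node contributes $I(z) = 0$, as does any node of
  degree < 2 (no neighbour pairs). This choice avoids infinite penalties
  from never-closed triads and is isolated in one function
  (`mi_node_information`) so a different stipulation is a one-line change.
* **Degree-0 endpoints.** After probe removal a training node can have
  degree 0. Its prior leaves no probability for a link, so the pair's score
  is $-\infty$ — an ordered sentinel that ranks below every finite score
  and keeps the ranking total.
* **Tie-breaking.** Rankings sort by descending score, then lexicographic
  pair label. Precision at $L$ can change by up to a tie-block under random
  tie order; the deterministic rule makes every reported number exactly
  reproducible.
* **Training-only estimation.** Degrees, $M$, triad counts and $C_z$ are
  always computed on the training graph; probe links never leak into any
  score.

## Reference indices

Six standard common-neighbour indices are provided for comparison: CN
($|O_{xy}|$), RA ($\sum_{z} 1/k_z$), the local naive Bayes variants LNB-CN
($\sum_z \log_2(s R_z)$, with prior odds $s = (N(N-1)/2 - M)/M$ and
smoothed role factor $R_z = (N_{\Delta z}+1)/(N_{\Lambda z}+1)$) and LNB-RA
(each term weighted by $1/k_z$), and the local-community pair CAR
($|O_{xy}| \cdot \tfrac12 \sum_z |\gamma(z)|$, $\gamma(z) = \Gamma(z) \cap
O_{xy}$) and CRA ($\sum_z |\gamma(z)|/k_z$). $\gamma(z)$ is computed per
candidate pair rather than cached globally — correctness over speed. On
triangle-free graphs CAR and CRA are identically zero for every candidate
pair, which is why they fail on sparse, weakly clustered networks. A
`"random"` pseudo-index (i.i.d. uniform scores) is included to calibrate
the evaluation machinery at AUC 0.5.

## Evaluation protocol

`split_train_probe()` hides a uniformly random fraction of links (default
0.1, the conventional 90/10 division) as the probe set; training
connectivity is deliberately not enforced, since the division is defined as
purely random. AUC is the probability that a random probe link outscores a
random non-existent pair, ties counted half: the default **exact** mode
evaluates all comparisons through a rank-sum identity, removing the
undocumented degree of freedom of sampled estimation; **sampled** mode
(`n` comparisons) is provided for very large candidate sets and converges
to the exact value. Precision@L is the fraction of probe links among the
top $L$ (default 100). `run_experiment()` repeats the split over `runs`
(default 100) seeds derived deterministically from a master seed.

## Structural statistics

`summary_stats()` reports $N$, $M$, network efficiency (mean of $1/d_{ij}$
over ordered pairs), mean local clustering (degree-<2 nodes contribute 0 —
the average-local convention, not the transitivity ratio; the two differ),
assortativity $r$ (Pearson correlation of excess degrees over both
orientations of each edge — the formulation under which the decomposition
below holds), degree heterogeneity $H = \langle k^2 \rangle / \langle k
\rangle^2$ ($= 1$ exactly for regular graphs), mean degree and mean
shortest distance (unordered pairs, BFS). Mean distance over unordered
versus ordered pairs is a documented convention choice; for an undirected
graph the two coincide.

The MI derivation assumes an uncorrelated network, yet works well on
globally assortative ones. The diagnostic is **local assortativity**
$$ \rho_v = \frac{(j_v + 1)\left(j_v \bar{k}_v - \mu_q^2\right)}
                 {2 M \sigma_q^2}, $$
with $j_v$ the excess degree (degree minus one), $\bar{k}_v$ the mean
excess degree of $v$'s neighbours and $\mu_q, \sigma_q$ the moments of the
excess-degree distribution sampled at a random edge end. The node values
sum exactly to $r$, and their cumulative distribution
(`local_assortativity_cdf`) typically shows most nodes near 0 even when $r$
is large — locally, the uncorrelated assumption holds. On a regular graph
$\sigma_q = 0$ and both $r$ and $\rho_v$ are the same $0/0$ degeneracy;
the package returns `NA` rather than inventing a value.

## Synthetic data: what it emulates, and what it does not

The generators make every stage testable without external downloads.
`erdos_renyi(n, p)` is the clustering-free null; `watts_strogatz(n, k,
beta)` produces the sparse, highly clustered, homogeneous-degree regime
where triad-based inference helps (edge count pinned at $nk/2$ by
duplicate-avoiding rewiring); `barabasi_albert(n, m)` produces heavy-tailed
degrees (seed clique on $m+1$ nodes, attachment without replacement, so the
edge count is exact and deterministic by seed). Small hard-coded fixtures —
notably `k4_minus_edge`, whose sole candidate pair (3,4) has the
hand-expanded score $2 \times (-0.3121) - 0.5146 = -1.1388$ bits — anchor
the worked examples.

These graphs do not reproduce the community structure, motif spectrum or
measurement biases of real interactomes. A green test suite therefore
establishes that the indices compute their definitions exactly and that the
evaluation machinery is calibrated (random scores give AUC 0.5; the
assortativity decomposition sums to $r$ to $10^{-8}$) — not that any
particular AUC will be attained on a given real dataset, which additionally
depends on dataset version and curation. Published headline numbers on
named PPI or router networks require those exact edge lists; with a
user-supplied file, `read_edge_list() |> giant_component() |>
run_experiment()` reproduces that pipeline.

## Design choices made here

* The exact algebraic form of the degree prior and of the LNB constant were
  fixed to the standard forms stated above and frozen against independent
  brute-force transcriptions (tolerance $10^{-9}$) before any evaluation
  was run.
* Whether the CAR $|\gamma(z)|/2$ factor sits inside or outside the sum
  does not change any ranking; the package keeps the global
  $\tfrac12\sum_z|\gamma(z)|$ form (links among common neighbours).
* Per-run seeds are drawn once from the master seed (`sample.int` under
  `set.seed(master)`), capped below $2^{31}$ so derived offsets remain
  valid R integers.
* The optional YAML mirror of the CLI flags was dropped: no YAML parser is
  available to R in the supported environment, and flags cover every
  option.

## Known limitations

Scoring all candidate pairs is $O(N^2)$ in memory for the ranking table;
graphs beyond a few thousand nodes should be evaluated with sampled AUC
and a restricted candidate set. The independence assumption across common
neighbours ignores correlations within dense communities, where the
LCP-style indices (CAR/CRA) can rank the very top of the list better even
while their global AUC is worse. Weighted, directed and bipartite networks
are out of scope.
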