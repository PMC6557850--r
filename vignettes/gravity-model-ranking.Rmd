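---
title: "Ranking influential spreaders with gravity-model centralities"
author: "gravityrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking influential spreaders with gravity-model centralities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravityrank)
```

## The problem

In epidemiology, information diffusion and systems biology alike, a few
well-placed nodes dominate how far a spreading process reaches: a
superspreader can blow up an epidemic, a hub protein can be an essential
drug target. Given only the topology of an undirected contact network, which
nodes should be ranked as the most influential spreaders?

Classical answers use either *neighbourhood* information (degree, the
node-level H-index, the k-shell index from iterative core decomposition) or
*path* information (closeness, betweenness). The gravity model combines the
two.

## The gravity model and its local variant

Treating a node's degree $k_i$ as its mass and the shortest-path hop count
$d_{ij}$ as distance, the gravity centrality of node $i$ is

$$S(i) \;=\; \sum_{j \neq i} \frac{k_i\, k_j}{d_{ij}^2},$$

a sum over every node $j$ reachable from $i$ (unreachable pairs contribute
0, the natural $d \to \infty$ limit). A node scores highly when it has many
connections *and* sits close to the rest of the network.

Two practical problems motivate the local variant: all-pairs shortest paths
are expensive on large graphs, and interaction strength estimated across
many hops mostly accumulates noise. Truncating the sum at a hop radius $R$
gives the local gravity centrality

$$S_R(i) \;=\; \sum_{d_{ij} \le R,\; j \neq i} \frac{k_i\, k_j}{d_{ij}^2},$$

computed here by a radius-limited breadth-first search per node — the full
distance matrix is never materialised for the local model. For $R$ at least
the component diameter, $S_R = S$ exactly (the package guarantees this bit
for bit by accumulating both sums in the same order).

Two related benchmarks use the same gravity form with k-shell indices
$k_s$ as masses: $G(i) = \sum_{0 < d_{ij} \le 3} k_s(i) k_s(j) / d_{ij}^2$
(fixed radius 3, not a parameter), and its neighbour sum
$G_+(i) = \sum_{j \in \Lambda_i} G(j)$. Note that $G$ and $G_+$ are global
indices in disguise: computing any k-shell index requires the whole graph,
whereas $S_R$ needs only the radius-$R$ neighbourhood.

```{r}
net <- generateNetwork("barabasi_albert", 100, m = 3, seed = 1)
head(rankTable(localGravityModel(net, R = 2)))
```

## Ground truth: SIR spreading influence

A ranking method is judged by how well it predicts *simulated* spreading
influence. The package implements synchronous discrete-time
susceptible–infected–recovered dynamics: starting from one infected seed,
each step every infected node independently infects each currently
susceptible neighbour with probability $\beta$, and every node that was
infected at the start of the step then recovers with probability $\lambda$
(a node infected within a step cannot recover in that same step). When no
infected nodes remain, the seed's influence is the outbreak fraction
$F = N_r / N$, the recovered share of the network.

The protocol fixes $\lambda = 1$, under which each infected node makes
exactly one round of infection attempts: the process is then equivalent to
bond percolation with open-edge probability $\beta$, which is what the
exhaustive $2^E$ test oracle enumerates. The transmission probability
defaults to the heterogeneous mean-field epidemic threshold

$$\beta_c \;\approx\; \frac{\langle k\rangle}{\langle k^2\rangle - \langle k\rangle}
\;=\; \frac{1}{H\langle k\rangle - 1}, \qquad
H = \frac{\langle k^2\rangle}{\langle k\rangle^2},$$

the regime where ranking quality is hardest and most informative: far below
$\beta_c$ nothing spreads, far above it everything does and all rankings
collapse into ties. The algebraic identity between the two forms above is
enforced to $10^{-12}$ in the tests. On very sparse graphs the mean-field
expression can exceed 1; the command-line default caps it at 1.

`standardRanking()` estimates each node's mean $F$ over `runs` independent
realisations (default 1000, the standard protocol). Every (node, run) pair
draws from its own substream derived from the base seed, so results are
bit-reproducible and independent of evaluation order — a prerequisite for
any future parallel evaluation.

```{r}
cfg <- SIRConfig(beta = min(1, epidemicThreshold(net)), lam = 1,
                 runs = 200, seed = 42)
std <- standardRanking(net, cfg)
std
```

## Scoring rankings: the tie-aware Kendall tau

Accuracy is the Kendall rank correlation between a centrality's scores and
the simulated influences,

$$\tau = \frac{2\,(n_+ - n_-)}{N(N-1)},$$

where a node pair is concordant ($n_+$) when both sequences order it the
same way, discordant ($n_-$) when they disagree, and a pair tied in either
sequence counts in *neither* — while the denominator stays the full
$N(N-1)$. This is deliberately **not** the tie-corrected $\tau_b$ that
`cor(..., method = "kendall")` computes: $\tau_b$ rescales by the tie
structure, which would silently change accuracy values for methods with
many ties (k-shell, H-index). `kendallTau()` implements the literal form
with an $O(N \log N)$ merge-count; the $O(N^2)$ pair enumeration survives
only as a test oracle.

One consequence worth knowing: a sequence correlated with an identical copy
of itself scores $1 - 2t/(N(N-1))$ where $t$ is its number of tied pairs —
*not* 1. On a completely regular graph, where every centrality is constant,
every $\tau$ is 0. This is the definition's behaviour, not an artefact.

```{r}
rankingAccuracy(net, std, R = 2)
```

On a Barabási–Albert graph grown from a complete seed clique with $m = 3$,
every node has coreness exactly 3, so the k-shell ranking is one giant tie
and its $\tau$ is 0 — a compact illustration of why pure coreness fails on
networks with a homogeneous core, and why the distance-weighted $G$, $G_+$
and the gravity models do not inherit the problem.

## Choosing the truncation radius

`sweepRadius()` evaluates $S_R$ against the standard ranking for
$R = 1, \dots, R_{\max}$ (default: the diameter of the largest component)
and reports the empirically optimal radius $R^*$, breaking ties toward the
smallest — cheaper — radius. Empirically $R^*$ tracks half the average
shortest-path distance,

$$R^* \approx \tfrac{1}{2}\langle d\rangle,$$

which `predictRadius()` rounds to the nearest integer with half-integers
rounded down (so $\langle d\rangle = 4.03$ predicts $R = 2$) and floors at
1. Because real networks are small worlds, this predicted radius is small
and the local model is cheap.

`consecutiveRadiusSimilarity()` computes the purely deterministic
$\tau$ between the $S_R$ and $S_{R+1}$ score vectors: it rises quickly with
$R$, confirming that enlarging an already moderate radius barely changes
the ranking.

```{r}
prof <- sweepRadius(net, std)
prof
consecutiveRadiusSimilarity(net, max(2, max(prof@radii)))
```

## Design choices on degenerate inputs

* **Disconnected graphs.** All distance-based sums run over reachable pairs
  only; the average distance is taken over the largest connected component;
  closeness is evaluated per component with the component size substituted
  for $N$ (isolated nodes score 0). The CLI warns when the input is
  disconnected. This keeps every statistic finite without inventing a value
  for infinite distances.
* **Betweenness pair convention.** The sum runs over unordered pairs
  $\{s,t\}$, endpoints excluded, with fractional counting over all
  geodesics — the standard undirected convention. Rank correlations are
  invariant to the ordered/unordered factor of two.
* **Edge-list input.** Whitespace-separated label pairs; `#` comments and
  blank lines ignored; direction ignored; duplicates collapsed; self-loops
  dropped; labels kept verbatim; first appearance fixes internal order.
* **No normalisation anywhere.** All scores are raw; every comparison is by
  rank correlation, which is invariant under monotone transforms.
* **Ties in output rankings.** `rankTable()` breaks score ties by label so
  the printed ranking is reproducible; tie order cannot affect $\tau$.

## What the synthetic generators do and do not cover

Tests and examples run entirely on in-package generators: deterministic
families (path, star, cycle, complete, tree) with closed-form statistics,
and seeded random families (Erdős–Rényi, Watts–Strogatz, Barabási–Albert
grown from a complete clique on $m+1$ nodes, so $E = \binom{m+1}{2} +
m(n-m-1)$ and the minimum degree is $m$). These reproduce the features the
method actually exploits — heterogeneous degrees, short distances,
clustering — but not every property of real contact networks: no degree
correlations by design, no community structure, and (for BA) a degenerate
one-shell core structure. Passing tests therefore certify the
*implementation* (formulas, oracles, invariants), not the empirical
performance ordering of the methods on any particular real network, which
must be measured per network with `rankingAccuracy()`.

Problem sizes were chosen so the full suite exercises every code path in
well under a minute of simulation: oracle comparisons use graphs of at most
8–10 nodes (where exhaustive enumeration is exact), Monte-Carlo checks use
20 000 runs on graphs with at most 12 edges (3-standard-error agreement
with the exact percolation expectation), and the end-to-end pipeline runs
on a 200-node scale-free network with the standard 1000 runs per seed.

## Known limitations

* Unweighted, undirected, static graphs only; no SIS/SEIR variants and no
  continuous-time (Gillespie) dynamics. $\lambda < 1$ is supported by the
  simulator but the percolation oracle only covers $\lambda = 1$.
* The mean-field $\beta_c$ ignores degree correlations and clustering; on
  strongly assortative or clustered networks the true threshold differs.
* The $R^* \approx \langle d\rangle/2$ heuristic is empirical; networks
  with an unusually deep core (e.g. some email networks) can prefer a much
  larger $R^*$ while losing little accuracy at the predicted radius.
* The exponents in $k_i k_j / d_{ij}^2$ are fixed; tunable-exponent,
  topology-dependent and asymmetric gravity variants are out of scope.
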