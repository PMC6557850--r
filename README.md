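# gravityrank

Identifying **influential spreaders** in undirected networks with
gravity-model centralities, and validating any node ranking against
simulated epidemic spreading.

Who is a network's best seed for a spreading process — the patient zero
that maximises an outbreak, the account that maximises a cascade? Degree,
H-index and k-shell look only at a node's neighbourhood; closeness and
betweenness only at paths. The gravity model combines both: treating the
degree `k_i` as a mass and the shortest-path hop count `d_ij` as a
distance, it scores node `i` as

    S(i) = sum_{j != i} k_i * k_j / d_ij^2

and its **local** variant truncates the sum at a hop radius `R`
(`S_R(i)`, summing only over `d_ij <= R`), which is both cheaper and less
exposed to noisy long-range interactions. Empirically the best radius
tracks half the network's average distance, `R* ~ <d>/2`.

The package provides, as S4 classes with accessors:

* `gravityModel()` / `localGravityModel()` — the two gravity centralities;
* seven benchmarks: `degreeCentrality()`, `hIndex()`, `kShell()`,
  `closenessCentrality()`, `betweennessCentrality()`, and the
  k-shell-mass gravity pair `gravityCentrality()` (G) /
  `extendedGravityCentrality()` (G+);
* `standardRanking()` — ground-truth influence of every node as the mean
  final outbreak fraction `F = N_r / N` of a discrete-time SIR simulation
  (infection probability `beta`, recovery probability `lambda`, default
  protocol `lambda = 1`, 1000 runs per seed node, `beta` at the epidemic
  threshold `beta_c = <k> / (<k^2> - <k>)`);
* `kendallTau()` — the tie-aware rank correlation
  `tau = 2(n+ - n-) / (N(N-1))` (tied pairs count in the denominator but
  in neither term), plus `rankingAccuracy()`, `sweepRadius()`,
  `predictRadius()` and `consecutiveRadiusSimilarity()` for evaluation;
* `readEdgeList()` / `writeEdgeList()` for plain-text edge lists,
  `networkSummary()` for the standard eight-statistic topology row,
  `generateNetwork()` for synthetic test networks, and brute-force oracles
  (`bruteForceDistances()`, `bruteForceBetweenness()`,
  `exhaustiveSirExpectation()`) used by the test suite.

## Worked example

```r
library(gravityrank)

net <- generateNetwork("barabasi_albert", 100, m = 3, seed = 1)
networkSummary(net)
#> SummaryStats
#>   N              100
#>   E              294
#>   mean_degree    5.88
#>   mean_distance  2.60566
#>   clustering     0.133276
#>   assortativity  -0.162855
#>   heterogeneity  1.59945
#>   threshold      0.11898

cfg <- SIRConfig(beta = min(1, epidemicThreshold(net)), lam = 1,
                 runs = 200, seed = 42)
std <- standardRanking(net, cfg)          # simulated ground truth
rankingAccuracy(net, std, R = 2)
#>   method      beta  R       tau
#> 1     bc 0.1189802 NA 0.4846465
#> 2     cc 0.1189802 NA 0.7337374
#> 3     dc 0.1189802 NA 0.5761616
#> 4 hindex 0.1189802 NA 0.5264646
#> 5 kshell 0.1189802 NA 0.0000000
#> 6      g 0.1189802 NA 0.7658586
#> 7  gplus 0.1189802 NA 0.7749495
#> 8     gm 0.1189802 NA 0.7286869
#> 9    lgm 0.1189802  2 0.7622222

sweepRadius(net, std)
#> RadiusProfile: R = 1..5, optimal R* = 1, predicted R = 1
#>   tau: R=1:0.7673  R=2:0.7622  R=3:0.7335  R=4:0.7287  R=5:0.7287

head(rankTable(localGravityModel(net, R = 2)), 3)
#>   node   score
#> 1    3 6238.75
#> 2    7 6028.00
#> 3    5 4797.50
```

Reading the output: the gravity family (`g`, `gplus`, `lgm`, `gm`) tracks
the simulated influence ranking much more closely (tau ≈ 0.73–0.77) than
degree, H-index or betweenness, and the local model at small `R` already
matches or beats the full model — here the optimal truncation radius R\* = 1
coincides with the `<d>/2` prediction (`<d>` ≈ 2.6). The k-shell tau of 0
is real: a Barabási–Albert graph grown with `m = 3` has coreness 3
everywhere, so that ranking is one giant tie and, under the literal
tie rule, contributes no concordant pairs.

A command-line interface over the same functions ships with the package
(`stats`, `rank`, `evaluate`, `sweep` subcommands):

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "gravityrank.R", package = "gravityrank"))')
Rscript "$CLI" rank my.edges --method lgm --out ranking.tsv
Rscript "$CLI" evaluate my.edges --runs 1000 --seed 1
```

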