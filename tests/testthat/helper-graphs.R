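# Fixture builders and independent brute-force helpers shared across tests.

pathNet <- function(n) generateNetwork("path", n)
starNet <- function(leaves) generateNetwork("star", leaves)
cycleNet <- function(n) generateNetwork("cycle", n)
completeNet <- function(n) generateNetwork("complete", n)

netFromLines <- function(txt) readEdgeList(textConnection(txt))

# triangle a-b-c plus pendant d attached to a
trianglePendant <- function() netFromLines("a b\nb c\nc a\na d")

# small Erdos-Renyi sample with a fixed seed per draw
randomNet <- function(n, p, seed) {
  generateNetwork("erdos_renyi", n, p = p, seed = seed)
}

# O(N^2) pair-enumeration Kendall tau: the literal definition, used as the
# oracle for the merge-count implementation
tauOracle <- function(x, y) {
  n <- length(x)
  sxy <- sign(outer(x, x, "-")) * sign(outer(y, y, "-"))
  up <- upper.tri(sxy)
  2 * (sum(sxy[up] > 0) - sum(sxy[up] < 0)) / (n * (n - 1))
}

# relabel a network by a permutation of its labels (old label -> new label)
permuteLabels <- function(net, perm) {
  g <- asIgraph(net)
  g2 <- igraph::set_vertex_attr(g, "name",
                                value = unname(perm[igraph::V(g)$name]))
  asNetwork(g2)
}
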