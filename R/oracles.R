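# Brute-force reference computations. Deliberately naive and independent of
# the production code paths (and of igraph's algorithms), so they can serve
# as oracles in tests. They refuse to run above small size guards instead of
# running forever.

#' Brute-force all-pairs shortest distances
#'
#' Floyd-Warshall triple loop over the full matrix. Reference oracle for the
#' BFS distance field; unreachable pairs are \code{Inf}.
#'
#' @param net a [Network-class] with at most 200 nodes.
#' @return numeric N x N matrix with node labels as dimnames.
#' @export
bruteForceDistances <- function(net) {
  n <- numNodes(net)
  if (n > 200)
    stopParameter("bruteForceDistances is guarded at N <= 200 (got %d)", n)
  lab <- nodeLabels(net)
  D <- matrix(Inf, n, n, dimnames = list(lab, lab))
  if (n > 0) diag(D) <- 0
  el <- igraph::as_edgelist(asIgraph(net), names = FALSE)
  for (e in seq_len(nrow(el))) {
    D[el[e, 1], el[e, 2]] <- 1
    D[el[e, 2], el[e, 1]] <- 1
  }
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j])
          D[i, j] <- D[i, k] + D[k, j]
  D
}

# all geodesics from s to t as lists of vertex indices, by DFS over the
# BFS-distance DAG
enumerateGeodesics <- function(adj, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  extend <- function(pathSoFar) {
    v <- pathSoFar[length(pathSoFar)]
    if (v == t) return(list(pathSoFar))
    nxt <- adj[[v]][D[adj[[v]], t] == D[v, t] - 1]
    out <- list()
    for (u in nxt)
      out <- c(out, extend(c(pathSoFar, u)))
    out
  }
  extend(s)
}

#' Brute-force betweenness by explicit geodesic enumeration
#'
#' Enumerates every shortest path between every unordered node pair and
#' counts, per inner node, the fraction of each pair's geodesics passing
#' through it. Reference oracle for [betweennessCentrality()].
#'
#' @param net a [Network-class] with at most 10 nodes.
#' @return a [ScoreVector-class].
#' @export
bruteForceBetweenness <- function(net) {
  n <- numNodes(net)
  if (n > 10)
    stopParameter("bruteForceBetweenness is guarded at N <= 10 (got %d)", n)
  adj <- adjList(net)
  D <- bruteForceDistances(net)
  bc <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        paths <- enumerateGeodesics(adj, D, s, t)
        if (length(paths) == 0) next
        for (pth in paths) {
          inner <- pth[-c(1, length(pth))]
          bc[inner] <- bc[inner] + 1 / length(paths)
        }
      }
    }
  }
  newScores(net, "bc_oracle", bc)
}

#' Exact SIR outbreak expectation by percolation enumeration
#'
#' With recovery probability 1 every infected node attempts each susceptible
#' neighbour exactly once, so the final recovered set is the seed's cluster
#' under independent bond percolation with open probability beta. This
#' enumerates all 2^E open/closed edge configurations, weighting each by
#' beta^open (1-beta)^closed, and returns the exact expected outbreak
#' fraction E\[F\].
#'
#' @param net a [Network-class] with at most 20 edges.
#' @param seedNode label of the seed node.
#' @param beta infection probability in \[0, 1\].
#' @return exact E\[F\] as a single number.
#' @examples
#' net <- readEdgeList(textConnection("a b"))
#' exhaustiveSirExpectation(net, "a", 0.5)  # (1 + 0.5)/2
#' @export
exhaustiveSirExpectation <- function(net, seedNode, beta) {
  e <- numEdges(net)
  if (e > 20)
    stopParameter("exhaustiveSirExpectation is guarded at E <= 20 (got %d)", e)
  if (beta < 0 || beta > 1) stopParameter("beta must be in [0, 1]")
  s <- nodeIndex(net, seedNode)
  n <- numNodes(net)
  el <- igraph::as_edgelist(asIgraph(net), names = FALSE)
  reachCount <- function(open) {
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (ei in which(open)) {
        a <- el[ei, 1]; b <- el[ei, 2]
        if (seen[a] && !seen[b]) nxt <- c(nxt, b)
        if (seen[b] && !seen[a]) nxt <- c(nxt, a)
      }
      nxt <- unique(nxt)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    sum(seen)
  }
  if (e == 0) return(1 / n)
  ef <- 0
  for (mask in 0:(2^e - 1)) {
    open <- bitwAnd(mask, bitwShiftL(1L, seq_len(e) - 1L)) > 0
    nOpen <- sum(open)
    w <- beta^nOpen * (1 - beta)^(e - nOpen)
    if (w == 0) next
    ef <- ef + w * reachCount(open) / n
  }
  ef
}
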