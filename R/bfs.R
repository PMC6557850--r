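# Frontier-at-a-time BFS over the adjacency list. Expansion stops at
# maxRadius rather than filtering a full distance field afterwards, so the
# truncated gravity sum never pays for the whole component.
bfsDistances <- function(adj, src, maxRadius = Inf) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  frontier <- src
  d <- 0L
  while (length(frontier) > 0 && d < maxRadius) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    if (length(nxt) == 0) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' BFS shortest-path distances from one node
#'
#' Hop counts from \code{source} to every reachable node, optionally stopping
#' at a maximum radius. This radius-limited BFS is the primitive behind the
#' local gravity model's truncation.
#'
#' @param net a [Network-class].
#' @param source node label.
#' @param maxRadius optional integer radius \eqn{\ge 1}; when given, only
#'   nodes within \code{maxRadius} hops are returned.
#' @return named integer vector of distances over the reachable nodes
#'   (unreachable nodes are absent); \code{source} itself maps to 0.
#' @examples
#' net <- readEdgeList(textConnection("a b\nb c\nc d"))
#' shortestPathsFrom(net, "a")               # a=0 b=1 c=2 d=3
#' shortestPathsFrom(net, "a", maxRadius = 2)
#' @export
shortestPathsFrom <- function(net, source, maxRadius = NULL) {
  if (!is.null(maxRadius)) {
    if (length(maxRadius) != 1 || is.na(maxRadius) || maxRadius < 1)
      stopParameter("maxRadius must be a single integer >= 1")
  }
  i <- nodeIndex(net, source)
  dist <- bfsDistances(adjList(net), i,
                       if (is.null(maxRadius)) Inf else as.integer(maxRadius))
  names(dist) <- nodeLabels(net)
  dist[!is.na(dist)]
}
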