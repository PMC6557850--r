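#' Generate a synthetic test network
#'
#' Deterministic (given \code{seed}) generators for the standard graph
#' families used as stand-ins for real networks in tests and examples.
#' Outputs are always simple and undirected, with node labels
#' \code{"1", "2", ...} in generation order.
#'
#' Families and their size parameters:
#' \describe{
#'   \item{path}{path of \code{n} nodes (E = n - 1).}
#'   \item{star}{one hub with \code{n} leaves (N = n + 1, E = n).}
#'   \item{cycle}{cycle of \code{n} nodes.}
#'   \item{complete}{complete graph on \code{n} nodes.}
#'   \item{tree}{rooted tree on \code{n} nodes with \code{children} children
#'     per node.}
#'   \item{erdos_renyi}{G(n, p) random graph.}
#'   \item{barabasi_albert}{preferential attachment: start from a complete
#'     graph on \code{m + 1} nodes, then attach each new node with \code{m}
#'     edges, so E = choose(m+1, 2) + m (n - m - 1) and the minimum degree
#'     is m.}
#'   \item{watts_strogatz}{ring lattice with \code{neighbors} neighbours on
#'     each side, rewired with probability \code{p} (then simplified).}
#' }
#'
#' @param family one of \code{"path"}, \code{"star"}, \code{"cycle"},
#'   \code{"complete"}, \code{"tree"}, \code{"erdos_renyi"},
#'   \code{"barabasi_albert"}, \code{"watts_strogatz"}.
#' @param n size parameter (number of leaves for \code{"star"}, node count
#'   otherwise).
#' @param m attachment edges per new node (Barabasi-Albert), >= 1.
#' @param p edge/rewiring probability in \[0, 1\] (Erdos-Renyi,
#'   Watts-Strogatz).
#' @param children children per node (tree).
#' @param neighbors lattice neighbours per side (Watts-Strogatz).
#' @param seed RNG seed for the random families; the caller's RNG state is
#'   left untouched.
#' @return a [Network-class].
#' @examples
#' generateNetwork("star", 4)                      # N = 5, E = 4
#' generateNetwork("barabasi_albert", 50, m = 2, seed = 1)
#' @export
generateNetwork <- function(family, n, m = 2L, p = 0.1, children = 2L,
                            neighbors = 2L, seed = 1L) {
  if (length(n) != 1 || is.na(n) || n < 1)
    stopParameter("n must be a positive integer")
  n <- as.integer(n)
  old <- globalSeedState()
  on.exit(restoreSeedState(old))
  set.seed(as.integer(seed))
  g <- switch(family,
    path = igraph::make_ring(n, circular = FALSE),
    star = igraph::make_star(n + 1L, mode = "undirected", center = 1),
    cycle = {
      if (n < 3) stopParameter("cycle needs n >= 3")
      igraph::make_ring(n, circular = TRUE)
    },
    complete = igraph::make_full_graph(n),
    tree = igraph::make_tree(n, children = as.integer(children),
                             mode = "undirected"),
    erdos_renyi = {
      if (p < 0 || p > 1) stopParameter("erdos_renyi needs p in [0, 1]")
      igraph::sample_gnp(n, p)
    },
    barabasi_albert = {
      if (m < 1) stopParameter("barabasi_albert needs m >= 1")
      m <- as.integer(m)
      if (n < m + 1L) stopParameter("barabasi_albert needs n >= m + 1")
      igraph::sample_pa(n, power = 1, m = m,
                        start.graph = igraph::make_full_graph(m + 1L),
                        directed = FALSE)
    },
    watts_strogatz = {
      if (p < 0 || p > 1) stopParameter("watts_strogatz needs p in [0, 1]")
      igraph::sample_smallworld(1, n, as.integer(neighbors), p)
    },
    stopParameter("unknown network family '%s'", family))
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  asNetwork(g)
}
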