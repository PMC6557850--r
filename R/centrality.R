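newScores <- function(net, method, s, params = list()) {
  names(s) <- nodeLabels(net)
  new("ScoreVector", method = method, params = params, scores = s)
}

# Shared gravity kernel: S(i) = mass_i * sum_{0 < d_ij <= radius} mass_j / d_ij^2.
# Finite radius runs a radius-limited BFS per node; infinite radius uses the
# full distance matrix (unreachable pairs contribute 0 in both cases).
gravitySum <- function(net, mass, radius = Inf) {
  n <- numNodes(net)
  if (n == 0) return(numeric(0))
  if (is.finite(radius)) {
    adj <- adjList(net)
    s <- numeric(n)
    for (i in seq_len(n)) {
      d <- bfsDistances(adj, i, radius)
      j <- which(!is.na(d) & d > 0L)
      s[i] <- mass[i] * sum(mass[j] / as.numeric(d[j])^2)
    }
    s
  } else {
    D <- igraph::distances(asIgraph(net))
    # mass_j / d_ij^2 summed per row, then scaled by mass_i: the same
    # accumulation as the BFS branch, so truncation at the diameter
    # reproduces the full sum bit for bit
    W <- matrix(mass, n, n, byrow = TRUE) / D^2
    W[!is.finite(W)] <- 0   # diagonal (d = 0) and unreachable pairs
    mass * rowSums(W)
  }
}

#' Degree centrality
#'
#' @param net a [Network-class].
#' @return a [ScoreVector-class] with score(i) = degree of i.
#' @export
degreeCentrality <- function(net) {
  newScores(net, "dc", degreeOf(net))
}

#' H-index centrality
#'
#' The node-level H-index: the largest integer h such that the node has at
#' least h neighbours whose degrees are all at least h.
#'
#' @param net a [Network-class].
#' @return a [ScoreVector-class] of non-negative integers.
#' @examples
#' scores(hIndex(generateNetwork("star", 4)))  # all 1
#' @export
hIndex <- function(net) {
  adj <- adjList(net)
  k <- degreeOf(net)
  h <- vapply(adj, function(nb) {
    if (length(nb) == 0) return(0)
    ks <- sort(k[nb], decreasing = TRUE)
    sum(ks >= seq_along(ks))
  }, numeric(1))
  newScores(net, "hindex", h)
}

#' k-shell (coreness) centrality
#'
#' Iterative pruning: repeatedly remove all nodes of degree <= s (cascading)
#' before incrementing s; a node's shell index is the stage s at which it is
#' removed. Isolated nodes get shell 0; trees are entirely shell 1.
#'
#' @param net a [Network-class].
#' @return a [ScoreVector-class] of integer shell indices.
#' @export
kShell <- function(net) {
  newScores(net, "kshell", as.numeric(igraph::coreness(asIgraph(net))))
}

#' Closeness centrality
#'
#' CC(i) = (N - 1) / sum_j d_ij, evaluated per connected component with the
#' component's size substituted for N; isolated nodes score 0.
#'
#' @param net a [Network-class].
#' @return a [ScoreVector-class].
#' @examples
#' scores(closenessCentrality(generateNetwork("path", 3)))  # 2/3, 1, 2/3
#' @export
closenessCentrality <- function(net) {
  g <- asIgraph(net)
  n <- numNodes(net)
  cc <- numeric(n)
  if (n > 0) {
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      idx <- which(comp$membership == cid)
      if (length(idx) < 2) next   # isolated node -> 0
      D <- igraph::distances(g, v = idx, to = idx)
      cc[idx] <- (length(idx) - 1) / rowSums(D)
    }
  }
  newScores(net, "cc", cc)
}

#' Betweenness centrality
#'
#' BC(i) = sum over unordered pairs {s, t} (both distinct from i) of the
#' fraction of shortest s-t paths passing through i. Unnormalised, fractional
#' counting over all geodesics.
#'
#' @param net a [Network-class].
#' @return a [ScoreVector-class].
#' @examples
#' scores(betweennessCentrality(generateNetwork("star", 4)))  # center 6
#' @export
betweennessCentrality <- function(net) {
  b <- as.numeric(igraph::betweenness(asIgraph(net), directed = FALSE))
  newScores(net, "bc", b)
}

#' Gravity-model centrality
#'
#' Scores node i as \eqn{S(i) = \sum_{j \ne i} k_i k_j / d_{ij}^2}: degrees
#' act as masses, shortest-path distances as distances, so a node with many
#' neighbours that sits close to most other nodes is highly influential.
#' Unreachable pairs contribute 0 (the natural d -> Inf limit).
#'
#' @param net a [Network-class].
#' @return a [ScoreVector-class].
#' @examples
#' scores(gravityModel(generateNetwork("star", 4)))  # center 16, leaves 4.75
#' @export
gravityModel <- function(net) {
  newScores(net, "gm", gravitySum(net, degreeOf(net), Inf))
}

#' Local gravity-model centrality
#'
#' The gravity-model sum truncated at hop radius R:
#' \eqn{S_R(i) = \sum_{d_{ij} \le R, j \ne i} k_i k_j / d_{ij}^2}. Truncation
#' cuts the cost of all-pairs distances and suppresses noisy long-range
#' contributions; empirically the best radius tracks half the network's
#' average distance. Implemented by a radius-limited BFS per node, never via
#' the full distance matrix.
#'
#' @param net a [Network-class].
#' @param R truncation radius, integer >= 1. For R at least the component
#'   diameter the result equals [gravityModel()] exactly.
#' @return a [ScoreVector-class] with \code{R} recorded in its params.
#' @examples
#' scores(localGravityModel(generateNetwork("path", 4), R = 2))
#' @export
localGravityModel <- function(net, R) {
  if (length(R) != 1 || is.na(R) || R < 1)
    stopParameter("truncation radius R must be a single integer >= 1")
  R <- as.integer(R)
  newScores(net, "lgm", gravitySum(net, degreeOf(net), R), params = list(R = R))
}

#' Gravity centrality with k-shell masses (G)
#'
#' Like the local gravity model at fixed radius 3, but with each node's
#' k-shell index as its mass:
#' \eqn{G(i) = \sum_{0 < d_{ij} \le 3} k_s(i) k_s(j) / d_{ij}^2}.
#'
#' @param net a [Network-class].
#' @return a [ScoreVector-class].
#' @export
gravityCentrality <- function(net) {
  ks <- scores(kShell(net))
  newScores(net, "g", gravitySum(net, as.numeric(ks), 3L))
}

#' Extended gravity centrality (G+)
#'
#' Neighbour sum of the k-shell-mass gravity centrality:
#' \eqn{G_+(i) = \sum_{j \in \Lambda_i} G(j)} over i's neighbours
#' \eqn{\Lambda_i}. Isolated nodes score 0.
#'
#' @param net a [Network-class].
#' @return a [ScoreVector-class].
#' @export
extendedGravityCentrality <- function(net) {
  g <- scores(gravityCentrality(net))
  adj <- adjList(net)
  s <- vapply(adj, function(nb) sum(g[nb]), numeric(1))
  newScores(net, "gplus", s)
}

# method registry used by evaluation helpers and the CLI
centralityMethods <- c("bc", "cc", "dc", "hindex", "kshell", "g", "gplus",
                       "gm", "lgm")

computeScores <- function(net, method, R = NULL) {
  switch(method,
    dc = degreeCentrality(net),
    hindex = hIndex(net),
    kshell = kShell(net),
    cc = closenessCentrality(net),
    bc = betweennessCentrality(net),
    g = gravityCentrality(net),
    gplus = extendedGravityCentrality(net),
    gm = gravityModel(net),
    lgm = {
      if (is.null(R))
        stopParameter("method 'lgm' needs a truncation radius R")
      localGravityModel(net, R)
    },
    stopParameter("unknown ranking method '%s'", method))
}

#' @rdname accessors
#' @export
setMethod("scores", "ScoreVector", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("scoreMethod", "ScoreVector", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("scoreParams", "ScoreVector", function(x) x@params)

setMethod("show", "ScoreVector", function(object) {
  p <- if (length(object@params) > 0)
    paste0(" (", paste(names(object@params), unlist(object@params),
                       sep = "=", collapse = ", "), ")")
  else ""
  cat(sprintf("ScoreVector '%s'%s over %d nodes\n",
              object@method, p, length(object@scores)))
  if (length(object@scores) > 0) {
    top <- utils::head(sort(object@scores, decreasing = TRUE), 5)
    cat("  top:", paste(names(top), format(top, digits = 4),
                        sep = "=", collapse = ", "), "\n")
  }
})

#' Ranked table of a score vector
#'
#' Orders nodes by descending score; ties are broken by node label so the
#' output is reproducible (tie order does not affect any rank correlation,
#' which is computed on the scores themselves).
#'
#' @param sv a [ScoreVector-class].
#' @return data.frame with columns \code{node} and \code{score}.
#' @export
rankTable <- function(sv) {
  s <- scores(sv)
  ord <- order(-s, names(s))
  data.frame(node = names(s)[ord], score = as.numeric(s)[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
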