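largestComponent <- function(net) {
  g <- asIgraph(net)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(g, keep)
}

#' Average shortest-path distance
#'
#' Mean hop distance over all unordered pairs of the largest connected
#' component. Restricting to the largest component gives a finite statistic
#' on disconnected graphs without imputing infinite distances.
#'
#' @param net a [Network-class].
#' @return a single number.
#' @examples
#' averageDistance(generateNetwork("path", 3))  # 4/3
#' @export
averageDistance <- function(net) {
  lc <- largestComponent(net)
  if (igraph::vcount(lc) < 2)
    stopUndefinedStat("average distance needs >= 2 nodes in the largest component")
  igraph::mean_distance(lc, directed = FALSE)
}

#' Average local clustering coefficient
#'
#' Watts-Strogatz clustering: the mean over all nodes of (number of edges
#' among a node's neighbours) / (k(k-1)/2), with nodes of degree < 2
#' contributing 0.
#'
#' @param net a [Network-class].
#' @return a single number in \[0, 1\].
#' @export
clusteringCoefficient <- function(net) {
  if (numNodes(net) < 1)
    stopUndefinedStat("clustering coefficient undefined on the empty graph")
  local <- igraph::transitivity(asIgraph(net), type = "local", isolates = "zero")
  mean(local)
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two ends of edges, each
#' undirected edge contributing both orientations (Newman's r). Undefined
#' when the edge-end degrees have zero variance (e.g. regular graphs).
#'
#' @param net a [Network-class].
#' @return a single number in \[-1, 1\].
#' @examples
#' degreeAssortativity(generateNetwork("star", 4))  # -1
#' @export
degreeAssortativity <- function(net) {
  if (numEdges(net) < 2)
    stopUndefinedStat("assortativity needs at least 2 edges")
  r <- suppressWarnings(igraph::assortativity_degree(asIgraph(net)))
  if (is.na(r) || is.nan(r))
    stopUndefinedStat("assortativity undefined: zero degree variance over edge ends")
  r
}

#' Degree heterogeneity
#'
#' H = <k^2>/<k>^2, the second moment of the degree sequence over the squared
#' first moment. H >= 1 always, with equality exactly for regular graphs.
#'
#' @param net a [Network-class].
#' @return a single number >= 1.
#' @export
degreeHeterogeneity <- function(net) {
  k <- degreeOf(net)
  if (length(k) == 0 || mean(k) == 0)
    stopUndefinedStat("degree heterogeneity needs mean degree > 0")
  mean(k^2) / mean(k)^2
}

#' SIR epidemic threshold
#'
#' Heterogeneous mean-field threshold beta_c = <k> / (<k^2> - <k>) of SIR
#' dynamics with recovery probability 1. Algebraically identical to
#' 1 / (H <k> - 1) with H the degree heterogeneity.
#'
#' @param net a [Network-class].
#' @return a single positive number.
#' @examples
#' epidemicThreshold(generateNetwork("complete", 4))  # 3-regular: 1/2
#' @export
epidemicThreshold <- function(net) {
  k <- degreeOf(net)
  if (length(k) == 0)
    stopUndefinedStat("epidemic threshold undefined on the empty graph")
  m1 <- mean(k)
  m2 <- mean(k^2)
  if (m2 <= m1)
    stopUndefinedStat("epidemic threshold undefined: <k^2> <= <k>")
  m1 / (m2 - m1)
}

#' Topological summary of a network
#'
#' Computes the standard eight-statistic row: N, E, mean degree, mean
#' distance (largest component), average local clustering, degree
#' assortativity, degree heterogeneity and the SIR epidemic threshold.
#' Statistics undefined for the given graph come back as \code{NA} rather
#' than errors.
#'
#' @param net a [Network-class] with at least 2 nodes.
#' @return a [SummaryStats-class].
#' @examples
#' networkSummary(generateNetwork("complete", 5))
#' @export
networkSummary <- function(net) {
  if (numNodes(net) < 2)
    stopParameter("networkSummary needs a graph with >= 2 nodes")
  tryNA <- function(expr) {
    tryCatch(expr, gravityrankUndefinedStatError = function(e) NA_real_)
  }
  n <- numNodes(net)
  e <- numEdges(net)
  new("SummaryStats",
      N = as.numeric(n), E = as.numeric(e),
      meanDegree = 2 * e / n,
      meanDistance = tryNA(averageDistance(net)),
      clustering = tryNA(clusteringCoefficient(net)),
      assortativity = tryNA(degreeAssortativity(net)),
      heterogeneity = tryNA(degreeHeterogeneity(net)),
      threshold = tryNA(epidemicThreshold(net)))
}

#' @describeIn networkSummary one-row data.frame with columns in the
#'   conventional summary-table order.
#' @param x a \code{SummaryStats} object.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.SummaryStats <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(N = x@N, E = x@E, mean_degree = x@meanDegree,
             mean_distance = x@meanDistance, clustering = x@clustering,
             assortativity = x@assortativity, heterogeneity = x@heterogeneity,
             threshold = x@threshold)
}

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats\n")
  df <- as.data.frame.SummaryStats(object)
  for (nm in names(df))
    cat(sprintf("  %-14s %s\n", nm,
                ifelse(is.na(df[[nm]]), "NA", format(df[[nm]], digits = 6))))
})
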