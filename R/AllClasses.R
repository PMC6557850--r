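#' @import methods
NULL

#' Network: a simple undirected graph with stable node labels
#'
#' Thin S4 wrapper around an undirected, simple (no self-loops, no multi-edges)
#' \pkg{igraph} graph whose vertices carry unique character labels. All
#' centralities, summary statistics and the SIR simulator operate on this
#' class. Node labels are preserved verbatim from the input edge list and the
#' internal vertex order is the order of first appearance, so every
#' deterministic computation is bit-stable across runs.
#'
#' @slot graph an undirected simple \code{igraph} object with unique vertex
#'   names.
#'
#' @seealso [readEdgeList()], [generateNetwork()], [asNetwork()]
#' @export
setClass("Network", slots = c(graph = "ANY"))

setValidity("Network", function(object) {
  g <- object@graph
  if (!inherits(g, "igraph"))
    return("slot 'graph' must be an igraph object")
  if (igraph::is_directed(g))
    return("graph must be undirected")
  if (igraph::vcount(g) > 0) {
    nm <- igraph::V(g)$name
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
      return("all vertices must be named")
    if (anyDuplicated(nm))
      return("vertex names must be unique")
  }
  if (igraph::ecount(g) > 0 &&
      (any(igraph::which_loop(g)) || any(igraph::which_multiple(g))))
    return("graph must be simple (no self-loops or duplicate edges)")
  TRUE
})

#' ScoreVector: one centrality's scores over a network's nodes
#'
#' Result container for the nine ranking methods. Scores are raw, finite real
#' numbers; no normalisation is applied anywhere, because rankings are
#' compared by rank correlation only.
#'
#' @slot method identifier of the ranking method (e.g. \code{"gm"},
#'   \code{"lgm"}, \code{"dc"}).
#' @slot params named list of method parameters (e.g. the truncation radius
#'   \code{R} for the local gravity model).
#' @slot scores named numeric vector, one finite score per node label.
#'
#' @export
setClass("ScoreVector",
  slots = c(method = "character", params = "list", scores = "numeric"))

setValidity("ScoreVector", function(object) {
  s <- object@scores
  if (length(s) > 0) {
    if (is.null(names(s)) || anyDuplicated(names(s)))
      return("scores must be uniquely named by node label")
    if (any(!is.finite(s)))
      return("all scores must be finite")
  }
  if (length(object@method) != 1)
    return("method must be a single identifier")
  TRUE
})

#' SIRConfig: parameters of the SIR influence-estimation protocol
#'
#' @slot beta infection probability per infected-susceptible contact per
#'   step, in \[0, 1\].
#' @slot lam recovery probability per infected node per step, in (0, 1\].
#'   The headline protocol fixes \code{lam = 1}, under which the dynamics are
#'   equivalent to bond percolation.
#' @slot runs number of independent realisations per seed node (default
#'   protocol: 1000).
#' @slot seed base RNG seed; every (node, run) pair gets its own
#'   deterministic substream so results are reproducible and independent of
#'   evaluation order.
#'
#' @seealso [SIRConfig()], [standardRanking()]
#' @export
setClass("SIRConfig",
  slots = c(beta = "numeric", lam = "numeric", runs = "integer",
            seed = "integer"))

setValidity("SIRConfig", function(object) {
  if (length(object@beta) != 1 || is.na(object@beta) ||
      object@beta < 0 || object@beta > 1)
    return("beta must be a single value in [0, 1]")
  if (length(object@lam) != 1 || is.na(object@lam) ||
      object@lam <= 0 || object@lam > 1)
    return("lam must be a single value in (0, 1]")
  if (length(object@runs) != 1 || is.na(object@runs) || object@runs < 1)
    return("runs must be a positive integer")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' InfluenceVector: simulated spreading influence of every node
#'
#' Monte-Carlo estimate of each node's spreading influence F = (final number
#' of recovered nodes) / N, averaged over independent SIR realisations seeded
#' at that node. This is the ground-truth "standard ranking" against which
#' centralities are evaluated.
#'
#' @slot scores named numeric vector of mean F per seed node; each value lies
#'   in \[1/N, 1\].
#' @slot stderr named numeric vector of standard errors (same names).
#' @slot config the [SIRConfig-class] used.
#'
#' @seealso [standardRanking()], [estimateInfluence()]
#' @export
setClass("InfluenceVector",
  slots = c(scores = "numeric", stderr = "numeric", config = "SIRConfig"))

setValidity("InfluenceVector", function(object) {
  if (length(object@scores) != length(object@stderr))
    return("scores and stderr must have equal length")
  if (!identical(names(object@scores), names(object@stderr)))
    return("scores and stderr must share node names")
  if (any(object@stderr < 0))
    return("standard errors must be non-negative")
  TRUE
})

#' SummaryStats: topological summary of a network
#'
#' One row of the standard eight summary statistics: node count N, edge count
#' E, mean degree, mean shortest-path distance (over the largest connected
#' component), average local clustering coefficient, degree assortativity,
#' degree heterogeneity H = <k^2>/<k>^2, and the heterogeneous mean-field
#' epidemic threshold beta_c = <k>/(<k^2> - <k>). Statistics undefined on the
#' given graph (e.g. assortativity of a regular graph) are \code{NA}.
#'
#' @slot N node count.
#' @slot E edge count.
#' @slot meanDegree 2E/N.
#' @slot meanDistance mean hop distance over unordered reachable pairs within
#'   the largest connected component.
#' @slot clustering average local clustering coefficient (degree-<2 nodes
#'   contribute 0).
#' @slot assortativity Pearson correlation of degrees over edge endpoints.
#' @slot heterogeneity <k^2>/<k>^2 (1 iff regular).
#' @slot threshold SIR epidemic threshold <k>/(<k^2> - <k>).
#'
#' @seealso [networkSummary()]
#' @export
setClass("SummaryStats",
  slots = c(N = "numeric", E = "numeric", meanDegree = "numeric",
            meanDistance = "numeric", clustering = "numeric",
            assortativity = "numeric", heterogeneity = "numeric",
            threshold = "numeric"))

#' EvalReport: accuracy of one ranking method against the SIR ground truth
#'
#' @slot method ranking method identifier.
#' @slot beta transmission probability of the SIR ground truth.
#' @slot tau tie-aware Kendall rank correlation between the method's scores
#'   and the simulated influences, in \[-1, 1\].
#' @slot params method parameters (e.g. truncation radius R).
#' @slot nNodes number of nodes compared.
#'
#' @seealso [evaluateMethod()], [kendallTau()]
#' @export
setClass("EvalReport",
  slots = c(method = "character", beta = "numeric", tau = "numeric",
            params = "list", nNodes = "integer"))

setValidity("EvalReport", function(object) {
  if (!is.na(object@tau) && (object@tau < -1 - 1e-12 || object@tau > 1 + 1e-12))
    return("tau must lie in [-1, 1]")
  TRUE
})

#' RadiusProfile: local-gravity accuracy as a function of truncation radius
#'
#' Kendall tau of the local gravity model against the SIR standard ranking
#' for each truncation radius R, together with the empirically optimal radius
#' R* (smallest argmax) and the radius predicted by the topological heuristic
#' R ~ <d>/2.
#'
#' @slot radii integer radii swept (1..R_max).
#' @slot taus Kendall tau at each radius.
#' @slot optimalR smallest radius attaining the maximal tau.
#' @slot predictedR max(1, nearest integer to <d>/2, half-integers rounded
#'   down).
#'
#' @seealso [sweepRadius()]
#' @export
setClass("RadiusProfile",
  slots = c(radii = "integer", taus = "numeric", optimalR = "integer",
            predictedR = "integer"))

setValidity("RadiusProfile", function(object) {
  if (length(object@radii) != length(object@taus))
    return("radii and taus must have equal length")
  if (length(object@taus) > 0 &&
      abs(max(object@taus) - object@taus[match(object@optimalR, object@radii)]) > 1e-12)
    return("optimalR must maximise tau")
  if (length(object@predictedR) == 1 && !is.na(object@predictedR) &&
      object@predictedR < 1)
    return("predictedR must be >= 1")
  TRUE
})
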