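#' Construct an SIR protocol configuration
#'
#' @param beta infection probability per infected-susceptible contact per
#'   step, in \[0, 1\]. The headline protocol sets beta to the network's
#'   epidemic threshold ([epidemicThreshold()]).
#' @param lam recovery probability per infected node per step, in (0, 1\];
#'   default 1, under which every infected node makes exactly one round of
#'   infection attempts and the process is equivalent to bond percolation.
#' @param runs independent realisations per seed node (default 1000).
#' @param seed base RNG seed for the per-(node, run) substreams.
#' @return a [SIRConfig-class].
#' @examples
#' SIRConfig(beta = 0.2, runs = 100, seed = 42)
#' @export
SIRConfig <- function(beta, lam = 1, runs = 1000L, seed = 1L) {
  new("SIRConfig", beta = as.numeric(beta), lam = as.numeric(lam),
      runs = as.integer(runs), seed = as.integer(seed))
}

setMethod("show", "SIRConfig", function(object) {
  cat(sprintf("SIRConfig: beta=%g, lambda=%g, runs=%d, seed=%d\n",
              object@beta, object@lam, object@runs, object@seed))
})

# one synchronous discrete-time SIR realisation over an adjacency list,
# using the current RNG stream; returns the recovered count.
# Step order: (1) every infected node attempts to infect each currently
# susceptible neighbour with prob beta (a node hit by any attempt becomes
# infected at step end); (2) every node infected at the *start* of the step
# recovers with prob lam (newly infected nodes are immune to same-step
# recovery).
sirRun <- function(adj, seedIdx, beta, lam) {
  n <- length(adj)
  susceptible <- rep(TRUE, n)
  susceptible[seedIdx] <- FALSE
  infected <- seedIdx
  nRecovered <- 0L
  while (length(infected) > 0) {
    contacts <- unlist(adj[infected], use.names = FALSE)
    contacts <- contacts[susceptible[contacts]]
    newly <- if (length(contacts) == 0) integer(0)
             else if (beta >= 1) unique(contacts)
             else if (beta <= 0) integer(0)
             else unique(contacts[stats::runif(length(contacts)) < beta])
    susceptible[newly] <- FALSE
    recov <- if (lam >= 1) rep(TRUE, length(infected))
             else stats::runif(length(infected)) < lam
    nRecovered <- nRecovered + sum(recov)
    infected <- c(infected[!recov], newly)
  }
  nRecovered
}

#' Simulate one SIR outbreak
#'
#' Single realisation of synchronous discrete-time SIR dynamics seeded at one
#' node, using the current RNG stream. Each step, every infected node
#' attempts to infect each currently susceptible neighbour independently
#' with probability \code{beta}; nodes infected at the start of the step then
#' recover with probability \code{lam} (newly infected nodes cannot recover
#' in the same step). The process stops when no infected nodes remain.
#'
#' @param net a [Network-class].
#' @param seedNode label of the initially infected node.
#' @param beta infection probability, in \[0, 1\].
#' @param lam recovery probability, in (0, 1\].
#' @return the final outbreak fraction F = (number recovered) / N, always in
#'   \{1/N, 2/N, ..., 1\}.
#' @examples
#' net <- generateNetwork("star", 4)
#' simulateOutbreak(net, "1", beta = 0, lam = 1)  # 1/5 exactly
#' @export
simulateOutbreak <- function(net, seedNode, beta, lam = 1) {
  if (beta < 0 || beta > 1) stopParameter("beta must be in [0, 1]")
  if (lam <= 0 || lam > 1) stopParameter("lam must be in (0, 1]")
  i <- nodeIndex(net, seedNode)
  sirRun(adjList(net), i, beta, lam) / numNodes(net)
}

# deterministic substream seed for (nodeIdx, run); distinct (nodeIdx, run)
# pairs map to distinct seeds below 2^31 for the graph sizes at hand
substreamSeed <- function(baseSeed, nodeIdx, runs, run) {
  idx <- (as.numeric(nodeIdx) - 1) * as.numeric(runs) + as.numeric(run)
  as.integer((as.numeric(baseSeed) %% 65536 * 32768 + idx) %% 2147483647)
}

estimateInfluenceIdx <- function(adj, n, nodeIdx, cfg) {
  f <- numeric(cfg@runs)
  for (r in seq_len(cfg@runs)) {
    set.seed(substreamSeed(cfg@seed, nodeIdx, cfg@runs, r))
    f[r] <- sirRun(adj, nodeIdx, cfg@beta, cfg@lam) / n
  }
  se <- if (cfg@runs > 1) stats::sd(f) / sqrt(cfg@runs) else 0
  c(mean = mean(f), stderr = se)
}

#' Monte-Carlo influence of one seed node
#'
#' Mean and standard error of the outbreak fraction F over \code{cfg@runs}
#' independent SIR realisations seeded at \code{seedNode}. Every (node, run)
#' pair draws from its own substream derived from \code{cfg@seed}, so the
#' estimate is reproducible and independent of evaluation order.
#'
#' @param net a [Network-class].
#' @param seedNode label of the seed node.
#' @param cfg a [SIRConfig-class].
#' @return named numeric vector \code{c(mean = ..., stderr = ...)}.
#' @examples
#' net <- generateNetwork("star", 4)
#' estimateInfluence(net, "1", SIRConfig(beta = 0.5, runs = 200, seed = 7))
#' @export
estimateInfluence <- function(net, seedNode, cfg) {
  i <- nodeIndex(net, seedNode)
  old <- globalSeedState()
  on.exit(restoreSeedState(old))
  estimateInfluenceIdx(adjList(net), numNodes(net), i, cfg)
}

#' SIR standard ranking of all nodes
#'
#' Ground-truth node influence: [estimateInfluence()] with every node as the
#' seed. The resulting mean outbreak fractions define the "standard ranking"
#' against which centrality rankings are scored by Kendall tau.
#'
#' @param net a [Network-class].
#' @param cfg a [SIRConfig-class]; the headline protocol uses
#'   \code{beta = epidemicThreshold(net)}, \code{lam = 1}, \code{runs = 1000}.
#' @return an [InfluenceVector-class].
#' @examples
#' net <- generateNetwork("star", 3)
#' standardRanking(net, SIRConfig(beta = 0.5, runs = 50, seed = 11))
#' @export
standardRanking <- function(net, cfg) {
  adj <- adjList(net)
  n <- numNodes(net)
  old <- globalSeedState()
  on.exit(restoreSeedState(old))
  est <- vapply(seq_len(n), function(i) estimateInfluenceIdx(adj, n, i, cfg),
                numeric(2))
  m <- est[1, ]
  se <- est[2, ]
  names(m) <- names(se) <- nodeLabels(net)
  new("InfluenceVector", scores = m, stderr = se, config = cfg)
}

#' @rdname accessors
#' @export
setMethod("scores", "InfluenceVector", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("stdErrors", "InfluenceVector", function(x) x@stderr)

setMethod("show", "InfluenceVector", function(object) {
  cat(sprintf("InfluenceVector over %d nodes (beta=%g, lambda=%g, runs=%d)\n",
              length(object@scores), object@config@beta, object@config@lam,
              object@config@runs))
  if (length(object@scores) > 0) {
    top <- utils::head(sort(object@scores, decreasing = TRUE), 5)
    cat("  top F:", paste(names(top), format(top, digits = 4),
                          sep = "=", collapse = ", "), "\n")
  }
})

# save/restore .Random.seed so seeded internals do not disturb the caller's
# RNG stream
globalSeedState <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restoreSeedState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
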