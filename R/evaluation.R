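# strict-inversion count by bottom-up merge sort; y must already be sorted
# within tied-x groups so that same-x pairs contribute nothing
countInversions <- function(y) {
  n <- length(y)
  inv <- 0
  width <- 1L
  arr <- y
  while (width < n) {
    tmp <- arr
    i <- 1L
    while (i <= n) {
      mid <- min(i + width - 1L, n)
      hi <- min(i + 2L * width - 1L, n)
      if (mid < hi) {
        a <- arr[i:mid]
        b <- arr[(mid + 1L):hi]
        la <- length(a)
        ia <- 1L; ib <- 1L; k <- i
        while (ia <= la && ib <= length(b)) {
          if (a[ia] <= b[ib]) {
            tmp[k] <- a[ia]; ia <- ia + 1L
          } else {
            tmp[k] <- b[ib]; ib <- ib + 1L
            inv <- inv + (la - ia + 1)
          }
          k <- k + 1L
        }
        if (ia <= la) tmp[k:(k + la - ia)] <- a[ia:la]
        if (ib <= length(b)) tmp[k:(k + length(b) - ib)] <- b[ib:length(b)]
      }
      i <- i + 2L * width
    }
    arr <- tmp
    width <- 2L * width
  }
  inv
}

tiePairs <- function(v) {
  r <- rle(v)$lengths
  sum(r * (r - 1)) / 2
}

#' Tie-aware Kendall rank correlation
#'
#' Kendall's tau in the form \eqn{\tau = 2(n_+ - n_-) / (N(N-1))}: a pair of
#' positions is concordant when both sequences order it the same way,
#' discordant when they disagree, and a pair tied in either sequence counts
#' in neither \eqn{n_+} nor \eqn{n_-} while the denominator stays the full
#' N(N-1). This differs from the tie-corrected tau-b of
#' \code{cor(..., method = "kendall")}, whose denominator shrinks with ties;
#' the literal form is used throughout so that accuracy values are directly
#' comparable across methods with different tie structures.
#'
#' Pairs are counted in O(N log N) by merge-count; the O(N^2) enumeration
#' exists in the test suite as an independent oracle.
#'
#' @param x,y numeric sequences of equal length N >= 2, aligned by position.
#' @return tau in \[-1, 1\].
#' @examples
#' kendallTau(c(1, 2, 3), c(1, 3, 2))  # 1/3
#' kendallTau(c(1, 1, 2), c(1, 2, 3))  # 2/3: the tied pair contributes nothing
#' @export
kendallTau <- function(x, y) {
  n <- length(x)
  if (length(y) != n)
    stopParameter("kendallTau: sequences must have equal length")
  if (n < 2)
    stopParameter("kendallTau: need at least 2 elements")
  x <- as.numeric(x)
  y <- as.numeric(y)
  ord <- order(x, y)
  xs <- x[ord]
  ys <- y[ord]
  n0 <- n * (n - 1) / 2
  tx <- tiePairs(xs)
  ty <- tiePairs(sort(y, method = "radix"))
  joint <- cumsum(c(TRUE, diff(xs) != 0 | diff(ys) != 0))
  txy <- {
    t <- tabulate(joint)
    sum(t * (t - 1)) / 2
  }
  nDis <- countInversions(ys)
  nCon <- n0 - tx - ty + txy - nDis
  2 * (nCon - nDis) / (n * (n - 1))
}

#' Score a centrality against the SIR ground truth
#'
#' Kendall tau between a centrality's raw scores and the simulated mean
#' outbreak fractions, aligned node by node. Raw scores are used directly:
#' tau depends only on pairwise order, so pre-ranking would change nothing.
#'
#' @param scores a [ScoreVector-class].
#' @param standard an [InfluenceVector-class] over the same node set.
#' @return an [EvalReport-class].
#' @export
evaluateMethod <- function(scores, standard) {
  sv <- scores(scores)
  iv <- scores(standard)
  if (length(sv) != length(iv) || !setequal(names(sv), names(iv)))
    stopAlignment("score vector and standard ranking cover different node sets")
  tau <- kendallTau(as.numeric(sv[names(iv)]), as.numeric(iv))
  new("EvalReport", method = scoreMethod(scores), beta = standard@config@beta,
      tau = tau, params = scoreParams(scores), nNodes = length(iv))
}

setMethod("show", "EvalReport", function(object) {
  p <- if (length(object@params) > 0)
    paste0(", ", paste(names(object@params), unlist(object@params),
                       sep = "=", collapse = ", "))
  else ""
  cat(sprintf("EvalReport: method=%s%s, beta=%g, n=%d, tau=%.4f\n",
              object@method, p, object@beta, object@nNodes, object@tau))
})

#' Accuracy of several ranking methods at once
#'
#' Convenience wrapper producing an accuracy table: one Kendall tau per
#' method against the same SIR standard ranking.
#'
#' @param net a [Network-class].
#' @param standard an [InfluenceVector-class] for \code{net}.
#' @param methods character vector of method identifiers among
#'   \code{"bc", "cc", "dc", "hindex", "kshell", "g", "gplus", "gm", "lgm"}.
#' @param R truncation radius used when \code{"lgm"} is requested; default is
#'   the topological prediction \code{predictRadius(net)}.
#' @return data.frame with columns \code{method}, \code{beta}, \code{R}
#'   (NA except for lgm) and \code{tau}.
#' @export
rankingAccuracy <- function(net, standard,
                            methods = centralityMethods,
                            R = predictRadius(net)) {
  bad <- setdiff(methods, centralityMethods)
  if (length(bad) > 0)
    stopParameter("unknown ranking method '%s'", bad[1])
  rows <- lapply(methods, function(m) {
    sv <- computeScores(net, m, R = R)
    rep <- evaluateMethod(sv, standard)
    data.frame(method = m, beta = rep@beta,
               R = if (m == "lgm") R else NA_integer_,
               tau = rep@tau, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# nearest integer with half-integers rounded down, floored at 1
roundHalfDown <- function(x) max(1L, as.integer(ceiling(x - 0.5)))

#' Predicted truncation radius from the average distance
#'
#' The topological heuristic R ~ <d>/2 relating the optimal truncation
#' radius of the local gravity model to the network's average shortest-path
#' distance, rounded to the nearest integer (half-integers down) and floored
#' at 1. E.g. <d> = 4.0252 predicts R = 2.
#'
#' @param net a [Network-class].
#' @return integer radius >= 1.
#' @export
predictRadius <- function(net) {
  roundHalfDown(averageDistance(net) / 2)
}

#' Truncation-radius sweep of the local gravity model
#'
#' Kendall tau of the local gravity model against the SIR standard ranking
#' for every truncation radius R = 1..R_max. Reports the empirically optimal
#' radius R* (smallest R on ties, preferring the cheaper model) alongside
#' the topological prediction <d>/2.
#'
#' @param net a [Network-class].
#' @param standard an [InfluenceVector-class] for \code{net}.
#' @param Rmax largest radius to sweep; defaults to the diameter of the
#'   largest component, beyond which the local model equals the full one.
#' @return a [RadiusProfile-class].
#' @export
sweepRadius <- function(net, standard, Rmax = NULL) {
  if (is.null(Rmax))
    Rmax <- max(1L, as.integer(igraph::diameter(asIgraph(net),
                                                unconnected = TRUE)))
  if (Rmax < 1) stopParameter("Rmax must be >= 1")
  radii <- seq_len(Rmax)
  taus <- vapply(radii, function(R) {
    evaluateMethod(localGravityModel(net, R), standard)@tau
  }, numeric(1))
  new("RadiusProfile", radii = radii, taus = taus,
      optimalR = radii[which.max(taus)],
      predictedR = predictRadius(net))
}

setMethod("show", "RadiusProfile", function(object) {
  cat(sprintf("RadiusProfile: R = 1..%d, optimal R* = %d, predicted R = %d\n",
              max(object@radii), object@optimalR, object@predictedR))
  cat("  tau:", paste(sprintf("R=%d:%.4f", object@radii, object@taus),
                      collapse = "  "), "\n")
})

#' Similarity of rankings at consecutive truncation radii
#'
#' Kendall tau between the local gravity scores at radius R and at R + 1,
#' for R = 1..R_max - 1. Purely deterministic (no simulation). The values
#' converge to 1 as R approaches the diameter: enlarging an already large
#' radius barely changes the ranking, which is why a small radius suffices
#' in practice.
#'
#' @param net a [Network-class].
#' @param Rmax integer >= 2.
#' @return data.frame with columns \code{R} and \code{tau}.
#' @export
consecutiveRadiusSimilarity <- function(net, Rmax) {
  if (length(Rmax) != 1 || is.na(Rmax) || Rmax < 2)
    stopParameter("Rmax must be a single integer >= 2")
  Rmax <- as.integer(Rmax)
  svs <- lapply(seq_len(Rmax), function(R) scores(localGravityModel(net, R)))
  taus <- vapply(seq_len(Rmax - 1L), function(R) {
    kendallTau(as.numeric(svs[[R]]), as.numeric(svs[[R + 1L]]))
  }, numeric(1))
  data.frame(R = seq_len(Rmax - 1L), tau = taus)
}
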