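test_that("Kendall tau follows the literal tie rule", {
  expect_equal(kendallTau(1:4, 1:4), 1)
  expect_equal(kendallTau(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(kendallTau(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  # the tied pair counts in the denominator but in neither n+ nor n-
  expect_equal(kendallTau(c(1, 1, 2), c(1, 2, 3)), 2 / 3)
  expect_equal(kendallTau(rep(1, 5), 1:5), 0)
  expect_error(kendallTau(1:3, 1:4), class = "gravityrankParameterError")
  expect_error(kendallTau(1, 1), class = "gravityrankParameterError")
})

test_that("merge-count tau equals the O(N^2) pair-enumeration oracle", {
  set.seed(42)
  for (i in 1:400) {
    n <- sample(2:50, 1)
    # mix continuous and heavily tied sequences
    x <- if (i %% 2) rnorm(n) else sample(1:4, n, replace = TRUE)
    y <- if (i %% 3) rnorm(n) else sample(1:3, n, replace = TRUE)
    expect_equal(kendallTau(x, y), tauOracle(x, y))
  }
})

test_that("tau is symmetric, rank-invariant, reversal-negated and tie-bounded", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- rnorm(n)
    expect_equal(kendallTau(x, y), kendallTau(y, x))
    # strictly increasing transforms change nothing
    expect_equal(kendallTau(exp(x), y), kendallTau(x, y))
    expect_equal(kendallTau(x, rank(y)), kendallTau(x, y))
    # tie bound: |tau| <= 1 - 2t/(N(N-1)) with t pairs tied in either sequence
    sxy <- abs(sign(outer(x, x, "-")) * sign(outer(y, y, "-")))
    t <- sum(sxy[upper.tri(sxy)] == 0)
    expect_lte(abs(kendallTau(x, y)), 1 - 2 * t / (n * (n - 1)) + 1e-12)
  }
  # no ties: reversing one order negates tau
  x <- sample(100, 20)
  y <- sample(100, 20)
  expect_equal(kendallTau(x, -y), -kendallTau(x, y))
  expect_equal(kendallTau(-x, y), -kendallTau(x, y))
})

test_that("evaluateMethod aligns by node label and reports tau", {
  net <- starNet(4)
  iv <- standardRanking(net, SIRConfig(beta = 0.5, runs = 500, seed = 3))
  self <- new("ScoreVector", method = "self", params = list(),
              scores = scores(iv))
  expect_equal(evaluateMethod(self, iv)@tau, 1)
  neg <- new("ScoreVector", method = "neg", params = list(),
             scores = -scores(iv))
  # leaves are tied in both sequences; only untied pairs flip sign
  expect_equal(evaluateMethod(neg, iv)@tau, -evaluateMethod(self, iv)@tau)
  # star DC vs exact SIR expectations, checked against the pair oracle
  dc <- degreeCentrality(net)
  exact <- vapply(nodeLabels(net),
                  function(v) exhaustiveSirExpectation(net, v, 0.5), numeric(1))
  expect_equal(
    kendallTau(as.numeric(scores(dc)), as.numeric(exact)),
    tauOracle(as.numeric(scores(dc)), as.numeric(exact)))

  bad <- new("ScoreVector", method = "bad", params = list(),
             scores = c(zz = 1, yy = 2, xx = 3, ww = 4, vv = 5))
  expect_error(evaluateMethod(bad, iv), class = "gravityrankAlignmentError")
})

test_that("predicted radius rounds <d>/2 to the nearest integer, halves down, floor 1", {
  # mean distance 4.0252 predicts R = 2
  expect_equal(gravityrank:::roundHalfDown(4.0252 / 2), 2L)
  expect_equal(gravityrank:::roundHalfDown(2.5), 2L)
  expect_equal(gravityrank:::roundHalfDown(2.51), 3L)
  expect_equal(gravityrank:::roundHalfDown(0.3), 1L)
  expect_equal(predictRadius(completeNet(5)), 1L)  # <d> = 1
})

test_that("radius sweep finds the saturating optimum and echoes the prediction", {
  net <- randomNet(25, 0.15, seed = 31)
  cfg <- SIRConfig(beta = epidemicThreshold(net), runs = 300, seed = 12)
  std <- standardRanking(net, cfg)
  prof <- sweepRadius(net, std)
  diam <- igraph::diameter(asIgraph(net), unconnected = TRUE)
  expect_equal(prof@radii, seq_len(diam))
  # at R >= diameter the LGM tau equals the GM tau exactly
  gmTau <- evaluateMethod(gravityModel(net), std)@tau
  expect_equal(prof@taus[diam], gmTau)
  expect_equal(prof@optimalR, prof@radii[which.max(prof@taus)])
  expect_gte(prof@predictedR, 1L)
  # diameter-2 graph: profile has <= 2 entries
  prof2 <- sweepRadius(starNet(5),
                       standardRanking(starNet(5),
                                       SIRConfig(beta = 0.3, runs = 100, seed = 2)))
  expect_lte(length(prof2@radii), 2L)
})

test_that("consecutive-radius similarity is deterministic and saturates", {
  # complete graph: both radii give identical fully tied score vectors, and
  # under the literal tie rule every pair is tied, so tau is 0
  expect_equal(consecutiveRadiusSimilarity(completeNet(6), 2)$tau, 0)
  # path of 6: compare against the pair-enumeration oracle on raw LGM scores
  p6 <- pathNet(6)
  crs <- consecutiveRadiusSimilarity(p6, 6)
  for (R in crs$R) {
    a <- as.numeric(scores(localGravityModel(p6, R)))
    b <- as.numeric(scores(localGravityModel(p6, R + 1)))
    expect_equal(crs$tau[crs$R == R], tauOracle(a, b))
  }
  # beyond the diameter the two score vectors coincide, so tau equals the
  # self-correlation 1 - 2t/(N(N-1)) set by the vector's own ties
  sat <- as.numeric(scores(localGravityModel(p6, 5)))
  expect_equal(crs$tau[5], tauOracle(sat, sat))
  net <- randomNet(20, 0.2, seed = 77)
  diam <- igraph::diameter(asIgraph(net), unconnected = TRUE)
  crs2 <- consecutiveRadiusSimilarity(net, diam + 2)
  sat2 <- as.numeric(scores(localGravityModel(net, diam + 1)))
  expect_equal(crs2$tau[length(crs2$tau)], tauOracle(sat2, sat2))
  expect_error(consecutiveRadiusSimilarity(p6, 1),
               class = "gravityrankParameterError")
})

test_that("rankingAccuracy reports one tau per requested method", {
  net <- randomNet(15, 0.3, seed = 8)
  std <- standardRanking(net, SIRConfig(beta = 0.2, runs = 200, seed = 5))
  acc <- rankingAccuracy(net, std)
  expect_equal(nrow(acc), 9L)
  expect_true(all(acc$tau >= -1 & acc$tau <= 1))
  expect_equal(acc$R[acc$method == "lgm"], predictRadius(net))
  expect_true(all(is.na(acc$R[acc$method != "lgm"])))
  expect_error(rankingAccuracy(net, std, methods = "pagerank"),
               class = "gravityrankParameterError")
})
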