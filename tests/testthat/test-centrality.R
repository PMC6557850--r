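test_that("degree, H-index, k-shell, closeness, betweenness match hand values", {
  star <- starNet(4)   # hub is node "1"
  expect_equal(unname(scores(degreeCentrality(star))), c(4, 1, 1, 1, 1))
  expect_equal(unname(scores(degreeCentrality(completeNet(5)))), rep(4, 5))
  expect_equal(unname(scores(degreeCentrality(pathNet(4)))), c(1, 2, 2, 1))

  expect_equal(unname(scores(hIndex(completeNet(6)))), rep(5, 6))
  expect_equal(unname(scores(hIndex(star))), rep(1, 5))
  # node with neighbour degrees (3, 3, 2, 1) has H-index 2
  h <- netFromLines("x a\nx b\nx c\nx d\na a1\na a2\nb b1\nb b2\nc c1")
  expect_equal(unname(scores(hIndex(h))["x"]), 2)

  expect_equal(unname(scores(kShell(generateNetwork("tree", 12)))), rep(1, 12))
  expect_equal(unname(scores(kShell(completeNet(5)))), rep(4, 5))
  k4p <- netFromLines("a b\na c\na d\nb c\nb d\nc d\nd e")
  expect_equal(scores(kShell(k4p)),
               c(a = 3, b = 3, c = 3, d = 3, e = 1))

  expect_equal(unname(scores(closenessCentrality(completeNet(6)))), rep(1, 6))
  p3 <- netFromLines("a b\nb c")
  expect_equal(scores(closenessCentrality(p3)), c(a = 2 / 3, b = 1, c = 2 / 3))
  expect_equal(unname(scores(closenessCentrality(star))), c(1, 4 / 7, 4 / 7, 4 / 7, 4 / 7))

  expect_equal(scores(betweennessCentrality(p3)), c(a = 0, b = 1, c = 0))
  expect_equal(unname(scores(betweennessCentrality(cycleNet(4)))), rep(0.5, 4))
  expect_equal(unname(scores(betweennessCentrality(star))), c(6, 0, 0, 0, 0))
})

test_that("gravity model and local gravity model match hand evaluation", {
  star <- starNet(4)
  expect_equal(unname(scores(gravityModel(star))),
               c(16, 4.75, 4.75, 4.75, 4.75))
  p4 <- pathNet(4)
  expect_equal(unname(scores(gravityModel(p4))),
               c(2 + 0.5 + 1 / 9, 6.5, 6.5, 2 + 0.5 + 1 / 9))
  edge <- netFromLines("a b")
  expect_equal(unname(scores(gravityModel(edge))), c(1, 1))

  expect_equal(unname(scores(localGravityModel(star, 1))), c(16, 4, 4, 4, 4))
  expect_equal(unname(scores(localGravityModel(p4, 2)))[1], 2.5)
  # truncation inactive at R >= diameter
  expect_equal(scores(localGravityModel(p4, 3)), scores(gravityModel(p4)))
  expect_equal(scoreParams(localGravityModel(p4, 2))$R, 2L)
  expect_error(localGravityModel(p4, 0), class = "gravityrankParameterError")
})

test_that("k-shell-mass gravity centralities G and G+ match hand evaluation", {
  p4 <- pathNet(4)  # all shells 1
  expect_equal(unname(scores(gravityCentrality(p4)))[1], 1 + 1 / 4 + 1 / 9)
  k5 <- completeNet(5)
  expect_equal(unname(scores(gravityCentrality(k5))), rep(64, 5))
  expect_equal(unname(scores(extendedGravityCentrality(k5))), rep(256, 5))
  edge <- netFromLines("a b")
  expect_equal(unname(scores(gravityCentrality(edge))), c(1, 1))
  # G+ of a one-neighbour node is its neighbour's G
  g <- scores(gravityCentrality(p4))
  gp <- scores(extendedGravityCentrality(p4))
  expect_equal(gp[["1"]], g[["2"]])
  # isolated node scores 0 in G+
  iso <- netFromLines("a b\nb c\nc a\nd d")
  expect_equal(scores(extendedGravityCentrality(iso))[["d"]], 0)
})

test_that("LGM is monotone in R and saturates to GM at the diameter", {
  nets <- c(list(pathNet(6), starNet(5), cycleNet(7), trianglePendant()),
            lapply(1:100, function(s) randomNet(sample(4:10, 1),
                                                runif(1, 0.2, 0.7),
                                                seed = 200 + s)))
  for (net in nets) {
    if (numEdges(net) == 0) next
    diam <- igraph::diameter(asIgraph(net), unconnected = TRUE)
    gm <- scores(gravityModel(net))
    prev <- scores(localGravityModel(net, 1))
    for (R in 2:(diam + 1)) {
      cur <- scores(localGravityModel(net, R))
      expect_true(all(cur >= prev - 1e-12))
      prev <- cur
    }
    expect_equal(scores(localGravityModel(net, max(diam, 1))), gm)
  }
})

test_that("GM pair contributions are symmetric: sum_i S(i) doubles the pair sum", {
  for (s in 1:20) {
    net <- randomNet(sample(4:12, 1), runif(1, 0.2, 0.8), seed = 300 + s)
    if (numEdges(net) == 0) next
    k <- unname(igraph::degree(asIgraph(net)))
    D <- bruteForceDistances(net)
    pairSum <- 0
    n <- numNodes(net)
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        if (is.finite(D[i, j]) && D[i, j] > 0)
          pairSum <- pairSum + k[i] * k[j] / D[i, j]^2
    expect_equal(sum(scores(gravityModel(net))), 2 * pairSum)
  }
})

test_that("betweenness agrees exactly with exhaustive geodesic enumeration", {
  for (s in 1:100) {
    net <- randomNet(sample(3:8, 1), runif(1, 0.25, 0.8), seed = 400 + s)
    expect_equal(scores(betweennessCentrality(net)),
                 scores(bruteForceBetweenness(net)), ignore_attr = FALSE)
  }
})

test_that("k-shell index is bounded by max degree and all methods are permutation-equivariant", {
  methodFuns <- list(degreeCentrality, hIndex, kShell, closenessCentrality,
                     betweennessCentrality, gravityModel,
                     function(n) localGravityModel(n, 2), gravityCentrality,
                     extendedGravityCentrality)
  for (s in 1:10) {
    net <- randomNet(sample(5:10, 1), runif(1, 0.3, 0.7), seed = 500 + s)
    ks <- scores(kShell(net))
    expect_lte(max(ks), max(igraph::degree(asIgraph(net)), 0))
    set.seed(s)
    lab <- nodeLabels(net)
    perm <- stats::setNames(sample(sprintf("v%02d", seq_along(lab))), lab)
    pnet <- permuteLabels(net, perm)
    for (f in methodFuns) {
      a <- scores(f(net))
      b <- scores(f(pnet))
      expect_equal(unname(b[perm[names(a)]]), unname(a))
    }
  }
})

test_that("rankTable sorts by descending score with label tie-breaks", {
  rt <- rankTable(degreeCentrality(starNet(3)))
  expect_equal(rt$node[1], "1")
  expect_equal(rt$node[-1], sort(rt$node[-1]))
  expect_true(all(diff(rt$score) <= 0))
})
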