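distFromAdj <- function(A, labels = as.character(seq_len(nrow(A)))) {
  connectivityToDistance(ConnectivityMatrix(A, labels, "wpli"))
}

test_that("efficiency reproduces closed-form small graphs", {
  # complete unit-weight graph: all shortest paths 1
  K <- matrix(1, 4, 4) - diag(4)
  expect_equal(networkEfficiency(distFromAdj(K)), 1)
  # 3-node path A-B-C: pairs (1,1,1/2) averaged over 3 pairs
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  expect_equal(networkEfficiency(distFromAdj(P)), (1 + 1 + 0.5) / 3)
  # empty graph
  expect_equal(networkEfficiency(distFromAdj(matrix(0, 5, 5))), 0)
})

test_that("efficiency equals the Floyd-Warshall oracle on random graphs", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(4:7, 1)
    A <- randomGraph(n, p = 0.6)
    dm <- distFromAdj(A)
    expect_equal(networkEfficiency(dm), oracleEfficiency(weightMatrix(dm)),
                 tolerance = 1e-10)
  }
})

test_that("efficiency never decreases when a weight increases", {
  set.seed(12)
  for (rep in 1:20) {
    A <- randomGraph(6, p = 0.5)
    e0 <- networkEfficiency(distFromAdj(A))
    ut <- which(upper.tri(A), arr.ind = TRUE)
    pick <- ut[sample(nrow(ut), 1), ]
    A2 <- A
    bump <- runif(1, 0.05, 0.5)
    A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <-
      min(1, A[pick[1], pick[2]] + bump)
    e1 <- networkEfficiency(distFromAdj(A2))
    expect_gte(e1 + 1e-12, e0)
  }
})

test_that("subgraph efficiency confines paths to the subset", {
  # A-B connected only through C: induced subgraph {A,B} is disconnected
  A <- matrix(0, 3, 3)
  A[1, 3] <- A[3, 1] <- A[2, 3] <- A[3, 2] <- 1
  dm <- distFromAdj(A, c("A", "B", "C"))
  expect_gt(networkEfficiency(dm), 0)
  expect_equal(networkEfficiency(dm, subset = c("A", "B")), 0)
  expect_error(networkEfficiency(dm, subset = c("A", "Z")), "unknown")
  expect_error(networkEfficiency(dm, subset = "A"), "2 members")
})

test_that("modularity Q matches the definition-based oracle", {
  # hand values: two disconnected triangles split by component
  B <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    B[p[1], p[2]] <- B[p[2], p[1]] <- 1
  expect_equal(modularityQ(B, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularityQ(B, rep(1, 6)), 0)
  # relabeling invariance
  expect_equal(modularityQ(B, c(7, 7, 7, 3, 3, 3)),
               modularityQ(B, c(1, 1, 1, 2, 2, 2)))
  # empty graph convention
  expect_equal(modularityQ(matrix(0, 4, 4), rep(1, 4)), 0)

  set.seed(21)
  for (rep in 1:25) {
    A <- randomGraph(6, p = 0.5)
    part <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularityQ(A, part), oracleModularity(A, part),
                 tolerance = 1e-12)
  }
})

test_that("Louvain recovers planted communities and respects the Q bound", {
  # two triangles joined by one bridge: partition = the triangles,
  # Q equal to the exhaustive maximum over all 203 partitions
  A <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4)))
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  part <- louvainPartition(A, seed = 1)
  expect_equal(part@membership[1:3], rep(part@membership[1], 3))
  expect_equal(part@membership[4:6], rep(part@membership[4], 3))
  expect_equal(part@Q, oracleMaxModularity(A), tolerance = 1e-12)

  # complete graph: one community, Q = 0
  K <- matrix(1, 5, 5) - diag(5)
  pk <- louvainPartition(K, seed = 2)
  expect_equal(pk@Q, 0, tolerance = 1e-12)

  # disconnected cliques: Q = 0.5 exactly
  B <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    B[p[1], p[2]] <- B[p[2], p[1]] <- 1
  expect_equal(louvainPartition(B, seed = 3)@Q, 0.5)

  # edgeless graph: singletons, Q = 0
  e <- louvainPartition(matrix(0, 4, 4), seed = 1)
  expect_equal(e@membership, 1:4)
  expect_equal(e@Q, 0)
})

test_that("Louvain agrees with igraph on binarized wPLI networks", {
  skip_if_not_installed("igraph")
  spec <- CouplingSpec(data.frame(
    i = c("A", "A", "B", "D", "D", "E"), j = c("B", "C", "C", "E", "F", "F"),
    freq = 10, lag = pi / 3, strength = 0.8), noiseSd = 0.5)
  rec <- generateCoupledRecording(spec, LETTERS[1:6], 250, 20, seed = 2)
  bin <- proportionalThreshold(wpliConnectivity(rec), 0.5)
  mine <- louvainPartition(bin, seed = 1)
  g <- igraph::graph_from_adjacency_matrix(weightMatrix(bin),
                                           mode = "undirected")
  ig <- igraph::cluster_louvain(g)
  expect_equal(mine@Q, igraph::modularity(g, igraph::membership(ig)),
               tolerance = 0.05)
})

test_that("eigenvector centrality matches closed forms and the dense solver", {
  # complete graph: uniform 1/sqrt(n)
  K <- matrix(1, 6, 6) - diag(6)
  cv <- eigenvectorCentrality(K)
  expect_equal(cv@values, rep(1 / sqrt(6), 6), tolerance = 1e-9)

  # star: center / leaf ratio = sqrt(n_leaves)
  n_leaves <- 8
  S <- matrix(0, n_leaves + 1, n_leaves + 1)
  S[1, -1] <- S[-1, 1] <- 1
  cs <- eigenvectorCentrality(S)
  expect_equal(cs@values[1] / cs@values[2], sqrt(n_leaves),
               tolerance = 1e-7)

  # random graphs vs dense eigendecomposition
  set.seed(31)
  for (rep in 1:20) {
    A <- randomGraph(10, p = 0.6)
    if (sum(A) == 0) next
    mine <- eigenvectorCentrality(A)@values
    ev <- eigen(A, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / sqrt(sum(ev^2))
    expect_lt(max(abs(mine - ev)), 1e-8)
  }

  # global scaling invariance
  A <- randomGraph(8, p = 0.5)
  expect_equal(eigenvectorCentrality(A)@values,
               eigenvectorCentrality(A * 37.5)@values, tolerance = 1e-8)

  expect_error(eigenvectorCentrality(matrix(0, 3, 3)), "no edges")
  expect_error(eigenvectorCentrality(randomGraph(6, 0.5), maxIter = 1),
               "converge")
})

test_that("regional aggregation uses induced subgraphs and mean centrality", {
  map <- defaultRegionMap()
  labs32 <- unlist(map@map, use.names = FALSE)
  # fully connected: every regional efficiency 1
  W <- matrix(1, 32, 32) - diag(32)
  dm <- distFromAdj(W, labs32)
  for (r in regionNames(map))
    expect_equal(regionalValue(dm, r, map, "efficiency"), 1)
  # uniform centrality: every regional mean = 1/sqrt(32)
  cv <- eigenvectorCentrality(ConnectivityMatrix(W, labs32, "wpli"))
  for (r in regionNames(map))
    expect_equal(regionalValue(cv, r, map, "centrality"), 1 / sqrt(32),
                 tolerance = 1e-9)
  # missing electrodes produce a named error
  dm16 <- distFromAdj(matrix(1, 16, 16) - diag(16), reducedMontage())
  expect_error(regionalValue(dm16, "frontal", map, "efficiency"),
               "missing.*F7")
})

test_that("planted frontal coupling raises frontal efficiency", {
  map <- restrictRegionMap(defaultRegionMap(), reducedMontage())
  base <- StudyDesign(nSubjects = 2)   # only to borrow default couplings
  highs <- lows <- numeric(25)
  for (s in 1:25) {
    spec_lo <- base@baseCoupling[["neutral.elevator"]]
    e_hi <- spec_lo@edges
    front <- vapply(e_hi$i, regionLookup, "", map = map) == "frontal" &
      vapply(e_hi$j, regionLookup, "", map = map) == "frontal"
    e_hi$strength[front] <- pmin(1, e_hi$strength[front] + 0.3)
    rec_lo <- generateCoupledRecording(spec_lo, reducedMontage(), 250, 10,
                                       seed = 9000 + s)
    rec_hi <- generateCoupledRecording(
      CouplingSpec(e_hi, noiseSd = spec_lo@noiseSd), reducedMontage(),
      250, 10, seed = 9000 + s)
    lows[s] <- epochRegionalEfficiency(rec_lo, "frontal", map)
    highs[s] <- epochRegionalEfficiency(rec_hi, "frontal", map)
  }
  expect_gte(mean(highs > lows), 0.95)
})
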