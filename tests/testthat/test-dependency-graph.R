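test_that("test correlation is Spearman on PC1 scores", {
  set.seed(14)
  scores <- matrix(rnorm(20 * 27), nrow = 20)
  tests <- c("DDK", "FNT", "FIN", "BAL", "FOO", "HST", "ROM", "WAL", "SPE")
  colnames(scores) <- as.vector(t(outer(tests, 1:3,
                                        function(a, b) sprintf("%s_PC%d", a, b))))
  # copying one test's scores into another forces rho = 1
  scores[, "FNT_PC1"] <- scores[, "DDK_PC1"]
  dg <- testCorrelation(scores)
  expect_equal(dg@rho["DDK", "FNT"], 1)
  # rank-then-Pearson oracle
  r_oracle <- cor(rank(scores[, "FIN_PC1"]), rank(scores[, "ROM_PC1"]))
  expect_equal(dg@rho["FIN", "ROM"], r_oracle, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  scores2 <- scores
  scores2[, "FIN_PC1"] <- exp(scores2[, "FIN_PC1"])
  dg2 <- testCorrelation(scores2)
  expect_equal(dg2@rho["FIN", "ROM"], dg@rho["FIN", "ROM"], tolerance = 1e-12)
  expect_error(
    testCorrelation(matrix(1, 6, 2,
                           dimnames = list(NULL, c("AAA_PC1", "BBB_PC1")))),
    "constant"
  )
})

test_that("rho-to-distance mappings evaluate at the anchor points", {
  expect_equal(rhoToDistance(1, "linear"), 0)
  expect_equal(rhoToDistance(1, "sqrt"), 0)
  expect_equal(rhoToDistance(0, "linear"), 1)
  expect_equal(rhoToDistance(0, "sqrt"), sqrt(2))
  expect_equal(rhoToDistance(-1, "linear"), 2)
  expect_equal(rhoToDistance(-1, "sqrt"), 2)
  expect_error(rhoToDistance(1.5), "out of")
})

test_that("MST is exact on small graphs and deterministic on ties", {
  # triangle with weights 1, 2, 3 keeps the two lightest edges
  D <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- minimumSpanningTree(D)
  expect_equal(mstTotalLength(tr), 3)
  expect_setequal(mstEdges(tr)$length, c(1, 2))
  # n - 1 edges always
  set.seed(15)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2)
    D <- D + t(D)
    expect_equal(nrow(mstEdges(minimumSpanningTree(D))), n - 1)
  }
  # ties broken lexicographically: equal-weight graph is reproducible
  D <- matrix(1, 4, 4) - diag(4)
  e1 <- mstEdges(minimumSpanningTree(D))
  e2 <- mstEdges(minimumSpanningTree(D))
  expect_identical(e1, e2)
})

test_that("MST total length equals the exhaustive spanning-tree minimum", {
  set.seed(16)
  for (i in 1:200) {
    n <- sample(3:6, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2)
    D <- D + t(D)
    expect_equal(mstTotalLength(minimumSpanningTree(D)),
                 oracle_mst_total(D), tolerance = 1e-12)
  }
})

test_that("the MST edge set is identical under both distance mappings", {
  set.seed(17)
  for (i in 1:20) {
    n <- 7
    rho <- matrix(0, n, n)
    rho[upper.tri(rho)] <- runif(n * (n - 1) / 2, -0.95, 0.95)
    rho <- rho + t(rho) + diag(n)
    rownames(rho) <- colnames(rho) <- LETTERS[1:n]
    e1 <- mstEdges(minimumSpanningTree(rhoToDistance(rho, "linear")))
    e2 <- mstEdges(minimumSpanningTree(rhoToDistance(rho, "sqrt")))
    expect_identical(e1[, c("from", "to")], e2[, c("from", "to")])
  }
})

test_that("tree centralities follow their definitions on hand examples", {
  # path A - B - C
  path <- methods::new("MSTree", nodes = c("A", "B", "C"),
                       edges = data.frame(from = c("A", "B"),
                                          to = c("B", "C"),
                                          length = c(1, 1)),
                       totalLength = 2)
  cen <- treeCentralities(path)
  b <- cen[cen$node == "B", ]
  expect_equal(b$degree, 2L)
  expect_equal(b$closeness, 1 / 2)
  expect_equal(b$betweenness, 1)
  # star with 4 leaves: center degree 4, betweenness C(4, 2) = 6
  star <- methods::new("MSTree", nodes = c("C0", paste0("L", 1:4)),
                       edges = data.frame(from = "C0",
                                          to = paste0("L", 1:4),
                                          length = 1),
                       totalLength = 4)
  cen <- treeCentralities(star)
  c0 <- cen[cen$node == "C0", ]
  expect_equal(c0$degree, 4L)
  expect_equal(c0$betweenness, 6)
})

test_that("centralities match an all-pairs brute force on random trees", {
  set.seed(18)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    nm <- sprintf("N%02d", 1:n)
    ed <- random_tree(n, nm)
    ed$length <- runif(nrow(ed))
    tr <- methods::new("MSTree", nodes = nm, edges = ed,
                       totalLength = sum(ed$length))
    got <- treeCentralities(tr)
    want <- oracle_tree_centralities(nm, ed)
    got <- got[match(nm, got$node), ]
    expect_equal(got$degree, want$degree, ignore_attr = TRUE)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("centrality measures are rank-correlated on random trees", {
  set.seed(19)
  rhos <- replicate(40, {
    n <- 10
    nm <- sprintf("N%02d", 1:n)
    ed <- random_tree(n, nm)
    ed$length <- runif(nrow(ed))
    tr <- methods::new("MSTree", nodes = nm, edges = ed,
                       totalLength = sum(ed$length))
    cen <- treeCentralities(tr)
    min(cor(cen$degree, cen$closeness, method = "spearman"),
        cor(cen$degree, cen$betweenness, method = "spearman"))
  })
  expect_gt(median(rhos), 0.5)
})

test_that("the SARA graph averages bilateral items into 8 nodes", {
  truth <- make_truth(6, 12, seed = 20)
  sg <- saraGraph(truth)
  expect_length(sg$graph@nodes, 8)
  expect_equal(nrow(mstEdges(sg$tree)), 7)
  expect_equal(sort(sg$graph@nodes),
               sort(c("SARA1_GAIT", "SARA2_STANCE", "SARA3_SITTIN",
                      "SARA4_SPEECH", "SARA5_FINGER", "SARA6_NOSEFINGER",
                      "SARA7_DKK", "SARA8_HEELSH")))
  # left = right implies the averaged column equals either side
  truth$sara5_finger_R <- truth$sara5_finger_L
  sg2 <- saraGraph(truth)
  expect_true(methods::is(sg2$graph, "DependencyGraph"))
  expect_error(saraGraph(truth[, 1:3]), "missing SARA")
})
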