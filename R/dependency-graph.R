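#' Spearman correlation network over tests
#'
#' Builds the test-level dependency network: one node per test, edge
#' weights from Spearman rank correlation between the tests' PC scores.
#' By default each test is represented by its first principal component
#' (the dominant-variance summary); alternatively the mean or maximum
#' absolute correlation over all PC pairs of the two tests is used.
#'
#' @param scores subjects x PC score matrix with \code{TEST_PCk} columns.
#' @param aggregation \code{"pc1"} (default), \code{"mean_abs_all_pairs"}
#'   or \code{"max_abs_all_pairs"}.
#' @param mode rho-to-distance mapping passed to
#'   \code{\link{rhoToDistance}}; \code{"sqrt"} (the metric form) by
#'   default.
#' @return a \linkS4class{DependencyGraph}.
#' @export
testCorrelation <- function(scores,
                            aggregation = c("pc1", "mean_abs_all_pairs",
                                            "max_abs_all_pairs"),
                            mode = c("sqrt", "linear")) {
  aggregation <- match.arg(aggregation)
  mode <- match.arg(mode)
  if (nrow(scores) < 5) stop("need at least 5 subjects")
  tests <- unique(sub("_PC\\d+$", "", colnames(scores)))
  n <- length(tests)
  rho <- diag(1, n)
  dimnames(rho) <- list(tests, tests)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- grep(paste0("^", tests[i], "_PC"), colnames(scores))
      cj <- grep(paste0("^", tests[j], "_PC"), colnames(scores))
      if (aggregation == "pc1") {
        r <- spearmanRho(scores[, ci[1]], scores[, cj[1]])
      } else {
        rs <- abs(outerSpearman(scores[, ci, drop = FALSE],
                                scores[, cj, drop = FALSE]))
        r <- if (aggregation == "mean_abs_all_pairs") mean(rs) else max(rs)
      }
      rho[i, j] <- rho[j, i] <- r
    }
  }
  methods::new("DependencyGraph",
    nodes = tests, rho = rho,
    dist = rhoToDistance(rho, mode), mode = mode
  )
}

spearmanRho <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant score column")
  }
  stats::cor(x, y, method = "spearman")
}

outerSpearman <- function(A, B) {
  out <- matrix(NA_real_, ncol(A), ncol(B))
  for (a in seq_len(ncol(A))) {
    for (b in seq_len(ncol(B))) out[a, b] <- spearmanRho(A[, a], B[, b])
  }
  out
}

#' Map Spearman correlations to edge distances
#'
#' \code{"linear"}: f(rho) = 1 - rho. \code{"sqrt"}:
#' f(rho) = sqrt(2 (1 - rho)), a proper metric. Both are strictly
#' decreasing in rho, so they induce the same minimum spanning tree.
#'
#' @param rho correlation value(s) in [-1, 1].
#' @param mode \code{"linear"} or \code{"sqrt"}.
#' @return distances of the same shape as \code{rho}.
#' @export
rhoToDistance <- function(rho, mode = c("sqrt", "linear")) {
  mode <- match.arg(mode)
  if (any(rho < -1 - 1e-12 | rho > 1 + 1e-12)) {
    stop("rho out of [-1, 1]")
  }
  rho <- pmin(pmax(rho, -1), 1)
  if (mode == "linear") 1 - rho else sqrt(2 * (1 - rho))
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with lexicographic edge tie-breaking (edges sorted
#' by length, then by node order), so the tree is deterministic even with
#' tied distances.
#'
#' @param dist symmetric distance matrix (or a
#'   \linkS4class{DependencyGraph}).
#' @return an \linkS4class{MSTree}.
#' @export
minimumSpanningTree <- function(dist) {
  if (methods::is(dist, "DependencyGraph")) dist <- dist@dist
  n <- nrow(dist)
  nodes <- rownames(dist)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (any(!is.finite(dist[upper.tri(dist)]))) {
    stop("disconnected input: non-finite distances")
  }
  idx <- which(upper.tri(dist), arr.ind = TRUE)
  ord <- order(dist[upper.tri(dist)], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  edges <- data.frame(from = character(0), to = character(0),
                      length = numeric(0))
  for (e in seq_len(nrow(idx))) {
    i <- idx[e, 1]
    j <- idx[e, 2]
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      edges <- rbind(edges, data.frame(
        from = nodes[i], to = nodes[j], length = dist[i, j]
      ))
      if (nrow(edges) == n - 1L) break
    }
  }
  if (nrow(edges) != n - 1L) stop("disconnected input")
  methods::new("MSTree",
    nodes = nodes, edges = edges,
    totalLength = sum(edges$length)
  )
}

#' Node centralities of a spanning tree
#'
#' Degree (number of adjoining edges), closeness (reciprocal of the sum
#' of hop distances to all other nodes) and betweenness (number of node
#' pairs whose unique tree path passes through the node).
#'
#' @param tree an \linkS4class{MSTree}.
#' @return data.frame with columns \code{node}, \code{degree},
#'   \code{closeness}, \code{betweenness}.
#' @export
treeCentralities <- function(tree) {
  g <- igraph::graph_from_data_frame(
    tree@edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = tree@nodes)
  )
  deg <- igraph::degree(g)
  clo <- igraph::closeness(g, weights = NA, normalized = FALSE)
  btw <- igraph::betweenness(g, weights = NA, directed = FALSE)
  data.frame(
    node = tree@nodes,
    degree = as.integer(deg[tree@nodes]),
    closeness = as.numeric(clo[tree@nodes]),
    betweenness = as.numeric(btw[tree@nodes]),
    row.names = NULL
  )
}

#' Dependency network of the clinical SARA items
#'
#' Averages the bilateral item scores (finger chase, nose-finger,
#' alternating hand movements, heel-shin) into one column per item,
#' builds the 8-node Spearman network over subjects, and runs the same
#' MST/centrality pipeline as for the instrumented tests.
#'
#' @param truth subject truth table with SARA item columns.
#' @param mode rho-to-distance mapping.
#' @return list with \code{graph}, \code{tree}, \code{centralities}.
#' @export
saraGraph <- function(truth, mode = c("sqrt", "linear")) {
  mode <- match.arg(mode)
  sara <- saraItemTable()
  if (!all(sara$item %in% colnames(truth))) stop("missing SARA item columns")
  items <- data.frame(
    SARA1_GAIT = truth$sara1_gait,
    SARA2_STANCE = truth$sara2_stance,
    SARA3_SITTIN = truth$sara3_sitting,
    SARA4_SPEECH = truth$sara4_speech,
    SARA5_FINGER = (truth$sara5_finger_L + truth$sara5_finger_R) / 2,
    SARA6_NOSEFINGER =
      (truth$sara6_nosefinger_L + truth$sara6_nosefinger_R) / 2,
    SARA7_DKK = (truth$sara7_hand_L + truth$sara7_hand_R) / 2,
    SARA8_HEELSH = (truth$sara8_heelshin_L + truth$sara8_heelshin_R) / 2
  )
  n <- ncol(items)
  rho <- diag(1, n)
  dimnames(rho) <- list(colnames(items), colnames(items))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rho[i, j] <- rho[j, i] <- spearmanRho(items[, i], items[, j])
    }
  }
  graph <- methods::new("DependencyGraph",
    nodes = colnames(items), rho = rho,
    dist = rhoToDistance(rho, mode), mode = mode
  )
  tree <- minimumSpanningTree(graph)
  list(graph = graph, tree = tree, centralities = treeCentralities(tree))
}
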