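# Independent brute-force oracles used to verify the package's operators.
# These deliberately use naive algorithms (exhaustive enumeration, double
# loops) and share no code with the implementations they check.

# DTW by memoised recursion over all monotone warping moves.
oracle_dtw <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    c0 <- abs(a[i] - b[j])
    v <- if (i == 1 && j == 1) {
      c0
    } else {
      prev <- Inf
      if (i > 1) prev <- min(prev, rec(i - 1, j))
      if (j > 1) prev <- min(prev, rec(i, j - 1))
      if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
      c0 + prev
    }
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

# Sample entropy by direct O(n^2) template counting.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nm <- n - m
  B <- 0
  A <- 0
  for (i in 1:(nm - 1)) {
    for (j in (i + 1):nm) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# Fuzzy entropy by direct double loop over mean-centred templates.
oracle_fuzzyen <- function(x, m, r, n_exp) {
  N <- length(x) - m
  phi <- function(mm) {
    tot <- 0
    cnt <- 0
    for (i in 1:(N - 1)) {
      for (j in (i + 1):N) {
        a <- x[i:(i + mm - 1)]
        a <- a - mean(a)
        b <- x[j:(j + mm - 1)]
        b <- b - mean(b)
        d <- max(abs(a - b))
        tot <- tot + exp(-(d / r)^n_exp)
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  -log(phi(m + 1) / phi(m))
}

# Two-sided MWW p by exhaustive enumeration of rank assignments.
oracle_mww_exact <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[1:nx])
  combs <- utils::combn(n, nx)
  Ws <- apply(combs, 2, function(id) sum(r[id]))
  mean(abs(Ws - nx * (n + 1) / 2) >= abs(W - nx * (n + 1) / 2) - 1e-9)
}

# Minimum spanning tree total length by enumerating all labelled trees
# (Pruefer sequences; Cayley's n^(n-2) trees).
oracle_mst_total <- function(D) {
  n <- nrow(D)
  if (n == 2) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(1:n), n - 2)))
  best <- Inf
  for (s in seq_len(nrow(seqs))) {
    pr <- seqs[s, ]
    deg <- rep(1, n)
    for (v in pr) deg[v] <- deg[v] + 1
    tot <- 0
    for (v in pr) {
      leaf <- min(which(deg == 1))
      tot <- tot + D[leaf, v]
      deg[leaf] <- 0
      deg[v] <- deg[v] - 1
    }
    last <- which(deg == 1)
    tot <- tot + D[last[1], last[2]]
    best <- min(best, tot)
  }
  best
}

# All-pairs hop distances and unique tree paths by breadth-first search
# over an edge list; returns degree/closeness/betweenness per node.
oracle_tree_centralities <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(nodes, function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  names(adj) <- nodes
  paths <- function(src) {
    parent <- stats::setNames(rep(NA_character_, n), nodes)
    seen <- src
    queue <- src
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!(w %in% seen)) {
          parent[w] <- v
          seen <- c(seen, w)
          queue <- c(queue, w)
        }
      }
    }
    parent
  }
  dist <- matrix(0, n, n, dimnames = list(nodes, nodes))
  btw <- stats::setNames(rep(0, n), nodes)
  for (src in nodes) {
    parent <- paths(src)
    for (dst in nodes) {
      if (dst == src) next
      path <- dst
      while (path[1] != src) path <- c(parent[[path[1]]], path)
      dist[src, dst] <- length(path) - 1
      inner <- setdiff(path, c(src, dst))
      # count each unordered pair once
      if (src < dst) for (v in inner) btw[v] <- btw[v] + 1
    }
  }
  data.frame(
    node = nodes,
    degree = vapply(adj, length, integer(1)),
    closeness = 1 / rowSums(dist),
    betweenness = as.numeric(btw),
    row.names = NULL
  )
}

# Direct DFT periodogram argmax (no FFT, no window) for the resonance
# cross-check.
oracle_dft_peak <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  ks <- 1:floor(n / 2)
  mag <- vapply(ks, function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))
  }, numeric(1))
  ks[which.max(mag)] * fs / n
}

# random labelled tree on n nodes via a random Pruefer sequence
random_tree <- function(n, node_names = as.character(seq_len(n))) {
  if (n == 2) {
    return(data.frame(from = node_names[1], to = node_names[2]))
  }
  pr <- sample(n, n - 2, replace = TRUE)
  deg <- rep(1, n)
  for (v in pr) deg[v] <- deg[v] + 1
  from <- integer(0)
  to <- integer(0)
  for (v in pr) {
    leaf <- min(which(deg == 1))
    from <- c(from, leaf)
    to <- c(to, v)
    deg[leaf] <- 0
    deg[v] <- deg[v] - 1
  }
  last <- which(deg == 1)
  from <- c(from, last[1])
  to <- c(to, last[2])
  data.frame(from = node_names[from], to = node_names[to])
}
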