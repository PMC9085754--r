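# independent oracles used across test files

# brute-force directed betweenness: enumerate every shortest path between
# every ordered pair by DFS over BFS layers, normalized by (n-1)(n-2)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    dist <- rep(Inf, n); dist[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(adj[v, ])) {
        if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; q <- c(q, w) }
      }
    }
    if (!is.finite(dist[t])) return(list())
    res <- list()
    recurse <- function(path) {
      v <- path[length(path)]
      if (v == t) { res[[length(res) + 1]] <<- path; return(invisible()) }
      if (dist[v] >= dist[t]) return(invisible())
      for (w in which(adj[v, ]))
        if (dist[w] == dist[v] + 1) recurse(c(path, w))
    }
    recurse(s)
    res
  }
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) if (s != t) {
    ps <- paths_between(s, t)
    if (length(ps)) {
      for (p in ps) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(ps)
      }
    }
  }
  bc / ((n - 1) * (n - 2))
}

random_digraph <- function(n, p = 0.4) {
  adj <- matrix(runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
  adj
}

digraph_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}

# exact combinatorial upper-tail hypergeometric sum
hyper_oracle <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# fraction of nodes agreeing with a planted 2-block partition under the best
# of the two label matchings
block_agreement <- function(membership, truth) {
  stopifnot(length(membership) == length(truth))
  m <- as.integer(membership == membership[1])
  t1 <- as.integer(truth == truth[1])
  max(mean(m == t1), mean(m != t1))
}

# planted 2-block undirected graph: edges within blocks with prob p_in,
# across with prob p_out
planted_two_block <- function(n_per_block = 20, p_in = 0.9, p_out = 0.05) {
  n <- 2 * n_per_block
  block <- rep(1:2, each = n_per_block)
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    p <- if (block[i] == block[j]) p_in else p_out
    adj[i, j] <- adj[j, i] <- as.integer(runif(1) < p)
  }
  dimnames(adj) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(graph = g, block = setNames(block, rownames(adj)))
}
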