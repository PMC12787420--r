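# Brute-force oracles, deliberately independent of igraph: shortest-path
# distances by Floyd-Warshall on the adjacency matrix, shortest-path counts
# by walk counting (every walk of minimal length is a shortest path), and
# hypergeometric tails by exhaustive subset enumeration.

# symmetric 0/1 adjacency matrix of a random simple graph
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# exact betweenness (normalized by (n-1)(n-2)/2) and component-restricted
# closeness from first principles
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  d <- floyd_warshall(adj)
  maxd <- max(0, d[is.finite(d)])
  # walks[[m + 1]] = adj^m, so walks[[d+1]][s,t] counts shortest s-t paths
  walks <- vector("list", maxd + 1)
  walks[[1]] <- diag(n)
  if (maxd >= 1) {
    for (m in seq_len(maxd)) walks[[m + 1]] <- walks[[m]] %*% adj
  }
  sigma <- function(s, t) walks[[d[s, t] + 1]][s, t]
  bc <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in seq((s + 1), n)) {
        if (!is.finite(d[s, t]) || d[s, t] < 2) next
        for (v in setdiff(seq_len(n), c(s, t))) {
          if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
              d[s, v] + d[v, t] == d[s, t]) {
            bc[v] <- bc[v] + sigma(s, v) * sigma(v, t) / sigma(s, t)
          }
        }
      }
    }
    bc <- bc * 2 / ((n - 1) * (n - 2))
  }
  cc <- vapply(seq_len(n), function(v) {
    reach <- d[v, is.finite(d[v, ])]
    if (length(reach) <= 1) 0 else (length(reach) - 1) / sum(reach)
  }, numeric(1))
  list(dc = rowSums(adj), bc = bc, cc = cc, dist = d)
}

adjacency_to_graph <- function(adj, names = sprintf("N%02d", seq_len(nrow(adj)))) {
  rownames(adj) <- colnames(adj) <- names
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# P[overlap >= k] by enumerating all n-subsets of a universe of size N in
# which K elements are "special"
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # elements 1..K are the special ones
  mean(hits >= k)
}
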