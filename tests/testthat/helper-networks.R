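# Shared fixture builders and independent oracles.

# Build a ppi_network straight from vectors (scores, not weights).
net_from_edges <- function(a, b, score) {
  build_network(data.frame(protein_a = a, protein_b = b, score = as.integer(score),
                           stringsAsFactors = FALSE))
}

# Build a network from integer edge WEIGHTS in [1, 850] (score = 1000 - w),
# convenient for shortest-path fixtures stated in weight space.
net_from_weights <- function(a, b, w) net_from_edges(a, b, 1000L - as.integer(w))

# Random connected graph: a random spanning tree plus `extra` random edges,
# integer weights uniform in [wmin, wmax]. Deterministic in `seed`.
random_connected_net <- function(n, extra = n, wmin = 1L, wmax = 850L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  a <- integer(0); b <- integer(0)
  for (v in 2:n) {           # spanning tree: attach each node to a random earlier one
    a <- c(a, v); b <- c(b, sample.int(v - 1L, 1L))
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  have <- paste(pmin(a, b), pmax(a, b))
  pool <- pairs[!paste(pairs[, 1], pairs[, 2]) %in% have, , drop = FALSE]
  if (extra > 0L && nrow(pool) > 0L) {
    take <- pool[sample.int(nrow(pool), min(extra, nrow(pool))), , drop = FALSE]
    a <- c(a, take[, 1]); b <- c(b, take[, 2])
  }
  w <- sample(seq.int(wmin, wmax), length(a), replace = TRUE)
  net_from_weights(ids[a], ids[b], w)
}

# Independent igraph oracle for single-source distances.
igraph_distances <- function(net, source) {
  g <- as_igraph(net)
  d <- igraph::distances(g, v = source, weights = igraph::E(g)$weight)
  stats::setNames(as.numeric(d[1, ]), colnames(d))[net$nodes]
}

# Betweenness oracle: count inner-node occurrences over exhaustively
# enumerated shortest paths, per unordered seed pair (all-paths semantics).
enumeration_betweenness <- function(net, seeds) {
  tal <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  seeds <- sort(seeds)
  for (i in seq_len(length(seeds) - 1L)) {
    for (j in seq(i + 1L, length(seeds))) {
      paths <- enumerate_shortest_paths(net, seeds[i], seeds[j])
      for (p in paths) {
        inner <- setdiff(p[-c(1L, length(p))], seeds)
        tal[inner] <- tal[inner] + 1
      }
    }
  }
  tal
}

# Exact brute-force hypergeometric upper tail from binomial coefficients
# (choose() is exact in double precision at the sizes used here).
hyper_brute_upper <- function(N, K, n, x) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
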