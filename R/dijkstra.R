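#' Single-source shortest-path DAG with path counts
#'
#' Runs Dijkstra's algorithm from one source over the weighted network and
#' returns, for every node, the shortest-path distance (sum of integer edge
#' weights), the number of distinct shortest paths from the source
#' (\code{sigma}), and the set of tight predecessors — every neighbour p of v
#' with \code{dist(p) + w(p, v) == dist(v)}. Ties in the priority queue are
#' resolved by (distance, node identifier) so runs are reproducible. Weights
#' are integers >= 1, so all comparisons are exact.
#'
#' @param network A \code{"ppi_network"} from [build_network()].
#' @param source Node identifier.
#' @param keep_preds Keep the predecessor lists (needed for path enumeration
#'   and one-path extraction; can be skipped when only distances and counts
#'   matter).
#' @return An object of class \code{"sp_dag"}: list with \code{source},
#'   \code{dist} (named numeric, \code{Inf} for unreachable), \code{sigma}
#'   (named numeric, 0 for unreachable) and \code{preds} (named list of
#'   predecessor identifiers, or NULL when \code{keep_preds = FALSE}).
#' @examples
#' net <- build_network(data.frame(protein_a = c("A", "A", "B", "C"),
#'                                 protein_b = c("B", "C", "D", "D"),
#'                                 score = 999L))
#' d <- dijkstra_dag(net, "A")
#' d$dist[["D"]]   # 2
#' d$sigma[["D"]]  # 2 tied shortest paths
#' @export
dijkstra_dag <- function(network, source, keep_preds = TRUE) {
  stopifnot(inherits(network, "ppi_network"))
  src <- match(source, network$nodes)
  if (is.na(src)) stop("source node not in network: ", source)
  res <- .dijkstra_idx(network, src, keep_preds = keep_preds)
  nodes <- network$nodes
  preds <- NULL
  if (keep_preds) {
    preds <- lapply(res$preds, function(ix) nodes[ix])
    names(preds) <- nodes
  }
  structure(
    list(source = source,
         dist = stats::setNames(res$dist, nodes),
         sigma = stats::setNames(res$sigma, nodes),
         preds = preds),
    class = "sp_dag"
  )
}

# Index-space Dijkstra; nodes are stored sorted, so index order is
# lexicographic order and which.min's first-minimum rule gives the
# deterministic (distance, identifier) tie-break.
.dijkstra_idx <- function(network, src, keep_preds = TRUE) {
  n <- length(network$nodes)
  adj <- network$adj
  adj_w <- network$adj_w
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  done <- logical(n)
  preds <- if (keep_preds) vector("list", n) else NULL
  dist[src] <- 0
  sigma[src] <- 1
  for (iter in seq_len(n)) {
    u <- which.min(replace(dist, done, Inf))
    if (is.infinite(dist[u]) || done[u]) break
    done[u] <- TRUE
    nbr <- adj[[u]]
    if (length(nbr) == 0L) next
    w <- adj_w[[u]]
    nd <- dist[u] + w
    for (k in seq_along(nbr)) {
      v <- nbr[k]
      if (done[v]) next
      if (nd[k] < dist[v]) {
        dist[v] <- nd[k]
        sigma[v] <- sigma[u]
        if (keep_preds) preds[[v]] <- u
      } else if (nd[k] == dist[v]) {
        sigma[v] <- sigma[v] + sigma[u]
        if (keep_preds) preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds)
}

#' Enumerate all shortest paths between two nodes
#'
#' Exhaustively lists every distinct minimum-total-weight path from \code{s} to
#' \code{t} by backtracking over the tight-predecessor DAG of [dijkstra_dag()].
#' This is the package's enumeration oracle for small graphs and reporting; the
#' production betweenness statistic never enumerates (it multiplies path
#' counts). A cap guards against combinatorial blow-up.
#'
#' @param network A \code{"ppi_network"}.
#' @param s,t Distinct node identifiers.
#' @param max_paths Abort with an error if more than this many paths exist
#'   (default 1e6).
#' @return A list of character vectors, each an ordered node sequence from
#'   \code{s} to \code{t}; empty list when \code{t} is unreachable.
#' @export
enumerate_shortest_paths <- function(network, s, t, max_paths = 1e6) {
  if (identical(s, t)) stop("s and t must be distinct nodes")
  dag <- dijkstra_dag(network, s, keep_preds = TRUE)
  if (!t %in% network$nodes) stop("node not in network: ", t)
  if (is.infinite(dag$dist[[t]])) return(list())
  if (dag$sigma[[t]] > max_paths) {
    stop("shortest-path count ", dag$sigma[[t]], " exceeds max_paths cap")
  }
  paths <- list()
  walk <- function(v, suffix) {
    if (v == s) {
      paths[[length(paths) + 1L]] <<- c(s, suffix)
      return(invisible())
    }
    for (p in sort(dag$preds[[v]])) walk(p, c(v, suffix))
  }
  walk(t, character(0))
  paths
}

# The deterministic single path for a pair: walk back from t taking the
# lexicographically smallest tight predecessor at each step.
.one_path <- function(dag, t) {
  path <- t
  v <- t
  while (v != dag$source) {
    v <- min(dag$preds[[v]])
    path <- c(v, path)
  }
  path
}
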