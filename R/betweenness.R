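#' Resolve requested seed genes against a network
#'
#' Partitions a requested seed list into the identifiers present in the network
#' (which drive discovery) and the missing ones (reported, then ignored).
#'
#' @param network A \code{"ppi_network"}.
#' @param requested Character vector of seed identifiers.
#' @return An object of class \code{"seed_set"}: list with \code{requested},
#'   \code{mapped} and \code{missing}. At least two mapped seeds are required.
#' @export
resolve_seeds <- function(network, requested) {
  stopifnot(inherits(network, "ppi_network"))
  requested <- unique(as.character(requested))
  if (length(requested) == 0L) stop("no seed genes requested")
  present <- requested %in% network$nodes
  mapped <- requested[present]
  missing <- requested[!present]
  if (length(mapped) < 2L) {
    stop("insufficient seeds in network: ", length(mapped),
         " of ", length(requested), " mapped (need >= 2)")
  }
  if (length(missing) > 0L) {
    message(length(missing), " seed gene(s) absent from the network: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "")
  }
  structure(list(requested = requested, mapped = mapped, missing = missing),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("Seed gene set:", length(x$mapped), "of", length(x$requested),
      "mapped to the network\n")
  invisible(x)
}

# Core tally in index space so the permutation loop pays no name lookups.
# seed_idx: sorted integer node indices. mode "all_paths" multiplies path
# counts (sigma_s(v) * sigma_t(v) on tight nodes); "one_path" walks the single
# deterministic path per pair. Returns numeric tally of length n plus the
# count of unreachable seed pairs.
.pair_tally <- function(network, seed_idx, mode = c("all_paths", "one_path")) {
  mode <- match.arg(mode)
  n <- length(network$nodes)
  k <- length(seed_idx)
  keep_preds <- mode == "one_path"
  dags <- lapply(seed_idx, function(s) .dijkstra_idx(network, s, keep_preds))
  tally <- numeric(n)
  unreachable <- 0L
  for (i in seq_len(k - 1L)) {
    di <- dags[[i]]
    for (j in seq((i + 1L), k)) {
      tgt <- seed_idx[j]
      D <- di$dist[tgt]
      if (is.infinite(D)) {
        unreachable <- unreachable + 1L
        next
      }
      if (mode == "all_paths") {
        dj <- dags[[j]]
        on_path <- which(di$dist + dj$dist == D)
        on_path <- setdiff(on_path, seed_idx)
        if (length(on_path) > 0L) {
          tally[on_path] <- tally[on_path] +
            di$sigma[on_path] * dj$sigma[on_path]
        }
      } else {
        path <- tgt
        v <- tgt
        src <- seed_idx[i]
        while (v != src) {
          v <- min(di$preds[[v]])
          path <- c(v, path)
        }
        inner <- setdiff(path[-c(1L, length(path))], seed_idx)
        tally[inner] <- tally[inner] + 1
      }
    }
  }
  list(tally = tally, unreachable_pairs = unreachable)
}

#' Seed-pair path betweenness of every node
#'
#' For every unordered pair of mapped seed genes, finds the shortest paths
#' between them and tallies, for each non-seed node, how many of those paths
#' contain it as an inner node. In \code{mode = "all_paths"} (the default) a
#' node's tally for a pair (s, t) is the number of distinct shortest s-t paths
#' through it, computed without enumeration as
#' \code{sigma_s(v) * sigma_t(v)} on nodes where
#' \code{dist_s(v) + dist_t(v) == dist_s(t)}. In \code{mode = "one_path"} each
#' pair contributes a single deterministically chosen path (lexicographically
#' smallest tight predecessor at every step back from t) and tallies its inner
#' nodes once. Seed genes are never tallied, even when interior to another
#' pair's path; unreachable pairs are skipped and counted.
#'
#' @param network A \code{"ppi_network"}.
#' @param seeds A \code{"seed_set"} from [resolve_seeds()], or a character
#'   vector of seed identifiers (resolved on the fly).
#' @param mode \code{"all_paths"} or \code{"one_path"}.
#' @return Named numeric vector over all network nodes (0 for nodes on no
#'   seed-pair shortest path), with attribute \code{"unreachable_pairs"}.
#' @export
seed_pair_betweenness <- function(network, seeds,
                                  mode = c("all_paths", "one_path")) {
  mode <- match.arg(mode)
  if (!inherits(seeds, "seed_set")) seeds <- resolve_seeds(network, seeds)
  seed_idx <- sort(match(seeds$mapped, network$nodes))
  res <- .pair_tally(network, seed_idx, mode)
  out <- stats::setNames(res$tally, network$nodes)
  attr(out, "unreachable_pairs") <- res$unreachable_pairs
  out
}

#' Discover candidate genes from seed-pair shortest paths
#'
#' Stage I of the discovery pipeline: every non-seed gene lying strictly inside
#' at least one shortest path between two mapped seed genes becomes a
#' candidate, scored by its path betweenness (see [seed_pair_betweenness()]).
#'
#' @inheritParams seed_pair_betweenness
#' @return A data frame of class \code{"candidate_table"} with columns
#'   \code{gene} and \code{betweenness}, sorted by betweenness descending and
#'   identifier ascending; empty (with a warning) when no seed pair has an
#'   inner node. Attributes: \code{"mode"}, \code{"unreachable_pairs"},
#'   \code{"seeds"} (the mapped seed identifiers).
#' @export
discover_candidates <- function(network, seeds,
                                mode = c("all_paths", "one_path")) {
  mode <- match.arg(mode)
  if (!inherits(seeds, "seed_set")) seeds <- resolve_seeds(network, seeds)
  tal <- seed_pair_betweenness(network, seeds, mode)
  hit <- tal[tal >= 1]
  tab <- data.frame(gene = names(hit), betweenness = unname(hit),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$betweenness, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab) == 0L) {
    warning("no candidate genes: every reachable seed pair is adjacent")
  }
  structure(tab,
            class = c("candidate_table", "data.frame"),
            mode = mode,
            unreachable_pairs = attr(tal, "unreachable_pairs"),
            seeds = seeds$mapped)
}

#' Write a candidate table as TSV
#'
#' @param candidates A \code{"candidate_table"} (or compatible data frame).
#' @param path Output path; columns \code{gene<TAB>betweenness} (plus any FDR
#'   columns present).
#' @return \code{path}, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
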