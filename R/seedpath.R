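#' Seed-based shortest-path candidate gene discovery
#'
#' Fits the full two-stage discovery model on a weighted interaction network.
#' Stage I finds, for every pair of mapped seed genes, all shortest paths
#' (Dijkstra on edge weights \code{1000 - score}) and scores each non-seed
#' inner node by its path betweenness. Stage II compares every candidate's
#' betweenness against \code{n_sets} random seed sets of the same size and
#' assigns a permutation FDR (fraction of random sets whose betweenness
#' strictly exceeds the observed value); candidates with FDR strictly below
#' \code{alpha} are flagged significant.
#'
#' @param network A \code{"ppi_network"} from [build_network()].
#' @param seeds Character vector of seed gene identifiers, or a
#'   \code{"seed_set"}.
#' @param mode Path-counting mode: \code{"all_paths"} (default; every tied
#'   shortest path counts) or \code{"one_path"} (one deterministic path per
#'   pair).
#' @param n_sets Random sets for the permutation null (default 500).
#' @param alpha Significance threshold on the permutation FDR (default 0.05).
#' @param rng_seed Integer seed for the permutation sampler (default 1).
#' @param pool Sampling pool: \code{"all_nodes"} (default) or
#'   \code{"non_seed_nodes"}.
#' @return An object of class \code{"seedpath"}: list with \code{seeds} (the
#'   resolved \code{"seed_set"}), \code{candidates} (Stage I
#'   \code{"candidate_table"}), \code{permutation} (Stage II
#'   \code{"permutation_result"}), \code{alpha}, \code{mode}, \code{network}
#'   and the matched \code{call}. Use [summary()], [coef()], [plot()],
#'   [simulate()] and [select_significant()] on it.
#' @examples
#' sim <- simulate_network(synthetic_spec(n_background = 60, n_seeds = 5,
#'                                        n_bridges = 1))
#' fit <- seedpath(sim$network, sim$truth$seed_ids, n_sets = 50, rng_seed = 7)
#' fit
#' head(coef(fit))
#' @export
seedpath <- function(network, seeds, mode = c("all_paths", "one_path"),
                     n_sets = 500L, alpha = 0.05, rng_seed = 1L,
                     pool = c("all_nodes", "non_seed_nodes")) {
  mode <- match.arg(mode)
  pool <- match.arg(pool)
  stopifnot(inherits(network, "ppi_network"))
  if (!inherits(seeds, "seed_set")) seeds <- resolve_seeds(network, seeds)
  candidates <- discover_candidates(network, seeds, mode)
  permutation <- if (nrow(candidates) > 0L) {
    permutation_fdr(network, seeds, candidates, n_sets = n_sets,
                    alpha = alpha, rng_seed = rng_seed, pool = pool,
                    mode = mode)
  } else {
    structure(data.frame(gene = character(0), betweenness = numeric(0),
                         exceed_count = integer(0), fdr = numeric(0),
                         significant = logical(0)),
              class = c("permutation_result", "data.frame"))
  }
  structure(
    list(seeds = seeds, candidates = candidates, permutation = permutation,
         alpha = alpha, mode = mode, network = network,
         call = match.call()),
    class = "seedpath"
  )
}

#' @export
print.seedpath <- function(x, ...) {
  cat("Seed-based shortest-path gene discovery\n")
  cat("  seeds mapped:     ", length(x$seeds$mapped), "of",
      length(x$seeds$requested), "\n")
  cat("  network:          ", length(x$network$nodes), "nodes,",
      nrow(x$network$edges), "edges\n")
  cat("  mode:             ", x$mode, "\n")
  cat("  candidates:       ", nrow(x$candidates), "\n")
  prov <- attr(x$permutation, "provenance")
  if (!is.null(prov)) {
    cat("  permutation sets: ", prov$n_sets, "(rng_seed", prov$rng_seed, ")\n")
  }
  cat("  significant (FDR <", format(x$alpha), "):",
      sum(x$permutation$significant), "\n")
  invisible(x)
}

#' Summarize a seedpath fit
#'
#' @param object A \code{"seedpath"} fit.
#' @param ... Unused.
#' @return A \code{"summary.seedpath"}: counts per stage, the number of
#'   unreachable seed pairs, the permutation provenance, and the table of
#'   significant candidates.
#' @export
summary.seedpath <- function(object, ...) {
  structure(
    list(n_requested = length(object$seeds$requested),
         n_mapped = length(object$seeds$mapped),
         n_missing = length(object$seeds$missing),
         n_nodes = length(object$network$nodes),
         n_edges = nrow(object$network$edges),
         unreachable_pairs = attr(object$candidates, "unreachable_pairs"),
         mode = object$mode,
         alpha = object$alpha,
         n_candidates = nrow(object$candidates),
         n_significant = sum(object$permutation$significant),
         provenance = attr(object$permutation, "provenance"),
         significant = select_significant(object$permutation, object$alpha)),
    class = "summary.seedpath"
  )
}

#' @export
print.summary.seedpath <- function(x, ...) {
  cat("Seed-based shortest-path gene discovery\n\n")
  cat("Network: ", x$n_nodes, " nodes, ", x$n_edges, " edges\n", sep = "")
  cat("Seeds:   ", x$n_mapped, " mapped / ", x$n_requested, " requested",
      if (x$n_missing > 0) paste0(" (", x$n_missing, " missing)"), "\n",
      sep = "")
  cat("Stage I: ", x$n_candidates, " candidate genes (mode ", x$mode, ", ",
      x$unreachable_pairs, " unreachable seed pairs)\n", sep = "")
  if (!is.null(x$provenance)) {
    cat("Stage II: ", x$provenance$n_sets, " random sets of size ",
        x$provenance$seed_set_size, " from ", x$provenance$pool_size,
        " nodes (rng_seed ", x$provenance$rng_seed, ")\n", sep = "")
  }
  cat("Significant candidates (permutation FDR < ", format(x$alpha), "): ",
      x$n_significant, "\n", sep = "")
  if (nrow(x$significant) > 0L) {
    cat("\n")
    print(utils::head(
      x$significant[, c("gene", "betweenness", "fdr")], 20L))
    if (nrow(x$significant) > 20L) {
      cat("... and", nrow(x$significant) - 20L, "more\n")
    }
  }
  invisible(x)
}

#' Candidate betweenness values from a seedpath fit
#'
#' @param object A \code{"seedpath"} fit.
#' @param ... Unused.
#' @return Named numeric vector of path betweenness, one entry per candidate,
#'   in the candidate-table order (betweenness descending).
#' @export
coef.seedpath <- function(object, ...) {
  stats::setNames(object$candidates$betweenness, object$candidates$gene)
}

#' Plot betweenness against permutation FDR
#'
#' One point per candidate: observed path betweenness (log scale when the
#' spread warrants it) against permutation FDR, with the significance
#' threshold drawn and significant candidates filled.
#'
#' @param x A \code{"seedpath"} fit.
#' @param ... Passed to [plot.default()].
#' @return \code{x}, invisibly.
#' @export
plot.seedpath <- function(x, ...) {
  p <- x$permutation
  if (nrow(p) == 0L) {
    stop("nothing to plot: the fit has no candidates")
  }
  logx <- if (max(p$betweenness) / max(1, min(p$betweenness)) > 50) "x" else ""
  plot(p$betweenness, p$fdr, log = logx,
       pch = ifelse(p$significant, 19, 1),
       col = ifelse(p$significant, "firebrick", "grey40"),
       xlab = "path betweenness (seed-pair shortest paths through gene)",
       ylab = "permutation FDR", ...)
  graphics::abline(h = x$alpha, lty = 2)
  invisible(x)
}

#' Simulate null betweenness tables from a seedpath fit
#'
#' Draws \code{nsim} fresh random seed sets (same size and pool as the fit's
#' permutation stage) and recomputes every candidate's betweenness under each
#' — the null replicates the permutation FDR is built from.
#'
#' @param object A \code{"seedpath"} fit.
#' @param nsim Number of null draws (default 1).
#' @param seed Integer RNG seed (default 1).
#' @param ... Unused.
#' @return Data frame with one row per candidate and one column per draw
#'   (\code{sim_1}, \code{sim_2}, ...), rownames = candidate genes.
#' @export
simulate.seedpath <- function(object, nsim = 1, seed = 1L, ...) {
  prov <- attr(object$permutation, "provenance")
  if (is.null(prov)) stop("fit has no permutation stage to simulate from")
  sets <- sample_random_seed_sets(object$network, prov$seed_set_size,
                                  n_sets = nsim, rng_seed = seed,
                                  pool = prov$pool,
                                  seeds = object$seeds$mapped)
  cand_idx <- match(object$candidates$gene, object$network$nodes)
  cols <- lapply(sets, function(set) {
    set_idx <- sort(match(set, object$network$nodes))
    .pair_tally(object$network, set_idx, object$mode)$tally[cand_idx]
  })
  out <- as.data.frame(cols, col.names = paste0("sim_", seq_len(nsim)))
  rownames(out) <- object$candidates$gene
  out
}

#' @rdname select_significant
#' @export
select_significant.seedpath <- function(result, alpha = NULL) {
  if (is.null(alpha)) alpha <- result$alpha
  select_significant(result$permutation, alpha)
}
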