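#' Draw random seed-sized gene sets from the network
#'
#' Builds the permutation null: \code{n_sets} gene sets of the same size as the
#' observed seed set, drawn uniformly without replacement from the sampling
#' pool. The pool is either every network node (default, the plain reading of
#' "gene sets whose sizes were equal" drawn from the graph) or the nodes minus
#' the true seeds.
#'
#' @param network A \code{"ppi_network"}.
#' @param size Set size (the number of mapped seed genes).
#' @param n_sets Number of sets (default 500).
#' @param rng_seed Integer seed; the whole sequence of sets is a deterministic
#'   function of it.
#' @param pool \code{"all_nodes"} or \code{"non_seed_nodes"}.
#' @param seeds Mapped seed identifiers; required when
#'   \code{pool = "non_seed_nodes"}.
#' @return List of character vectors, each of \code{size} distinct identifiers.
#' @export
sample_random_seed_sets <- function(network, size, n_sets = 500L,
                                    rng_seed = 1L,
                                    pool = c("all_nodes", "non_seed_nodes"),
                                    seeds = NULL) {
  stopifnot(inherits(network, "ppi_network"))
  pool <- match.arg(pool)
  universe <- network$nodes
  if (pool == "non_seed_nodes") {
    if (is.null(seeds)) stop("seeds required for pool = 'non_seed_nodes'")
    universe <- setdiff(universe, seeds)
  }
  if (size > length(universe)) {
    stop("requested set size ", size, " exceeds sampling pool of ",
         length(universe), " nodes")
  }
  if (n_sets < 1L) stop("n_sets must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(rng_seed)
  lapply(seq_len(n_sets), function(i) sample(universe, size))
}

#' Permutation false discovery rate of candidate genes
#'
#' Stage II of the discovery pipeline. For each of \code{n_sets} random gene
#' sets (same size as the observed seed set), the seed-pair betweenness of
#' every candidate is recomputed with the identical path-counting mode. A
#' candidate's permutation FDR is the fraction of random sets under which its
#' betweenness strictly exceeds the observed value ("exceeded" is read as
#' \code{>}; ties do not count against a candidate). Candidates absent from a
#' random run's paths get null betweenness 0 for that run.
#'
#' @param network A \code{"ppi_network"}.
#' @param seeds A \code{"seed_set"} or character vector of seed identifiers.
#' @param candidates A \code{"candidate_table"} from [discover_candidates()]
#'   computed on the same network, seeds and mode.
#' @param n_sets Number of random sets (default 500).
#' @param alpha Significance threshold on the FDR (default 0.05, strict
#'   \code{<}).
#' @param rng_seed Integer seed for the sampler.
#' @param pool Sampling pool policy, see [sample_random_seed_sets()].
#' @param mode Path-counting mode; must match the one used for
#'   \code{candidates}.
#' @return A data frame of class \code{"permutation_result"} with columns
#'   \code{gene}, \code{betweenness}, \code{exceed_count}, \code{fdr}
#'   (\code{= exceed_count / n_sets} exactly) and \code{significant}
#'   (\code{fdr < alpha}), one row per candidate in the input order, with a
#'   \code{"provenance"} attribute (rng_seed, n_sets, alpha, pool, pool size,
#'   seed-set size, mode).
#' @export
permutation_fdr <- function(network, seeds, candidates,
                            n_sets = 500L, alpha = 0.05, rng_seed = 1L,
                            pool = c("all_nodes", "non_seed_nodes"),
                            mode = NULL) {
  pool <- match.arg(pool)
  if (!inherits(seeds, "seed_set")) seeds <- resolve_seeds(network, seeds)
  cand_mode <- attr(candidates, "mode")
  if (is.null(mode)) mode <- if (is.null(cand_mode)) "all_paths" else cand_mode
  if (!is.null(cand_mode) && !identical(mode, cand_mode)) {
    stop("mode mismatch: candidates were discovered with mode '", cand_mode,
         "' but permutation requested '", mode, "'")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")

  size <- length(seeds$mapped)
  sets <- sample_random_seed_sets(network, size, n_sets = n_sets,
                                  rng_seed = rng_seed, pool = pool,
                                  seeds = seeds$mapped)
  cand_idx <- match(candidates$gene, network$nodes)
  if (anyNA(cand_idx)) stop("candidate gene(s) absent from the network")
  observed <- candidates$betweenness
  exceed <- integer(nrow(candidates))
  for (set in sets) {
    set_idx <- sort(match(set, network$nodes))
    null_tally <- .pair_tally(network, set_idx, mode)$tally
    exceed <- exceed + (null_tally[cand_idx] > observed)
  }
  fdr <- exceed / n_sets
  res <- data.frame(
    gene = candidates$gene,
    betweenness = observed,
    exceed_count = as.integer(exceed),
    fdr = fdr,
    significant = fdr < alpha,
    stringsAsFactors = FALSE
  )
  pool_size <- if (pool == "all_nodes") length(network$nodes) else
    length(network$nodes) - size
  structure(res,
            class = c("permutation_result", "data.frame"),
            provenance = list(rng_seed = rng_seed, n_sets = n_sets,
                              alpha = alpha, pool = pool,
                              pool_size = pool_size, seed_set_size = size,
                              mode = mode))
}

#' Select significant candidates
#'
#' Retains exactly the candidates with permutation FDR strictly smaller than
#' \code{alpha} (an FDR equal to the threshold is excluded), preserving the
#' input ordering.
#'
#' @param result A \code{"permutation_result"} (or data frame with an
#'   \code{fdr} column).
#' @param alpha Threshold (default 0.05).
#' @return The significant rows of \code{result}.
#' @export
select_significant <- function(result, alpha = 0.05) {
  UseMethod("select_significant")
}

#' @rdname select_significant
#' @export
select_significant.default <- function(result, alpha = 0.05) {
  stopifnot(is.data.frame(result), "fdr" %in% names(result))
  out <- result[result$fdr < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a permutation result as TSV with a provenance sidecar
#'
#' Emits \code{gene<TAB>betweenness<TAB>permutation_fdr<TAB>significant} plus a
#' JSON sidecar (\code{<path>.provenance.json}) recording the RNG seed, set
#' count, pool and mode.
#'
#' @param result A \code{"permutation_result"}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_permutation_tsv <- function(result, path) {
  df <- data.frame(gene = result$gene, betweenness = result$betweenness,
                   permutation_fdr = result$fdr,
                   significant = result$significant)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  prov <- attr(result, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
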