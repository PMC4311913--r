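#' Run the full discovery pipeline from a configuration
#'
#' Orchestrates graph construction, Stage I candidate discovery, Stage II
#' permutation filtering and (optionally) gene-set enrichment of the
#' significant candidates, writing every stage's output to the configured
#' directory. Rerunning with an identical configuration yields byte-identical
#' outputs.
#'
#' Configuration keys (flat, a YAML file or an R list):
#' \describe{
#'   \item{network}{path to a STRING-dialect interaction file (required)}
#'   \item{seeds}{path to a one-identifier-per-line seed list (required)}
#'   \item{out_dir}{output directory (required)}
#'   \item{gene_sets}{optional GMT file; enables the enrichment stage}
#'   \item{universe}{\code{"collection"} (default) or \code{"network"} — the
#'     hypergeometric universe}
#'   \item{min_score}{score floor at parse time (default 150)}
#'   \item{mode}{\code{"all_paths"} (default) or \code{"one_path"}}
#'   \item{n_sets}{permutation sets (default 500)}
#'   \item{alpha}{FDR threshold (default 0.05)}
#'   \item{rng_seed}{permutation RNG seed (default 1)}
#'   \item{pool}{\code{"all_nodes"} (default) or \code{"non_seed_nodes"}}
#' }
#'
#' Outputs in \code{out_dir}: \code{network.tsv}, \code{candidates.tsv},
#' \code{permutation.tsv} (+ provenance sidecar), \code{significant.tsv},
#' \code{enrichment.tsv} (when gene sets are given), \code{run_report.json}
#' and \code{resolved_config.yaml}.
#'
#' @param config A named list or the path to a YAML file.
#' @param quiet Suppress per-stage messages.
#' @return The run report (named list of per-stage counts and output paths),
#'   invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(min_score = 150L, mode = "all_paths", n_sets = 500L,
                   alpha = 0.05, rng_seed = 1L, pool = "all_nodes",
                   universe = "collection", gene_sets = NULL)
  cfg <- utils::modifyList(defaults, config)
  for (key in c("network", "seeds", "out_dir")) {
    if (is.null(cfg[[key]])) stop("config missing required key: ", key)
  }
  for (key in c("network", "seeds", "gene_sets")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config path does not exist (", key, "): ", cfg[[key]])
    }
  }
  say <- function(...) if (!quiet) message("[seedpath] ", ...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  say("stage build-graph: parsing ", cfg$network)
  records <- parse_interactions(cfg$network, min_score = cfg$min_score)
  network <- build_network(records)
  write_network_tsv(network, out("network.tsv"))
  say("stage build-graph: ", length(network$nodes), " nodes, ",
      nrow(network$edges), " edges")

  say("stage discover: resolving seeds from ", cfg$seeds)
  seeds <- resolve_seeds(network, read_gene_list(cfg$seeds))
  candidates <- discover_candidates(network, seeds, cfg$mode)
  write_candidates_tsv(candidates, out("candidates.tsv"))
  say("stage discover: ", nrow(candidates), " candidate genes (",
      attr(candidates, "unreachable_pairs"), " unreachable seed pairs)")

  say("stage permute: ", cfg$n_sets, " random sets, rng_seed ", cfg$rng_seed)
  permutation <- permutation_fdr(network, seeds, candidates,
                                 n_sets = cfg$n_sets, alpha = cfg$alpha,
                                 rng_seed = cfg$rng_seed, pool = cfg$pool,
                                 mode = cfg$mode)
  write_permutation_tsv(permutation, out("permutation.tsv"))
  significant <- select_significant(permutation, cfg$alpha)
  write_permutation_tsv(significant, out("significant.tsv"))
  say("stage permute: ", nrow(significant), " significant candidates")

  enrichment_rows <- NA_integer_
  if (!is.null(cfg$gene_sets)) {
    say("stage enrich: ", cfg$gene_sets)
    universe <- if (identical(cfg$universe, "network")) network$nodes else NULL
    collection <- read_gmt(cfg$gene_sets, universe = universe)
    if (nrow(significant) > 0L) {
      enr <- enrich(significant$gene, collection)
      write_enrichment_tsv(enr, out("enrichment.tsv"))
      enrichment_rows <- nrow(enr)
      say("stage enrich: ", enrichment_rows, " gene sets tested")
    } else {
      say("stage enrich: skipped, no significant candidates")
    }
  }

  report <- list(
    n_nodes = length(network$nodes),
    n_edges = nrow(network$edges),
    seeds_requested = length(seeds$requested),
    seeds_mapped = length(seeds$mapped),
    seeds_missing = length(seeds$missing),
    unreachable_pairs = attr(candidates, "unreachable_pairs"),
    n_candidates = nrow(candidates),
    n_significant = nrow(significant),
    n_enrichment_rows = enrichment_rows,
    parameters = cfg[c("min_score", "mode", "n_sets", "alpha", "rng_seed",
                       "pool", "universe")],
    outputs = list(
      network = out("network.tsv"),
      candidates = out("candidates.tsv"),
      permutation = out("permutation.tsv"),
      significant = out("significant.tsv"),
      enrichment = if (!is.na(enrichment_rows)) out("enrichment.tsv") else NULL
    )
  )
  jsonlite::write_json(report, out("run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  yaml::write_yaml(cfg, out("resolved_config.yaml"))
  invisible(report)
}
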