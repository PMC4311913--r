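#' Specification for a synthetic interaction network with planted truth
#'
#' Defines a STRING-like synthetic network: a heavy-tailed background graph
#' (preferential attachment) with uniform integer confidence scores, plus a
#' planted module of seed genes connected through designated high-confidence
#' "bridge" genes. Because the bridge score strictly exceeds the background
#' score ceiling, the cheapest route between any two planted seeds is the
#' two-hop seed-bridge-seed path (weight \code{2 * (1000 - bridge_score)}),
#' while any background detour costs at least
#' \code{2 * (1000 - max(background_score_range))}. Every bridge therefore lies
#' on one tied shortest path per seed pair, with betweenness
#' \code{choose(n_seeds, 2)} under all-paths counting — known ground truth for
#' recovery tests.
#'
#' @param n_background Background node count (default 300).
#' @param attachment Edges added per new background node (default 2); the
#'   background has exactly \code{attachment * (n_background - attachment)}
#'   edges.
#' @param n_seeds Planted seed genes (default 10).
#' @param n_bridges Planted bridge genes (default 3).
#' @param bridge_score Confidence score of every seed-bridge edge (default
#'   990); must strictly exceed \code{max(background_score_range)}.
#' @param background_score_range Integer score interval for background and
#'   decoy edges (default \code{c(150, 800)}), within [150, 999].
#' @param decoy_edges_per_seed Random seed-to-background edges per seed
#'   (default 2), so seeds are embedded in the background, not isolated.
#' @param rng_seed Integer seed driving all randomness (default 3).
#' @return A \code{"synthetic_spec"} list of the validated parameters.
#' @export
synthetic_spec <- function(n_background = 300L, attachment = 2L,
                           n_seeds = 10L, n_bridges = 3L,
                           bridge_score = 990L,
                           background_score_range = c(150L, 800L),
                           decoy_edges_per_seed = 2L, rng_seed = 3L) {
  spec <- list(n_background = as.integer(n_background),
               attachment = as.integer(attachment),
               n_seeds = as.integer(n_seeds),
               n_bridges = as.integer(n_bridges),
               bridge_score = as.integer(bridge_score),
               background_score_range = as.integer(background_score_range),
               decoy_edges_per_seed = as.integer(decoy_edges_per_seed),
               rng_seed = as.integer(rng_seed))
  if (spec$n_seeds < 2L) stop("n_seeds must be >= 2")
  if (spec$n_bridges < 1L) stop("n_bridges must be >= 1")
  if (length(spec$background_score_range) != 2L ||
      spec$background_score_range[1L] > spec$background_score_range[2L] ||
      spec$background_score_range[1L] < 150L ||
      spec$background_score_range[2L] > 999L) {
    stop("background_score_range must be an increasing interval within [150, 999]")
  }
  if (spec$bridge_score <= spec$background_score_range[2L]) {
    stop("bridge_score must strictly exceed the background score ceiling ",
         "(shortest-path dominance of the planted module requires it)")
  }
  if (spec$bridge_score > 999L) stop("bridge_score must be <= 999")
  if (spec$n_background < spec$attachment + 1L) {
    stop("n_background must exceed attachment")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate the heavy-tailed background network
#'
#' Preferential attachment: the first \code{attachment} nodes start isolated;
#' each subsequent node attaches to \code{attachment} distinct existing nodes
#' chosen with probability proportional to degree + 1. Each edge gets an
#' integer score drawn uniformly from \code{background_score_range}. The graph
#' is connected and has exactly \code{attachment * (n_background - attachment)}
#' edges; everything is a deterministic function of \code{rng_seed}.
#'
#' @param spec A \code{"synthetic_spec"}.
#' @return A \code{"ppi_network"} over nodes \code{BG0001}, \code{BG0002}, ...
#' @export
generate_background <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$rng_seed)
  n <- spec$n_background
  m <- spec$attachment
  ids <- sprintf("BG%04d", seq_len(n))
  deg <- integer(n)
  from <- integer(0)
  to <- integer(0)
  for (v in seq(m + 1L, n)) {
    existing <- seq_len(v - 1L)
    targets <- sample(existing, m, prob = deg[existing] + 1)
    from <- c(from, rep.int(v, m))
    to <- c(to, targets)
    deg[v] <- deg[v] + m
    deg[targets] <- deg[targets] + 1L
  }
  scores <- sample(seq(spec$background_score_range[1L],
                       spec$background_score_range[2L]),
                   length(from), replace = TRUE)
  build_network(data.frame(protein_a = ids[from], protein_b = ids[to],
                           score = scores, stringsAsFactors = FALSE))
}

#' Plant a seed module with bridge genes into a background network
#'
#' Adds \code{n_seeds} seed nodes and \code{n_bridges} bridge nodes. Every
#' seed-bridge pair is connected at \code{bridge_score}; each seed also gets
#' \code{decoy_edges_per_seed} edges to random background nodes at background
#' scores. The score separation guarantees that all shortest paths between any
#' two seeds are exactly the \code{n_bridges} two-hop routes through the
#' bridges, so ground-truth betweenness is known by construction.
#'
#' @param background A \code{"ppi_network"} from [generate_background()] built
#'   from the same \code{spec}.
#' @param spec The \code{"synthetic_spec"}.
#' @return List with \code{network} (the augmented \code{"ppi_network"}) and
#'   \code{truth} (class \code{"synthetic_truth"}): \code{seed_ids},
#'   \code{bridge_ids}, \code{expected_min_betweenness} (per bridge, under
#'   all-paths counting), \code{pair_path_weight}, \code{min_detour_weight} and
#'   the spec echo.
#' @export
plant_module <- function(background, spec) {
  stopifnot(inherits(background, "ppi_network"),
            inherits(spec, "synthetic_spec"))
  if (spec$bridge_score <= spec$background_score_range[2L]) {
    stop("bridge_score must strictly exceed the background score ceiling")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$rng_seed + 1L)

  seed_ids <- sprintf("SEED%03d", seq_len(spec$n_seeds))
  bridge_ids <- sprintf("BRIDGE%02d", seq_len(spec$n_bridges))
  bg_ids <- background$nodes

  a <- character(0); b <- character(0); s <- integer(0)
  for (sd in seed_ids) {
    a <- c(a, rep.int(sd, spec$n_bridges))
    b <- c(b, bridge_ids)
    s <- c(s, rep.int(spec$bridge_score, spec$n_bridges))
    if (spec$decoy_edges_per_seed > 0L) {
      decoys <- sample(bg_ids, spec$decoy_edges_per_seed)
      a <- c(a, rep.int(sd, spec$decoy_edges_per_seed))
      b <- c(b, decoys)
      s <- c(s, sample(seq(spec$background_score_range[1L],
                           spec$background_score_range[2L]),
                       spec$decoy_edges_per_seed, replace = TRUE))
    }
  }
  all_edges <- rbind(
    background$edges[, c("a", "b", "score")],
    data.frame(a = a, b = b, score = s, stringsAsFactors = FALSE)
  )
  names(all_edges) <- c("protein_a", "protein_b", "score")
  network <- build_network(all_edges)

  expected <- stats::setNames(
    rep.int(choose(spec$n_seeds, 2L), spec$n_bridges), bridge_ids)
  truth <- structure(
    list(seed_ids = seed_ids, bridge_ids = bridge_ids,
         expected_min_betweenness = expected,
         pair_path_weight = 2L * (1000L - spec$bridge_score),
         min_detour_weight = 2L * (1000L - spec$background_score_range[2L]),
         spec = unclass(spec)),
    class = "synthetic_truth"
  )
  list(network = network, truth = truth)
}

#' Generate a complete synthetic network with planted ground truth
#'
#' Convenience wrapper: [generate_background()] then [plant_module()].
#'
#' @param spec A \code{"synthetic_spec"} (default: the standard recovery
#'   conditions — 300 background nodes, 10 seeds, 3 bridges, bridge score 990,
#'   background scores 150-800, 2 decoys per seed, seed 3).
#' @return List with \code{network} and \code{truth}.
#' @examples
#' sim <- simulate_network(synthetic_spec(n_background = 50, n_seeds = 4))
#' sim$truth$bridge_ids
#' @export
simulate_network <- function(spec = synthetic_spec()) {
  plant_module(generate_background(spec), spec)
}

#' Write a synthetic fixture to disk in STRING dialect
#'
#' Emits three files into \code{directory}: \code{links.txt} (STRING-style
#' protein-links file with a header and both orientations of every edge, as
#' real STRING downloads ship), \code{seeds.txt} (one seed identifier per
#' line) and \code{truth.json} (ground-truth bridge identifiers and the
#' generating parameters).
#'
#' @param network The synthetic \code{"ppi_network"}.
#' @param truth The matching \code{"synthetic_truth"}.
#' @param directory Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(network, truth, directory) {
  stopifnot(inherits(network, "ppi_network"),
            inherits(truth, "synthetic_truth"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  links <- file.path(directory, "links.txt")
  seeds <- file.path(directory, "seeds.txt")
  tjson <- file.path(directory, "truth.json")
  e <- network$edges
  both <- data.frame(
    p1 = c(e$a, e$b), p2 = c(e$b, e$a), score = c(e$score, e$score),
    stringsAsFactors = FALSE
  )
  both <- both[order(both$p1, both$p2), , drop = FALSE]
  writeLines(c("protein1 protein2 combined_score",
               paste(both$p1, both$p2, both$score)), links)
  writeLines(truth$seed_ids, seeds)
  jsonlite::write_json(
    list(seed_ids = truth$seed_ids, bridge_ids = truth$bridge_ids,
         expected_min_betweenness = as.list(truth$expected_min_betweenness),
         spec = truth$spec),
    tjson, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(links = links, seeds = seeds, truth = tjson))
}
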