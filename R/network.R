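#' Parse a STRING-style protein interaction file
#'
#' Reads a whitespace- or tab-separated interaction file in the STRING
#' protein-links dialect: one interaction per row with at least three fields,
#' \code{protein_1 protein_2 combined_score}. The combined score is an integer
#' confidence (150-999 in the snapshots this package targets). Self-pairs and
#' rows scoring below \code{min_score} are dropped; an optional one-line header
#' (first row whose third field is not an integer) is auto-detected.
#'
#' @param source Path to the interaction file, or a character vector of lines.
#' @param min_score Minimum combined score to retain (default 150, the floor of
#'   the STRING score range).
#' @param skip_header Header handling: \code{"auto"} (default) drops the first
#'   row when its third field does not parse as an integer; \code{TRUE} always
#'   drops the first row; \code{FALSE} never does.
#' @return A data frame of retained interaction records with columns
#'   \code{protein_a}, \code{protein_b} (character) and \code{score} (integer),
#'   carrying a \code{"parse_report"} attribute (rows read / retained / dropped
#'   by reason).
#' @seealso [build_network()] to turn the records into a weighted graph.
#' @examples
#' lines <- c("protein1 protein2 combined_score",
#'            "ENSP000A ENSP000B 999",
#'            "ENSP000A ENSP000A 800",
#'            "ENSP000B ENSP000C 149")
#' rec <- parse_interactions(lines)
#' attr(rec, "parse_report")
#' @export
parse_interactions <- function(source, min_score = 150L, skip_header = "auto") {
  if (length(source) == 1L && !grepl("[\n\t ]", source)) {
    if (!file.exists(source)) {
      stop("interaction file not found: ", source)
    }
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- as.character(source)
  }
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("empty interaction input: no data rows")
  }

  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)

  header_dropped <- FALSE
  drop_first <- function() {
    fields <<- fields[-1L]; nf <<- nf[-1L]; line_no <<- line_no[-1L]
    header_dropped <<- TRUE
  }
  if (isTRUE(skip_header)) {
    drop_first()
  } else if (identical(skip_header, "auto") && length(fields) > 0L) {
    f1 <- fields[[1L]]
    if (length(f1) < 3L || is.na(suppressWarnings(as.integer(f1[3L])))) drop_first()
  }
  if (length(fields) == 0L) {
    stop("empty interaction input: only a header row")
  }

  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    stop("malformed interaction row (fewer than 3 fields) at line ", line_no[bad[1L]])
  }
  protein_a <- vapply(fields, `[[`, character(1L), 1L)
  protein_b <- vapply(fields, `[[`, character(1L), 2L)
  score_raw <- vapply(fields, `[[`, character(1L), 3L)
  score <- suppressWarnings(as.integer(score_raw))
  if (anyNA(score)) {
    stop("malformed interaction row (non-integer score '",
         score_raw[which(is.na(score))[1L]], "') at line ",
         line_no[which(is.na(score))[1L]])
  }

  self_loop <- protein_a == protein_b
  low_score <- !self_loop & score < min_score
  retain <- !self_loop & !low_score
  report <- list(
    rows_read = length(fields) + as.integer(header_dropped),
    header_dropped = header_dropped,
    rows_retained = sum(retain),
    dropped_self_loop = sum(self_loop),
    dropped_low_score = sum(low_score),
    min_score = as.integer(min_score)
  )
  rec <- data.frame(
    protein_a = protein_a[retain],
    protein_b = protein_b[retain],
    score = score[retain],
    stringsAsFactors = FALSE
  )
  attr(rec, "parse_report") <- report
  rec
}

#' Build a weighted undirected interaction network
#'
#' Constructs the weighted graph G = (V, E) used for shortest-path discovery:
#' nodes are the protein identifiers of the retained interactions, and each
#' undirected edge carries weight \code{1000 - score}, so high-confidence
#' interactions are short. STRING files list each pair in both orientations;
#' duplicates (in either orientation) are collapsed to one undirected edge
#' keeping the maximum score.
#'
#' @param records Interaction records from [parse_interactions()], or any data
#'   frame with columns \code{protein_a}, \code{protein_b}, \code{score}.
#' @return An object of class \code{"ppi_network"}: a list with \code{nodes}
#'   (sorted identifiers), \code{edges} (data frame \code{a}, \code{b},
#'   \code{score}, \code{weight} with \code{a < b} lexicographically) and
#'   integer adjacency indexed by node position.
#' @examples
#' rec <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "A"),
#'                   score = c(700L, 900L))
#' net <- build_network(rec)
#' net$edges  # one undirected edge, score 900, weight 100
#' @export
build_network <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("protein_a", "protein_b", "score") %in% names(records))) {
    stop("records must be a data frame with protein_a, protein_b, score")
  }
  if (nrow(records) == 0L) {
    stop("cannot build a network from zero interaction records")
  }
  a <- as.character(records$protein_a)
  b <- as.character(records$protein_b)
  s <- as.integer(records$score)
  if (any(a == b)) stop("self-loop records present; filter them before building")
  if (any(s < 150L | s > 999L)) {
    stop("scores outside [150, 999]; filter or rescale before building")
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste0(lo, "\r", hi)
  # duplicate pairs (either orientation) collapse to the maximum score
  smax <- tapply(s, key, max)
  keys <- names(smax)
  split_at <- regexpr("\r", keys, fixed = TRUE)
  edges <- data.frame(
    a = substr(keys, 1L, split_at - 1L),
    b = substring(keys, split_at + 1L),
    score = as.integer(smax),
    stringsAsFactors = FALSE
  )
  edges$weight <- 1000L - edges$score
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- sort(unique(c(edges$a, edges$b)))
  ia <- match(edges$a, nodes)
  ib <- match(edges$b, nodes)
  n <- length(nodes)
  adj_from <- c(ia, ib)
  adj_to <- c(ib, ia)
  adj_w <- c(edges$weight, edges$weight)
  ord <- order(adj_from)
  adj <- split(adj_to[ord], factor(adj_from[ord], levels = seq_len(n)))
  wts <- split(adj_w[ord], factor(adj_from[ord], levels = seq_len(n)))

  structure(
    list(nodes = nodes, edges = edges,
         adj = unname(adj), adj_w = unname(wts)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("Weighted protein interaction network\n")
  cat("  nodes:", length(x$nodes), "\n")
  cat("  edges:", nrow(x$edges),
      sprintf("(scores %d-%d, weights %d-%d)\n",
              min(x$edges$score), max(x$edges$score),
              min(x$edges$weight), max(x$edges$weight)))
  invisible(x)
}

#' Summary statistics of an interaction network
#'
#' @param network A \code{"ppi_network"} from [build_network()].
#' @return A list with node count, edge count, score range, weight range and
#'   the number of connected components of the undirected graph.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  g <- as_igraph(network)
  list(
    n_nodes = length(network$nodes),
    n_edges = nrow(network$edges),
    score_range = range(network$edges$score),
    weight_range = range(network$edges$weight),
    n_components = igraph::count_components(g)
  )
}

#' Convert a ppi_network to an igraph object
#'
#' @param network A \code{"ppi_network"}.
#' @return An undirected \pkg{igraph} graph with a \code{weight} edge attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("a", "b")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
  igraph::E(g)$weight <- network$edges$weight
  igraph::E(g)$score <- network$edges$score
  g
}

#' Write a network as a canonical edge-list TSV
#'
#' Emits \code{node_a<TAB>node_b<TAB>score<TAB>weight} with identifiers
#' lexicographically ordered within each row and rows sorted, so the output is
#' byte-stable and round-trips through [parse_interactions()] and
#' [build_network()].
#'
#' @param network A \code{"ppi_network"}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  df <- network$edges[, c("a", "b", "score", "weight")]
  names(df) <- c("node_a", "node_b", "score", "weight")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene list (one identifier per line)
#'
#' Blank lines and \code{#} comments are ignored; identifiers are trimmed.
#'
#' @param path File path, or a character vector of lines.
#' @return Character vector of identifiers, in file order, duplicates removed.
#' @export
read_gene_list <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  ids <- trimws(sub("#.*$", "", lines))
  unique(ids[nzchar(ids)])
}

#' Read a two-column protein-to-symbol mapping file
#'
#' Optional reporting aid: translates opaque protein identifiers (e.g. Ensembl
#' peptide IDs) to gene symbols. Discovery always runs in the input namespace;
#' the mapping is applied only when labelling output.
#'
#' @param path TSV with two columns: \code{protein_id}, \code{gene_symbol}.
#' @return Named character vector (names = protein IDs, values = symbols).
#' @export
read_id_mapping <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("protein_id", "gene_symbol"))
  stats::setNames(df$gene_symbol, df$protein_id)
}
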