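#' Upper-tail hypergeometric probability
#'
#' P(X >= x) when drawing \code{n} genes without replacement from a universe of
#' \code{N} genes of which \code{K} belong to the annotated set — the standard
#' over-representation p-value, including the observed overlap. Computed via
#' \code{phyper(..., lower.tail = FALSE)}, which works in log space and is
#' exact to double precision.
#'
#' @param N Universe size.
#' @param K Annotated set size (successes in the universe).
#' @param n Query size (draws).
#' @param x Observed overlap.
#' @return P(X >= x), in (0, 1].
#' @examples
#' hypergeom_upper(10, 5, 5, 5)  # 1 / choose(10, 5)
#' @export
hypergeom_upper <- function(N, K, n, x) {
  if (any(c(N, K, n, x) < 0) || K > N || n > N || x > min(K, n)) {
    stop("invalid hypergeometric arguments: need 0 <= K,n <= N and 0 <= x <= min(K, n)")
  }
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a GMT gene-set collection
#'
#' GMT format: one set per line, \code{set_name<TAB>description<TAB>gene1...}.
#' Identifiers are normalized (trimmed, uppercased) to make intersections
#' robust to case and whitespace differences between sources.
#'
#' @param path GMT file path, or a character vector of GMT lines.
#' @param universe Optional universe of gene identifiers. Default: the union of
#'   all set members. Sets are clipped to the universe (with a message when
#'   members are dropped) since the hypergeometric model requires K <= N.
#' @return An object of class \code{"gene_set_collection"}: list with
#'   \code{sets} (named list of character vectors) and \code{universe}.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT input")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("malformed GMT line (need name, description, >=1 gene) at line ",
         which(lengths(parts) < 3L)[1L])
  }
  sets <- lapply(parts, function(p) unique(.norm_ids(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  gene_set_collection(sets, universe)
}

#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member genes).
#' @param universe Optional universe; defaults to the union of all members.
#' @return A \code{"gene_set_collection"}.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  sets <- lapply(sets, .norm_ids)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- sort(unique(.norm_ids(universe)))
    clipped <- vapply(sets, function(s) sum(!s %in% universe), integer(1L))
    if (any(clipped > 0L)) {
      message(sum(clipped), " gene-set member(s) outside the universe clipped")
      sets <- lapply(sets, function(s) s[s %in% universe])
    }
  }
  if (length(universe) == 0L) stop("empty gene universe")
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

.norm_ids <- function(x) toupper(trimws(as.character(x)))

#' Hypergeometric over-representation of a query gene list
#'
#' Tests a query list (e.g. the significant candidate genes) against every set
#' in a collection. For each set: N = universe size, K = set size, n = query
#' size after clipping to the universe, x = overlap; the p-value is the
#' upper-tail hypergeometric probability P(X >= x). A Benjamini-Hochberg
#' column is included as supplementary output; rows are sorted by ascending
#' p-value. P-values depend directly on the universe choice, which should be
#' stated whenever results are reported.
#'
#' @param query Character vector of gene identifiers.
#' @param collection A \code{"gene_set_collection"}.
#' @return A data frame of class \code{"enrichment_result"}: one row per set
#'   with columns \code{set_name}, \code{N}, \code{K}, \code{n}, \code{overlap},
#'   \code{p_value}, \code{bh_fdr}, \code{overlap_genes} (comma-separated,
#'   sorted). Attribute \code{"dropped_query"} counts query identifiers outside
#'   the universe.
#' @export
enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(.norm_ids(query))
  if (length(query) == 0L) stop("empty query gene list")
  inside <- query %in% collection$universe
  dropped <- sum(!inside)
  if (dropped > 0L) {
    message(dropped, " query gene(s) outside the universe dropped")
  }
  query <- query[inside]
  if (length(query) == 0L) stop("no query genes inside the universe")
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    ov <- sort(intersect(query, members))
    data.frame(set_name = nm, N = N, K = length(members), n = n,
               overlap = length(ov),
               p_value = hypergeom_upper(N, length(members), n, length(ov)),
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$bh_fdr <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set_name),
             c("set_name", "N", "K", "n", "overlap", "p_value", "bh_fdr",
               "overlap_genes")]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"),
            dropped_query = dropped)
}

#' Write an enrichment result as TSV
#'
#' @param result An \code{"enrichment_result"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
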