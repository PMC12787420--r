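#' Read a STRING-style weighted edge list
#'
#' Parses a tab-separated protein-protein interaction edge list with columns
#' `gene_a`, `gene_b` and `combined_score`, the layout of a STRING network
#' export.  STRING distributes combined scores either on the unit interval or
#' as integers on a 0--1000 scale; the scale is auto-detected (any score
#' above 1 implies the 0--1000 convention) and scores are returned on
#' \eqn{[0, 1]}.
#'
#' @param path Path to a TSV file with a header row.  Lines starting with
#'   `#` are ignored.
#' @return A data frame with columns `gene_a`, `gene_b` (uppercased symbols)
#'   and `combined_score` in \eqn{[0, 1]}.
#' @export
read_string_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  required <- c("gene_a", "gene_b", "combined_score")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("edge list ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score))
  if (length(bad) > 0) {
    stop("non-numeric combined_score at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  if (any(score > 1)) score <- score / 1000
  if (any(score < 0 | score > 1)) {
    stop("combined_score out of range [0, 1] after rescaling in ", path,
         call. = FALSE)
  }
  data.frame(gene_a = toupper(trimws(df$gene_a)),
             gene_b = toupper(trimws(df$gene_b)),
             combined_score = score,
             stringsAsFactors = FALSE)
}

#' Build a simple undirected PPI graph from scored edges
#'
#' Filters edges by interaction confidence and canonicalizes the result into
#' a simple undirected graph: self-loops are dropped and duplicate pairs
#' (in either orientation) are collapsed, keeping the maximum score.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`,
#'   `combined_score` (as returned by [read_string_edges()]).
#' @param min_score Minimum combined score an edge must reach to be kept.
#'   The default 0.7 is the customary "high confidence" STRING cutoff.
#' @param isolated Optional character vector of node names to include even
#'   if no retained edge touches them.
#' @return An [igraph][igraph::igraph-package] undirected graph whose edges
#'   carry a `combined_score` attribute.
#' @export
build_graph <- function(edges, min_score = 0.7, isolated = character()) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  if (min_score < 0 || min_score > 1) {
    stop("min_score must lie in [0, 1]", call. = FALSE)
  }
  keep <- edges$combined_score >= min_score & edges$gene_a != edges$gene_b
  edges <- edges[keep, , drop = FALSE]
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  if (length(key) == 0) {
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(sort(unique(isolated))))
  }
  score <- tapply(edges$combined_score, key, max)
  pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  nodes <- sort(unique(c(as.vector(pairs), isolated)))
  igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2],
               combined_score = as.numeric(score)),
    directed = FALSE,
    vertices = nodes)
}

#' Degree centrality
#'
#' Number of distinct neighbours of each node, reported as an unnormalized
#' integer (the convention of Cytoscape-style topology tables).
#'
#' @param graph An igraph undirected graph.
#' @return A named integer vector over the graph's nodes.
#' @export
degree_centrality <- function(graph) {
  d <- igraph::degree(graph, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Betweenness centrality
#'
#' Brandes betweenness on unweighted (hop-count) shortest paths,
#' \eqn{\sum_{s \ne v \ne t} \sigma_{st}(v) / \sigma_{st}}, normalized by
#' \eqn{(n-1)(n-2)/2} so that values lie in \eqn{[0, 1]} for undirected
#' graphs.  Pairs in different components contribute zero.  Confidence
#' scores act only as an edge filter upstream, never as distances.
#'
#' @param graph An igraph undirected graph.
#' @param normalized If `FALSE`, return raw pair counts.
#' @return A named numeric vector.
#' @export
betweenness_centrality <- function(graph, normalized = TRUE) {
  n <- igraph::vcount(graph)
  if (n < 3) {
    return(stats::setNames(numeric(n), igraph::V(graph)$name))
  }
  b <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  if (normalized) b <- b * 2 / ((n - 1) * (n - 2))
  b
}

#' Closeness centrality
#'
#' Component-restricted closeness on hop-count shortest paths: for a node
#' \eqn{v} in a connected component of size \eqn{n_c},
#' \eqn{cc(v) = (n_c - 1) / \sum_{u} d(v, u)} over the nodes of that
#' component -- the reciprocal of the mean intra-component distance.
#' Isolated nodes score 0.  No cross-component (Wasserman-Faust) scaling is
#' applied.
#'
#' @param graph An igraph undirected graph.
#' @return A named numeric vector in \eqn{[0, 1]}.
#' @export
closeness_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  d <- igraph::distances(graph, weights = NA)
  cc <- apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    if (length(reach) <= 1) return(0)
    (length(reach) - 1) / sum(reach)
  })
  stats::setNames(as.numeric(cc), nm)
}

#' Per-node centrality table
#'
#' One row per node with degree (`dc`), normalized betweenness (`bc`) and
#' component-restricted closeness (`cc`), ordered by descending degree with
#' ties broken alphabetically -- the layout of a hub-gene summary table.
#'
#' @param graph An igraph undirected graph.
#' @return A data frame with columns `node`, `dc`, `bc`, `cc`.
#' @export
centrality_table <- function(graph) {
  nm <- igraph::V(graph)$name
  if (length(nm) == 0) {
    return(data.frame(node = character(), dc = integer(),
                      bc = numeric(), cc = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- data.frame(node = nm,
                    dc = as.integer(degree_centrality(graph)[nm]),
                    bc = as.numeric(betweenness_centrality(graph)[nm]),
                    cc = as.numeric(closeness_centrality(graph)[nm]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$dc, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Mean of pairwise interaction scores
#'
#' Arithmetic mean of a set of pairwise combined scores, e.g. the scores
#' among a core-gene subnetwork, summarising how tightly interconnected the
#' module is.
#'
#' @param scores Numeric vector of scores, each in \eqn{[0, 1]}.
#' @return The arithmetic mean.
#' @export
summarize_pairwise_scores <- function(scores) {
  if (length(scores) == 0) stop("no scores supplied", call. = FALSE)
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must be finite and in [0, 1]", call. = FALSE)
  }
  mean(scores)
}
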