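DHCTP_LAYERS <- c("drug", "herb", "compound", "target", "pathway")

#' Construct a multipartite drug-herb-compound-target-pathway network
#'
#' Internal-facing constructor validating the layer structure: node ids are
#' layer-prefixed (`"drug:..."`, `"herb:..."`, ...) so that a compound and
#' a gene may share a display name, and every edge must connect adjacent
#' layers in the drug-to-pathway direction.
#'
#' @param nodes Data frame with columns `node_id`, `layer`, `display_name`.
#' @param edges Data frame with columns `from`, `to` (node ids; `from` in
#'   the earlier layer).
#' @return An object of class `dhctp_network`.
#' @export
dhctp_network <- function(nodes, edges) {
  stopifnot(all(c("node_id", "layer", "display_name") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node ids", call. = FALSE)
  }
  if (!all(nodes$layer %in% DHCTP_LAYERS)) {
    stop("unknown layer label", call. = FALSE)
  }
  layer_of <- stats::setNames(nodes$layer, nodes$node_id)
  if (nrow(edges) > 0) {
    if (!all(edges$from %in% nodes$node_id) ||
        !all(edges$to %in% nodes$node_id)) {
      stop("edge endpoint not among nodes", call. = FALSE)
    }
    li <- match(layer_of[edges$from], DHCTP_LAYERS)
    lj <- match(layer_of[edges$to], DHCTP_LAYERS)
    if (!all(lj - li == 1L)) {
      stop("edges must connect adjacent layers in drug->pathway direction",
           call. = FALSE)
    }
    if (anyDuplicated(paste(edges$from, edges$to, sep = "\r"))) {
      stop("duplicate edges", call. = FALSE)
    }
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes[, c("node_id", "layer", "display_name")],
                 edges = edges[, c("from", "to")]),
            class = "dhctp_network")
}

#' Assemble the five-layer drug-herb-compound-target-pathway network
#'
#' Integrates the pipeline's outputs into one multipartite network: the
#' drug connects to its herbs, herbs to their curated compounds, compounds
#' to the core target genes they hit, and core genes to their enriched
#' pathways.  Compound-target edges are restricted to core genes, and
#' compounds hitting no core gene are omitted (together with their
#' herb-compound edges) so the network carries no orphan branches.
#'
#' @param drug_name Display name of the formulation.
#' @param records Curated compound table (columns `compound`, `herb`).
#' @param mapping Named list from [read_target_map()].
#' @param core Character vector of core target genes (non-empty).
#' @param pathway_map Data frame with columns `gene`, `pathway` (or a named
#'   list gene -> pathway vector); may be empty, in which case the network
#'   has no pathway layer nodes.
#' @return A `dhctp_network`.
#' @export
assemble_dhctp <- function(drug_name, records, mapping, core,
                           pathway_map = data.frame(gene = character(),
                                                    pathway = character())) {
  stopifnot(is.data.frame(records),
            all(c("compound", "herb") %in% names(records)))
  core <- normalize_symbols(core)
  if (length(core) == 0) stop("core gene set is empty", call. = FALSE)
  if (is.list(pathway_map) && !is.data.frame(pathway_map)) {
    pathway_map <- data.frame(
      gene = rep(names(pathway_map), lengths(pathway_map)),
      pathway = unlist(pathway_map, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  pathway_map$gene <- toupper(trimws(pathway_map$gene))
  pathway_map <- pathway_map[pathway_map$gene %in% core, , drop = FALSE]

  core_hits <- lapply(mapping, function(g) intersect(g, core))
  kept <- names(core_hits)[lengths(core_hits) > 0]
  records <- records[records$compound %in% kept, , drop = FALSE]

  herb_names <- unique(records$herb)
  comp_names <- unique(records$compound)
  path_names <- unique(pathway_map$pathway)

  nodes <- rbind(
    data.frame(node_id = paste0("drug:", drug_name), layer = "drug",
               display_name = drug_name, stringsAsFactors = FALSE),
    data.frame(node_id = paste0("herb:", herb_names), layer = "herb",
               display_name = herb_names, stringsAsFactors = FALSE),
    data.frame(node_id = paste0("compound:", comp_names), layer = "compound",
               display_name = comp_names, stringsAsFactors = FALSE),
    data.frame(node_id = paste0("target:", core), layer = "target",
               display_name = core, stringsAsFactors = FALSE),
    if (length(path_names) > 0)
      data.frame(node_id = paste0("pathway:", path_names), layer = "pathway",
                 display_name = path_names, stringsAsFactors = FALSE))

  hc <- unique(records[, c("herb", "compound")])
  ct <- do.call(rbind, lapply(kept, function(cp) {
    data.frame(from = paste0("compound:", cp),
               to = paste0("target:", core_hits[[cp]]),
               stringsAsFactors = FALSE)
  }))
  edges <- rbind(
    data.frame(from = paste0("drug:", drug_name),
               to = paste0("herb:", herb_names), stringsAsFactors = FALSE),
    data.frame(from = paste0("herb:", hc$herb),
               to = paste0("compound:", hc$compound),
               stringsAsFactors = FALSE),
    ct,
    if (nrow(pathway_map) > 0)
      data.frame(from = paste0("target:", pathway_map$gene),
                 to = paste0("pathway:", pathway_map$pathway),
                 stringsAsFactors = FALSE))
  edges <- unique(edges)
  dhctp_network(nodes, edges)
}

#' Out-degree of a node toward the next layer
#'
#' Counts the edges incident to a node in the drug-to-pathway direction:
#' for a compound, the number of core genes it hits; for a target gene, the
#' number of pathways it belongs to.  Pathway nodes (the last layer) have
#' out-degree 0.
#'
#' @param network A `dhctp_network`.
#' @param node_id Layer-prefixed node id (e.g. `"target:IL6"`).
#' @return Integer count.
#' @export
layer_degree <- function(network, node_id) {
  stopifnot(inherits(network, "dhctp_network"))
  if (!node_id %in% network$nodes$node_id) {
    stop("unknown node: ", node_id, call. = FALSE)
  }
  sum(network$edges$from == node_id)
}

#' Export a multipartite network
#'
#' Writes a `dhctp_network` to disk losslessly in one of three formats:
#' `"tsv"` (a `<path>.nodes.tsv` / `<path>.edges.tsv` pair), `"sif"`
#' (Cytoscape simple-interaction format, one `source relation target` line
#' per edge, relation = the layer pair), or `"graphml"` (via igraph, with
#' `layer` and `display_name` vertex attributes).
#'
#' @param network A `dhctp_network`.
#' @param path Output path; for `"tsv"` a stem to which `.nodes.tsv` and
#'   `.edges.tsv` are appended.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return The path(s) written, invisibly.
#' @export
export_dhctp <- function(network, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "dhctp_network"))
  format <- match.arg(format)
  layer_of <- stats::setNames(network$nodes$layer, network$nodes$node_id)
  if (format == "tsv") {
    np <- paste0(path, ".nodes.tsv")
    ep <- paste0(path, ".edges.tsv")
    utils::write.table(network$nodes, np, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(network$edges, ep, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(c(np, ep)))
  }
  if (format == "sif") {
    rel <- paste(layer_of[network$edges$from], layer_of[network$edges$to],
                 sep = "-")
    writeLines(paste(network$edges$from, rel, network$edges$to, sep = "\t"),
               path)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = data.frame(
                                       name = network$nodes$node_id,
                                       layer = network$nodes$layer,
                                       display_name = network$nodes$display_name,
                                       stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a multipartite network written by [export_dhctp()]
#'
#' @param path Path (or stem, for `"tsv"`) previously passed to
#'   [export_dhctp()].
#' @param format One of `"tsv"`, `"graphml"`.
#' @return A `dhctp_network`.
#' @export
import_dhctp <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    nodes <- utils::read.delim(paste0(path, ".nodes.tsv"),
                               stringsAsFactors = FALSE)
    edges <- utils::read.delim(paste0(path, ".edges.tsv"),
                               stringsAsFactors = FALSE)
    if (nrow(edges) == 0) {
      edges <- data.frame(from = character(), to = character())
    }
    return(dhctp_network(nodes, edges))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(node_id = igraph::V(g)$name,
                      layer = igraph::V(g)$layer,
                      display_name = igraph::V(g)$display_name,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  dhctp_network(nodes, edges)
}

#' @export
print.dhctp_network <- function(x, ...) {
  counts <- table(factor(x$nodes$layer, levels = DHCTP_LAYERS))
  cat("D-H-C-T-P network:",
      paste(sprintf("%d %s", counts, names(counts)), collapse = ", "),
      "\n")
  cat(nrow(x$edges), "edges\n")
  invisible(x)
}
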