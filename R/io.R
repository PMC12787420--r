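# Plain-text writers for the pipeline's tabular formats.  All writers are
# deterministic: identical inputs give byte-identical files.

#' Write an herb-compound table
#' @param records Data frame with columns `compound`, `pubchem_cid`, `herb`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(records, path) {
  stopifnot(all(c("compound", "pubchem_cid", "herb") %in% names(records)))
  utils::write.table(records[, c("compound", "pubchem_cid", "herb")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a compound-to-target mapping
#' @param targets Either a data frame with columns `compound`, `gene`, or a
#'   named list mapping compound to gene vector.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(targets, path) {
  if (is.list(targets) && !is.data.frame(targets)) {
    targets <- data.frame(
      compound = rep(names(targets), lengths(targets)),
      gene = unlist(targets, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("compound", "gene") %in% names(targets)))
  utils::write.table(targets[, c("compound", "gene")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene list, one symbol per line
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a gene list, one symbol per line
#' @param path Input path.
#' @return Character vector of normalized (uppercase, trimmed) symbols.
#' @export
read_gene_list <- function(path) {
  normalize_symbols(readLines(path, warn = FALSE))
}

#' Write a graph as a STRING-style weighted edge list
#' @param graph An igraph graph with a `combined_score` edge attribute.
#' @param path Output TSV path (columns `gene_a`, `gene_b`,
#'   `combined_score`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  score <- igraph::E(graph)$combined_score
  if (is.null(score)) score <- rep(1, nrow(el))
  df <- data.frame(gene_a = pmin(el[, 1], el[, 2]),
                   gene_b = pmax(el[, 1], el[, 2]),
                   combined_score = score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
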