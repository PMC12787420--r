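#' Read and curate an herb-compound table
#'
#' Reads a tab-separated herb-compound table with columns `compound`,
#' `pubchem_cid` and `herb`, and applies deterministic curation: exact
#' duplicates on the (herb, CID) pair are removed, keeping the first
#' occurrence in file order.  The same CID may legitimately appear under
#' different herbs (shared constituents such as glycyrrhizin), so
#' cross-herb duplicates are retained as separate records.
#'
#' The package ships a curated 192-compound table for the nine-herb
#' formulation Mecasin under
#' `system.file("extdata", "mecasin_compounds.tsv", package = "netpharm")`.
#'
#' @param path Path to a TSV file with a header row; `#` lines are ignored.
#' @return A data frame with columns `compound`, `pubchem_cid` (integer),
#'   `herb`, in file order minus duplicates.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("compound", "pubchem_cid", "herb")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("compound table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cid <- suppressWarnings(as.integer(df$pubchem_cid))
  bad <- which(is.na(cid) | cid <= 0)
  if (length(bad) > 0) {
    stop("invalid pubchem_cid at line ", bad[1] + 1L, " of ", path,
         ": ", df$pubchem_cid[bad[1]], call. = FALSE)
  }
  if (any(!nzchar(trimws(df$compound)))) {
    stop("empty compound name in ", path, call. = FALSE)
  }
  out <- data.frame(compound = trimws(df$compound),
                    pubchem_cid = cid,
                    herb = trimws(df$herb),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$herb, out$pubchem_cid, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a compound-to-target mapping
#'
#' Reads a two-column TSV (`compound`, `gene`) and builds a mapping from
#' compound name to its set of target gene symbols.  Symbols are
#' whitespace-trimmed, uppercased and deduplicated.  Rows with an empty
#' gene field are dropped with a warning rather than aborting the read;
#' compounds absent from the file simply have no entry.
#'
#' @param path Path to a TSV file with a header row.
#' @return A named list mapping compound name to a character vector of
#'   uppercase gene symbols; every entry is non-empty.
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  required <- c("compound", "gene")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("target map ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gene <- toupper(trimws(df$gene))
  empty <- !nzchar(gene) | is.na(gene)
  if (any(empty)) {
    warning(sum(empty), " row(s) with an empty gene field dropped from ",
            path, call. = FALSE)
  }
  df <- df[!empty, , drop = FALSE]
  gene <- gene[!empty]
  if (nrow(df) == 0) return(stats::setNames(list(), character(0)))
  lapply(split(gene, trimws(df$compound)), function(g) sort(unique(g)))
}

#' Drop compounds without target annotations
#'
#' Restricts a curated compound table to the compounds that have an entry
#' in the target mapping, preserving the original record order.  This
#' mirrors the curation step in which molecules without defined gene
#' targets are excluded from a formulation's constituent list.
#'
#' @param records Data frame from [read_compound_table()].
#' @param mapping Named list from [read_target_map()].
#' @return The subset of `records` whose `compound` is a key of `mapping`.
#' @export
drop_targetless <- function(records, mapping) {
  stopifnot(is.data.frame(records), "compound" %in% names(records))
  out <- records[records$compound %in% names(mapping), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of predicted targets over retained compounds
#'
#' The set union of the target sets of all compounds present in the curated
#' record table -- the formulation's predicted target gene set.
#'
#' @param mapping Named list from [read_target_map()].
#' @param records Curated compound table.
#' @return Sorted character vector of unique uppercase gene symbols.
#' @export
union_targets <- function(mapping, records) {
  stopifnot(is.data.frame(records), "compound" %in% names(records))
  sort(unique(unlist(mapping[unique(records$compound)], use.names = FALSE)))
}
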