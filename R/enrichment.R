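#' Construct an annotation library
#'
#' A named collection of gene sets (terms) together with the background
#' universe they are tested against.  By default the universe is the union
#' of all term genes, the convention when no explicit background is stated.
#'
#' @param name Library label (e.g. `"GO_BP"`, `"KEGG"`).
#' @param terms Named list of character vectors of gene symbols; every term
#'   must be non-empty.
#' @param universe Optional character vector; defaults to the union of all
#'   term genes.  Every term must be a subset of it.
#' @return An object of class `annotation_library`.
#' @export
annotation_library <- function(name, terms, universe = NULL) {
  stopifnot(is.character(name), length(name) == 1, is.list(terms))
  if (length(terms) > 0 && is.null(names(terms))) {
    stop("terms must be named", call. = FALSE)
  }
  terms <- lapply(terms, function(g) sort(unique(toupper(trimws(g)))))
  if (any(lengths(terms) == 0)) stop("empty term in library", call. = FALSE)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(terms, use.names = FALSE)))
  } else {
    universe <- sort(unique(toupper(trimws(universe))))
    outside <- setdiff(unlist(terms, use.names = FALSE), universe)
    if (length(outside) > 0) {
      stop("term genes outside the universe: ",
           paste(utils::head(outside, 3), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, terms = terms, universe = universe),
            class = "annotation_library")
}

#' Read a GMT gene-set library
#'
#' Parses the standard tab-separated GMT format (term id, description,
#' then one gene per field).  Lines with fewer than three fields are
#' rejected with their line number.
#'
#' @param path Path to a GMT file.
#' @param name Library label; defaults to the file name.
#' @param universe Optional explicit background; defaults to the union of
#'   all term genes.
#' @return An `annotation_library`.
#' @export
read_gmt <- function(path, name = basename(path), universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " of ", path,
         " has fewer than 3 fields", call. = FALSE)
  }
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- vapply(fields, `[[`, character(1), 1)
  annotation_library(name, terms, universe)
}

#' Write a GMT gene-set library
#'
#' @param library An `annotation_library`.
#' @param path Output path.
#' @param descriptions Optional character vector of term descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  stopifnot(inherits(library, "annotation_library"))
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(library$terms))
  }
  lines <- mapply(function(id, desc, genes) {
    paste(c(id, desc, genes), collapse = "\t")
  }, names(library$terms), descriptions, library$terms)
  writeLines(lines, path)
  invisible(path)
}

#' Fisher's exact over-representation analysis
#'
#' Tests each term of an annotation library for over-representation of a
#' query gene set with the one-sided hypergeometric upper tail
#' \eqn{p = \sum_{i \ge k} \binom{K}{i} \binom{N-K}{n-i} / \binom{N}{n}},
#' where \eqn{k} is the query/term overlap, \eqn{K} the term size, \eqn{n}
#' the query size and \eqn{N} the universe size.  Query genes outside the
#' universe are dropped with a warning.  Raw p-values are adjusted with
#' [bh_adjust()].
#'
#' @param query Character vector of gene symbols.
#' @param library An `annotation_library`.
#' @return A data frame with one row per term: `term_id`, `library`, `k`,
#'   `K`, `n`, `N`, `p_value`, `fdr`, in library order.
#' @export
fisher_enrich <- function(query, library) {
  stopifnot(inherits(library, "annotation_library"))
  if (length(library$universe) == 0) stop("empty universe", call. = FALSE)
  query <- normalize_symbols(query)
  outside <- setdiff(query, library$universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, library$universe)
  }
  N <- length(library$universe)
  n <- length(query)
  k <- vapply(library$terms, function(t) length(intersect(t, query)),
              integer(1))
  K <- lengths(library$terms)
  p <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  out <- data.frame(term_id = names(library$terms),
                    library = library$name,
                    k = as.integer(k), K = as.integer(K),
                    n = n, N = N,
                    p_value = as.numeric(p),
                    fdr = bh_adjust(as.numeric(p)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: in ascending order of p,
#' \eqn{\mathrm{adj}_i = \min_{j \ge i} p_j m / j}, capped at 1, returned
#' in input order.
#'
#' @param p_values Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Top-k enriched terms
#'
#' Ranks enrichment results by ascending p-value, breaking ties by larger
#' overlap `k`, then term id, and truncates to the `k_top` best.
#'
#' @param terms Data frame from [fisher_enrich()].
#' @param k_top Number of terms to keep (positive).
#' @return The ranked, truncated data frame.
#' @export
top_k <- function(terms, k_top) {
  stopifnot(is.data.frame(terms),
            all(c("p_value", "k", "term_id") %in% names(terms)))
  if (k_top <= 0) stop("k_top must be positive", call. = FALSE)
  ord <- order(terms$p_value, -terms$k, terms$term_id)
  out <- terms[ord, , drop = FALSE][seq_len(min(k_top, nrow(terms))), ,
                                    drop = FALSE]
  rownames(out) <- NULL
  out
}
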