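#' Intersection of two gene sets
#'
#' Exact set intersection of normalized (uppercase, trimmed) gene symbols,
#' e.g. predicted formulation targets against a disease gene list.
#'
#' @param targets,disease Character vectors of gene symbols.
#' @return Sorted character vector of shared symbols.
#' @export
intersect_genes <- function(targets, disease) {
  sort(intersect(normalize_symbols(targets), normalize_symbols(disease)))
}

normalize_symbols <- function(x) {
  x <- toupper(trimws(x))
  unique(x[nzchar(x) & !is.na(x)])
}

#' Summarize the overlap between target and disease gene sets
#'
#' Venn-style bookkeeping of two gene sets plus, when a universe size is
#' supplied, an exact hypergeometric upper-tail test of whether the overlap
#' exceeds chance (see [overlap_significance()]).
#'
#' @param targets,disease Character vectors of gene symbols.
#' @param universe_size Optional total number of genes the two sets were
#'   drawn from; when supplied the summary carries `hypergeometric_p`.
#' @return An object of class `overlap_summary`: a list with `n_targets`,
#'   `n_disease`, `n_shared`, `n_target_only`, `n_disease_only`, `shared`
#'   (character vector), and optionally `universe_size` and
#'   `hypergeometric_p`.
#' @export
overlap_summary <- function(targets, disease, universe_size = NULL) {
  t <- normalize_symbols(targets)
  d <- normalize_symbols(disease)
  shared <- sort(intersect(t, d))
  out <- list(n_targets = length(t),
              n_disease = length(d),
              n_shared = length(shared),
              n_target_only = length(t) - length(shared),
              n_disease_only = length(d) - length(shared),
              shared = shared)
  if (!is.null(universe_size)) {
    out$universe_size <- as.integer(universe_size)
    out$hypergeometric_p <- overlap_significance(
      n_shared = out$n_shared, n_targets = out$n_targets,
      n_disease = out$n_disease, universe_size = universe_size)
  }
  structure(out, class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("targets: %d, disease: %d, shared: %d (target-only %d, disease-only %d)\n",
              x$n_targets, x$n_disease, x$n_shared,
              x$n_target_only, x$n_disease_only))
  if (!is.null(x$hypergeometric_p)) {
    cat(sprintf("hypergeometric P[X >= %d] = %.4g (universe %d)\n",
                x$n_shared, x$hypergeometric_p, x$universe_size))
  }
  invisible(x)
}

#' Hypergeometric significance of a gene-set overlap
#'
#' Exact upper-tail probability \eqn{P[X \ge k]} for
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)}: the chance of seeing at
#' least the observed overlap if `n_targets` genes were drawn uniformly
#' from a universe of `universe_size` genes of which `n_disease` are
#' disease-associated.
#'
#' @param n_shared Observed overlap.
#' @param n_targets Size of the target set.
#' @param n_disease Size of the disease set.
#' @param universe_size Size of the gene universe.
#' @return A probability in \eqn{[0, 1]}.
#' @export
overlap_significance <- function(n_shared, n_targets, n_disease,
                                 universe_size) {
  if (n_shared > min(n_targets, n_disease)) {
    stop("n_shared cannot exceed either set size", call. = FALSE)
  }
  if (universe_size < n_targets + (n_disease - n_shared)) {
    stop("universe_size is too small to hold both sets", call. = FALSE)
  }
  if (n_shared <= 0) return(1)
  stats::phyper(n_shared - 1, m = n_disease, n = universe_size - n_disease,
                k = n_targets, lower.tail = FALSE)
}
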