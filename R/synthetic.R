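#' Specification for a planted-core synthetic PPI network
#'
#' Describes a random graph with a densely interconnected "core" embedded in
#' a sparse background: the `core_size` planted nodes form a clique, each
#' core node additionally attaches to a fraction `core_attach_frac` of the
#' periphery, and every remaining node pair receives an independent
#' background edge with probability `bg_edge_prob`.  This is the topology in
#' which iterative mean-threshold screening has a well-defined ground truth.
#'
#' @param n_total Total number of nodes.
#' @param core_size Number of planted core nodes (at least 2).
#' @param core_attach_frac Fraction of the periphery each core node attaches
#'   to, in \eqn{[0, 1]}.
#' @param bg_edge_prob Independent background edge probability in
#'   \eqn{[0, 1]}.
#' @param seed Integer RNG seed; the same spec always yields the same graph.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_total, core_size, core_attach_frac,
                         bg_edge_prob, seed) {
  stopifnot(is.numeric(n_total), is.numeric(core_size),
            is.numeric(core_attach_frac), is.numeric(bg_edge_prob),
            is.numeric(seed))
  if (core_size < 2) stop("core_size must be at least 2", call. = FALSE)
  if (core_size >= n_total) stop("core_size must be smaller than n_total",
                                 call. = FALSE)
  if (core_attach_frac < 0 || core_attach_frac > 1 ||
      bg_edge_prob < 0 || bg_edge_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (core_attach_frac == 0 && bg_edge_prob == 0 && n_total > core_size) {
    stop("periphery can never connect: core_attach_frac and bg_edge_prob are both zero",
         call. = FALSE)
  }
  structure(list(n_total = as.integer(n_total),
                 core_size = as.integer(core_size),
                 core_attach_frac = core_attach_frac,
                 bg_edge_prob = bg_edge_prob,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Generate a planted-core PPI network
#'
#' Draws the graph described by a [network_spec()]: a clique on the core,
#' \eqn{\lceil f (n - k) \rceil} periphery attachments per core node, and
#' independent background edges.  If the draw leaves components detached
#' from the core, one node of each such component is wired to a uniformly
#' chosen core node so the returned graph is always connected.  Edges carry
#' a `combined_score` attribute emulating a high-confidence STRING export:
#' planted (core-incident) edges score in \eqn{[0.9, 1)}, background edges
#' in \eqn{[0.7, 0.9)}.
#'
#' Gene names are synthetic tokens (`G000001`, ...) to avoid implying claims
#' about real genes.
#'
#' @param spec A `network_spec`.
#' @return A list with elements `graph` (igraph) and `core` (character
#'   vector of ground-truth core gene names).
#' @export
gen_planted_core_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_total
    k <- spec$core_size
    nodes <- sprintf("G%06d", seq_len(n))
    core <- sort(sample(nodes, k))
    periph <- setdiff(nodes, core)

    clique <- t(utils::combn(core, 2))
    n_attach <- ceiling(spec$core_attach_frac * length(periph))
    attach <- NULL
    if (n_attach > 0) {
      attach <- do.call(rbind, lapply(core, function(v) {
        cbind(v, sample(periph, n_attach))
      }))
    }
    all_pairs <- t(utils::combn(nodes, 2))
    bg <- all_pairs[stats::runif(nrow(all_pairs)) < spec$bg_edge_prob, ,
                    drop = FALSE]

    planted <- rbind(clique, attach)
    edges <- canonical_pairs(rbind(planted, bg))
    planted_key <- pair_key(canonical_pairs(planted))

    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2]),
      directed = FALSE, vertices = nodes)

    comp <- igraph::components(g)
    core_comp <- comp$membership[core[1]]
    stray <- setdiff(unique(comp$membership), core_comp)
    if (length(stray) > 0) {
      repair <- do.call(rbind, lapply(stray, function(cid) {
        members <- names(comp$membership)[comp$membership == cid]
        c(sample(members, 1), sample(core, 1))
      }))
      g <- igraph::add_edges(g, as.vector(t(repair)))
      edges <- canonical_pairs(rbind(edges, repair))
    }

    key <- pair_key(igraph::as_edgelist(g))
    score <- numeric(length(key))
    is_planted <- key %in% planted_key
    score[is_planted] <- stats::runif(sum(is_planted), 0.90, 0.999)
    score[!is_planted] <- stats::runif(sum(!is_planted), 0.70, 0.90)
    igraph::E(g)$combined_score <- score

    list(graph = g, core = core)
  })
}

# uniform draw from an inclusive integer range; immune to sample()'s
# scalar expansion when lo == hi
sample_range <- function(lo, hi, n) {
  vals <- seq.int(lo, hi)
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

canonical_pairs <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(character(0), ncol = 2))
  a <- pmin(m[, 1], m[, 2])
  b <- pmax(m[, 1], m[, 2])
  unique(cbind(a, b))
}

pair_key <- function(m) {
  if (nrow(m) == 0) return(character(0))
  paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "\r")
}

#' Generate a 40-node hub network with prescribed labeled degrees
#'
#' Builds a simple connected graph on exactly 40 nodes reproducing the
#' degree structure of a six-gene hub table: a universal node `IL6` adjacent
#' to all 39 others, nodes `AKT1`, `STAT3` and `IL1B` with degree exactly
#' 36, and `TNF` and `EGFR` with degree exactly 35.  The 34 filler nodes
#' carry synthetic names and arbitrary (seed-dependent) extra edges.
#'
#' Because `IL6` is universal, every non-adjacent pair sits at distance
#' exactly 2, so closeness centralities of the labeled nodes are fixed small
#' rationals regardless of the seed: \eqn{39/39 = 1} for `IL6`,
#' \eqn{39/(36 + 2 \cdot 3) = 39/42} for the degree-36 nodes and
#' \eqn{39/(35 + 2 \cdot 4) = 39/43} for the degree-35 nodes.
#'
#' @param seed Integer RNG seed.
#' @return An igraph undirected graph with a `combined_score` edge
#'   attribute.
#' @export
gen_table2_network <- function(seed = 1L) {
  withr::with_seed(as.integer(seed), {
    filler <- sprintf("G%06d", seq_len(34))
    labeled <- c("IL6", "AKT1", "STAT3", "IL1B", "TNF", "EGFR")
    nodes <- c(labeled, filler)

    edges <- cbind("IL6", setdiff(nodes, "IL6"))
    # a triangle among the degree-36 nodes: each needs one more neighbour
    # than the 34 fillers plus IL6 can provide
    edges <- rbind(edges,
                   c("AKT1", "STAT3"), c("STAT3", "IL1B"), c("IL1B", "AKT1"))
    for (v in c("AKT1", "STAT3", "IL1B")) {
      edges <- rbind(edges, cbind(v, sample(filler, 33)))
    }
    for (v in c("TNF", "EGFR")) {
      edges <- rbind(edges, cbind(v, filler))
    }
    pad_pairs <- t(utils::combn(filler, 2))
    pad <- pad_pairs[stats::runif(nrow(pad_pairs)) < 0.08, , drop = FALSE]
    edges <- canonical_pairs(rbind(edges, pad))

    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2]),
      directed = FALSE, vertices = nodes)
    igraph::E(g)$combined_score <- round(stats::runif(igraph::ecount(g),
                                                      0.9, 0.999), 3)
    g
  })
}

#' Specification for a synthetic multi-herb compound-target study
#'
#' Describes the tabular inputs of a compound-to-disease screening study:
#' how many compounds each herb contributes, the size of the gene universe
#' targets and disease genes are drawn from, the per-compound target-count
#' range, the disease-set size, and how strongly disease genes are
#' over-represented among predicted targets.
#'
#' The defaults mirror a nine-herb formulation study: per-herb compound
#' counts `c(6, 20, 5, 17, 34, 83, 17, 5, 5)` (192 compounds), a
#' 20000-gene universe and an 8886-gene disease set.
#'
#' @param compounds_per_herb Integer vector, one entry per herb.
#' @param gene_universe_size Number of genes in the universe.
#' @param targets_per_compound Length-2 integer range (inclusive) for the
#'   number of targets drawn per compound; minimum at least 1, so every
#'   compound has a defined target set.
#' @param disease_set_size Number of disease genes.
#' @param overlap_enrichment Sampling-weight multiplier applied to genes in
#'   the predicted-target union when drawing the disease set.  At 1 the
#'   disease set is uniform and the target/disease overlap is exactly
#'   hypergeometric; above 1 the overlap exceeds the hypergeometric
#'   expectation in expectation.
#' @param seed Integer RNG seed.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(compounds_per_herb = c(6, 20, 5, 17, 34, 83, 17, 5, 5),
                       gene_universe_size = 20000,
                       targets_per_compound = c(5, 50),
                       disease_set_size = 8886,
                       overlap_enrichment = 1,
                       seed = 1L) {
  stopifnot(length(compounds_per_herb) >= 1, all(compounds_per_herb >= 1),
            length(targets_per_compound) == 2)
  if (targets_per_compound[1] < 1 ||
      targets_per_compound[2] < targets_per_compound[1]) {
    stop("targets_per_compound must be an increasing range with minimum >= 1",
         call. = FALSE)
  }
  if (targets_per_compound[2] > gene_universe_size) {
    stop("targets_per_compound exceeds the gene universe", call. = FALSE)
  }
  if (disease_set_size > gene_universe_size) {
    stop("disease_set_size cannot exceed gene_universe_size", call. = FALSE)
  }
  if (overlap_enrichment < 1) {
    stop("overlap_enrichment must be >= 1", call. = FALSE)
  }
  structure(list(compounds_per_herb = as.integer(compounds_per_herb),
                 gene_universe_size = as.integer(gene_universe_size),
                 targets_per_compound = as.integer(targets_per_compound),
                 disease_set_size = as.integer(disease_set_size),
                 overlap_enrichment = overlap_enrichment,
                 seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate synthetic compound, target and disease-gene tables
#'
#' Draws the three tabular inputs of the ingestion stage from a
#' [study_spec()]: an herb-compound table (compound name, PubChem-style
#' CID, origin herb), a compound-to-gene target map in which every compound
#' has at least one target, and a disease gene list sampled so that genes in
#' the predicted-target union are picked at `overlap_enrichment` times the
#' uniform rate.  All identifiers are synthetic tokens; output is
#' deterministic under the spec's seed.
#'
#' @param spec A `study_spec`.
#' @return A list with elements `compounds` (data frame: `compound`,
#'   `pubchem_cid`, `herb`), `targets` (data frame: `compound`, `gene`),
#'   `disease` (character vector) and `universe` (character vector).
#' @export
gen_compound_target_data <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  withr::with_seed(spec$seed, {
    universe <- sprintf("G%06d", seq_len(spec$gene_universe_size))
    n_herbs <- length(spec$compounds_per_herb)
    herbs <- sprintf("Herb%02d", seq_len(n_herbs))
    n_comp <- sum(spec$compounds_per_herb)
    compounds <- data.frame(
      compound = sprintf("CMP%04d", seq_len(n_comp)),
      pubchem_cid = sample.int(99999999L, n_comp),
      herb = rep(herbs, times = spec$compounds_per_herb),
      stringsAsFactors = FALSE)

    sizes <- sample_range(spec$targets_per_compound[1],
                          spec$targets_per_compound[2], n_comp)
    targets <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
      data.frame(compound = compounds$compound[i],
                 gene = sample(universe, sizes[i]),
                 stringsAsFactors = FALSE)
    }))

    hit <- universe %in% targets$gene
    w <- ifelse(hit, spec$overlap_enrichment, 1)
    disease <- sort(sample(universe, spec$disease_set_size, prob = w))

    list(compounds = compounds, targets = targets,
         disease = disease, universe = universe)
  })
}

#' Generate a synthetic GMT annotation library
#'
#' Draws `n_terms` gene sets from a universe.  Non-planted terms sample the
#' universe uniformly; the first `n_planted` terms over-sample members of
#' `planted_query` with weight `enrichment_factor`, planting true
#' enrichment signal for calibration and power testing of the
#' over-representation stage.  At `enrichment_factor = 1` all terms are
#' null draws.
#'
#' @param universe Character vector of gene symbols.
#' @param n_terms Number of terms.
#' @param term_size_range Length-2 inclusive range of genes per term.
#' @param planted_query Character vector of query genes the planted terms
#'   over-sample (may be empty).
#' @param n_planted Number of planted terms (at most `n_terms`).
#' @param enrichment_factor Sampling-weight multiplier (>= 1) applied to
#'   `planted_query` members within planted terms.
#' @param seed Integer RNG seed.
#' @return An `annotation_library` (see [annotation_library()]); planted
#'   terms are named `PLANTED###`, null terms `TERM###`.
#' @export
gen_annotation_library <- function(universe, n_terms, term_size_range,
                                   planted_query = character(),
                                   n_planted = 0, enrichment_factor = 1,
                                   seed = 1L) {
  stopifnot(n_terms >= 1, length(term_size_range) == 2)
  if (n_planted > n_terms) stop("n_planted cannot exceed n_terms",
                                call. = FALSE)
  if (term_size_range[1] < 1 || term_size_range[2] > length(universe) ||
      term_size_range[2] < term_size_range[1]) {
    stop("term_size_range must lie within the universe size", call. = FALSE)
  }
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1",
                                  call. = FALSE)
  withr::with_seed(as.integer(seed), {
    w_planted <- ifelse(universe %in% planted_query, enrichment_factor, 1)
    terms <- vector("list", n_terms)
    nms <- character(n_terms)
    for (i in seq_len(n_terms)) {
      size <- sample_range(term_size_range[1], term_size_range[2], 1)
      if (i <= n_planted) {
        terms[[i]] <- sort(sample(universe, size, prob = w_planted))
        nms[i] <- sprintf("PLANTED%03d", i)
      } else {
        terms[[i]] <- sort(sample(universe, size))
        nms[i] <- sprintf("TERM%03d", i)
      }
    }
    names(terms) <- nms
    annotation_library("synthetic", terms, universe)
  })
}
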