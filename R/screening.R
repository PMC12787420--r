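#' One round of mean-threshold centrality screening
#'
#' Computes degree, betweenness and closeness centrality on the current
#' graph, sets each metric's threshold to its arithmetic mean over all
#' current nodes, and retains the nodes that *strictly* exceed all three
#' thresholds.  The returned record is a full audit of the round: the three
#' thresholds, the node/edge counts of the input graph and of the induced
#' subgraph on the retained nodes, and the retained node set itself.
#'
#' By the handshake lemma the degree threshold of a round always equals
#' \eqn{2E/N} of that round's graph, which makes the reported thresholds
#' independently checkable from the node and edge counts alone.
#'
#' @param graph A non-empty igraph undirected graph.
#' @param round_index 1-based index used for bookkeeping in multi-round
#'   screens.
#' @param rule `"all"` (default) retains nodes strictly above the mean on
#'   *all three* metrics -- the standard hub definition in
#'   centrality-screening workflows; `"any"` retains nodes above the mean
#'   on at least one metric, a gentler variant useful for sensitivity
#'   analysis (see the package vignette for how the two behave on
#'   clique-like cores).
#' @return An object of class `screening_round`: a list with elements
#'   `round_index`, `dc_threshold`, `bc_threshold`, `cc_threshold`,
#'   `n_nodes_in`, `n_edges_in`, `n_nodes_out`, `n_edges_out`, `retained`
#'   (character vector) and `centrality` (the round's centrality table).
#' @seealso [iterative_screen()] for the full procedure,
#'   [thresholds_report()] for a per-round summary table.
#' @export
screening_round <- function(graph, round_index = 1L, rule = c("all", "any")) {
  if (!inherits(graph, "igraph")) stop("graph must be an igraph object",
                                       call. = FALSE)
  if (igraph::vcount(graph) == 0) stop("cannot screen an empty graph",
                                       call. = FALSE)
  rule <- match.arg(rule)
  tab <- centrality_table(graph)
  dc_thr <- mean(tab$dc)
  bc_thr <- mean(tab$bc)
  cc_thr <- mean(tab$cc)
  pass <- cbind(tab$dc > dc_thr, tab$bc > bc_thr, tab$cc > cc_thr)
  retained <- tab$node[if (rule == "all") rowSums(pass) == 3L
                       else rowSums(pass) >= 1L]
  sub <- igraph::induced_subgraph(graph, retained)
  structure(list(round_index = as.integer(round_index),
                 dc_threshold = dc_thr,
                 bc_threshold = bc_thr,
                 cc_threshold = cc_thr,
                 n_nodes_in = igraph::vcount(graph),
                 n_edges_in = igraph::ecount(graph),
                 n_nodes_out = igraph::vcount(sub),
                 n_edges_out = igraph::ecount(sub),
                 retained = retained,
                 rule = rule,
                 centrality = tab),
            class = "screening_round")
}

#' Iterative mean-threshold screening of hub genes
#'
#' Applies [screening_round()] repeatedly, each time recomputing all three
#' centralities on the induced subgraph of the previously retained nodes, so
#' thresholds tighten as the network condenses.  Nodes isolated by the
#' induction are carried into the next round, where their zero closeness
#' removes them.
#'
#' Stopping is governed by `policy`:
#' \describe{
#'   \item{`"convergence"`}{(default) iterate until a round retains every
#'     current node (the core) or retains nothing, in which case the round's
#'     input node set is the core.  On a regular (fully symmetric) graph no
#'     node strictly exceeds the mean, so the whole graph is its own core.}
#'   \item{`"rounds:k"`}{run exactly `k` rounds (fewer if a round first
#'     empties or stabilises).}
#'   \item{`"size:m"`}{stop as soon as a round retains `m` nodes or fewer.}
#' }
#' Because retention uses strict inequalities, the node count strictly
#' decreases every non-terminal round and the procedure always terminates.
#'
#' @param graph A non-empty igraph undirected graph.
#' @param policy Stopping policy string (see Details).
#' @param rule Retention rule passed to [screening_round()]: `"all"`
#'   (default, conjunction of the three metrics) or `"any"`.
#' @return An object of class `screening_result`: list with `rounds` (list
#'   of `screening_round` audits, including the terminal round), `core`
#'   (character vector of core genes) and `core_subgraph` (igraph induced
#'   subgraph on the core).
#' @examples
#' spec <- network_spec(n_total = 60, core_size = 4,
#'                      core_attach_frac = 0.5, bg_edge_prob = 0.03,
#'                      seed = 11)
#' net <- gen_planted_core_network(spec)
#' res <- iterative_screen(net$graph)
#' sort(res$core)
#' @export
iterative_screen <- function(graph, policy = "convergence",
                             rule = c("all", "any")) {
  pol <- parse_stop_policy(policy)
  rule <- match.arg(rule)
  rounds <- list()
  current <- graph
  i <- 1L
  repeat {
    rd <- screening_round(current, round_index = i, rule = rule)
    rounds[[i]] <- rd
    if (length(rd$retained) == 0) {
      core <- igraph::V(current)$name
      break
    }
    if (length(rd$retained) == rd$n_nodes_in) {
      core <- rd$retained
      break
    }
    if (pol$kind == "rounds" && i >= pol$k) {
      core <- rd$retained
      break
    }
    if (pol$kind == "size" && length(rd$retained) <= pol$k) {
      core <- rd$retained
      break
    }
    current <- igraph::induced_subgraph(current, rd$retained)
    i <- i + 1L
  }
  structure(list(rounds = rounds,
                 core = sort(core),
                 core_subgraph = igraph::induced_subgraph(graph, core)),
            class = "screening_result")
}

parse_stop_policy <- function(policy) {
  stopifnot(is.character(policy), length(policy) == 1)
  if (policy == "convergence") return(list(kind = "convergence", k = NA))
  m <- regmatches(policy, regexec("^(rounds|size):([0-9]+)$", policy))[[1]]
  if (length(m) == 0) {
    stop("policy must be \"convergence\", \"rounds:k\" or \"size:m\"",
         call. = FALSE)
  }
  k <- as.integer(m[3])
  if (k < 1) stop("policy count must be >= 1", call. = FALSE)
  list(kind = m[2], k = k)
}

#' Per-round threshold report
#'
#' Renders the audit trail of an [iterative_screen()] run as one row per
#' round, carrying the full-precision thresholds together with display
#' strings rounded the way topology-screening tables customarily print them:
#' degree thresholds to 5 decimals, betweenness and closeness thresholds to
#' 6.  Rounding is display-only; all screening comparisons use full
#' precision.
#'
#' @param result A `screening_result`.
#' @return A data frame with columns `round`, `n_nodes_in`, `n_edges_in`,
#'   `n_nodes_out`, `n_edges_out`, `dc_threshold`, `bc_threshold`,
#'   `cc_threshold`, `dc_display`, `bc_display`, `cc_display`.
#' @export
thresholds_report <- function(result) {
  stopifnot(inherits(result, "screening_result"))
  rows <- lapply(result$rounds, function(rd) {
    data.frame(round = rd$round_index,
               n_nodes_in = rd$n_nodes_in,
               n_edges_in = rd$n_edges_in,
               n_nodes_out = rd$n_nodes_out,
               n_edges_out = rd$n_edges_out,
               dc_threshold = rd$dc_threshold,
               bc_threshold = rd$bc_threshold,
               cc_threshold = rd$cc_threshold,
               dc_display = format_threshold(rd$dc_threshold, 5L),
               bc_display = format_threshold(rd$bc_threshold, 6L),
               cc_display = format_threshold(rd$cc_threshold, 6L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

format_threshold <- function(x, digits) {
  formatC(round(x, digits), format = "f", digits = digits)
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Iterative centrality screening:",
      length(x$rounds), "round(s)\n")
  rep <- thresholds_report(x)
  for (i in seq_len(nrow(rep))) {
    cat(sprintf("  round %d: %d nodes / %d edges -> %d nodes; DC > %s, BC > %s, CC > %s\n",
                rep$round[i], rep$n_nodes_in[i], rep$n_edges_in[i],
                rep$n_nodes_out[i], rep$dc_display[i], rep$bc_display[i],
                rep$cc_display[i]))
  }
  cat("core (", length(x$core), " genes): ",
      paste(x$core, collapse = ", "), "\n", sep = "")
  cat("core subgraph: ", igraph::vcount(x$core_subgraph), " nodes, ",
      igraph::ecount(x$core_subgraph), " edges\n", sep = "")
  invisible(x)
}
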