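test_that("network_spec validates its invariants", {
  expect_error(network_spec(10, 1, 0.5, 0.1, 1), "core_size")
  expect_error(network_spec(10, 10, 0.5, 0.1, 1), "core_size")
  expect_error(network_spec(10, 3, 1.5, 0.1, 1), "probabilities")
  expect_error(network_spec(10, 3, 0, 0, 1), "never connect")
})

test_that("planted-core networks have an exact clique core and are connected", {
  spec <- network_spec(n_total = 300, core_size = 6, core_attach_frac = 0.4,
                       bg_edge_prob = 0.01, seed = 1)
  net <- gen_planted_core_network(spec)
  expect_equal(igraph::vcount(net$graph), 300)
  expect_length(net$core, 6)
  sub <- igraph::induced_subgraph(net$graph, net$core)
  expect_equal(igraph::ecount(sub), choose(6, 2))
  expect_true(igraph::is_connected(net$graph))
  expect_true(all(igraph::E(net$graph)$combined_score >= 0 &
                    igraph::E(net$graph)$combined_score <= 1))

  # degenerate corner: 2-node core, full attachment, no background
  tiny <- gen_planted_core_network(network_spec(10, 2, 1.0, 0, seed = 7))
  d <- degree_centrality(tiny$graph)
  expect_equal(unname(d[tiny$core]), c(9L, 9L))
})

test_that("planted-core generation is deterministic and core degrees dominate", {
  spec <- network_spec(120, 5, 0.3, 0.02, seed = 42)
  a <- gen_planted_core_network(spec)
  b <- gen_planted_core_network(spec)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_identical(igraph::E(a$graph)$combined_score,
                   igraph::E(b$graph)$combined_score)
  expect_identical(a$core, b$core)

  for (seed in 1:25) {
    net <- gen_planted_core_network(network_spec(150, 6, 0.4, 0.01, seed = seed))
    d <- degree_centrality(net$graph)
    expect_gt(mean(d[net$core]), mean(d[setdiff(names(d), net$core)]))
  }
})

test_that("the 40-node hub network reproduces the labeled degrees for any seed", {
  for (seed in c(1, 2, 17, 101)) {
    g <- gen_table2_network(seed)
    expect_equal(igraph::vcount(g), 40)
    expect_true(igraph::is_simple(g))
    expect_true(igraph::is_connected(g))
    d <- degree_centrality(g)
    expect_equal(unname(d["IL6"]), 39L)
    expect_equal(unname(d[c("AKT1", "STAT3", "IL1B")]), rep(36L, 3))
    expect_equal(unname(d[c("TNF", "EGFR")]), rep(35L, 3 - 1))
  }
})

test_that("universal-node closeness identity holds on every seed", {
  # with a universal node every non-neighbour sits at distance exactly 2:
  # cc(v) = (n-1) / (dc(v) + 2 (n-1-dc(v)))
  for (seed in 1:10) {
    g <- gen_table2_network(seed)
    d <- degree_centrality(g)
    cc <- closeness_centrality(g)
    expect_equal(unname(cc), (39) / (unname(d) + 2 * (39 - unname(d))),
                 tolerance = 1e-12)
  }
})

test_that("synthetic study tables honour the spec and are reproducible", {
  spec <- study_spec(compounds_per_herb = c(3, 5, 2),
                     gene_universe_size = 500,
                     targets_per_compound = c(2, 10),
                     disease_set_size = 100,
                     overlap_enrichment = 1, seed = 9)
  dat <- gen_compound_target_data(spec)
  expect_equal(unname(table(dat$compounds$herb)[unique(dat$compounds$herb)]),
               c(3L, 5L, 2L), ignore_attr = TRUE)
  expect_equal(nrow(dat$compounds), 10)
  # every compound has at least one target
  expect_setequal(unique(dat$targets$compound), dat$compounds$compound)
  sizes <- table(dat$targets$compound)
  expect_true(all(sizes >= 2 & sizes <= 10))
  expect_length(dat$disease, 100)

  # byte-identical determinism through the writers
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_target_map(gen_compound_target_data(spec)$targets, f1)
  write_target_map(gen_compound_target_data(spec)$targets, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("study spec validation rejects impossible settings", {
  expect_error(study_spec(disease_set_size = 600, gene_universe_size = 500),
               "disease_set_size")
  expect_error(study_spec(targets_per_compound = c(0, 5)), "minimum")
  expect_error(study_spec(overlap_enrichment = 0.5), "overlap_enrichment")
})

test_that("null-overlap studies match the hypergeometric expectation", {
  # with overlap_enrichment = 1 the disease draw is uniform, so the overlap
  # with the target union is Hypergeometric(N, K, n) with mean nK/N
  overlaps <- numeric(200)
  expected <- numeric(200)
  vars <- numeric(200)
  for (s in 1:200) {
    spec <- study_spec(compounds_per_herb = c(4, 4), gene_universe_size = 400,
                       targets_per_compound = c(5, 15), disease_set_size = 80,
                       overlap_enrichment = 1, seed = s)
    dat <- gen_compound_target_data(spec)
    union <- sort(unique(dat$targets$gene))
    K <- length(union); N <- 400; n <- 80
    overlaps[s] <- length(intersect(union, dat$disease))
    expected[s] <- n * K / N
    vars[s] <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
  }
  se <- sqrt(sum(vars)) / 200
  expect_lt(abs(mean(overlaps) - mean(expected)), 3 * se)
})

test_that("synthetic GMT libraries have the requested shape", {
  universe <- sprintf("G%06d", 1:200)
  lib <- gen_annotation_library(universe, n_terms = 5,
                                term_size_range = c(10, 10), seed = 3)
  expect_length(lib$terms, 5)
  expect_true(all(lengths(lib$terms) == 10))
  expect_true(all(unlist(lib$terms) %in% universe))

  # a planted term holding exactly the query attains the library's minimum p
  query <- sample(universe, 12)
  terms <- c(list(EXACT = query),
             lapply(1:6, function(i) sample(universe, 12)))
  names(terms) <- c("EXACT", sprintf("NULL%d", 1:6))
  res <- fisher_enrich(query, annotation_library("demo", terms, universe))
  expect_equal(res$term_id[which.min(res$p_value)], "EXACT")

  expect_error(gen_annotation_library(universe, 5, c(10, 300)), "universe")
  expect_error(gen_annotation_library(universe, 5, c(5, 10), n_planted = 9),
               "n_planted")
})

test_that("planted enrichment signal ranks planted terms first", {
  universe <- sprintf("G%06d", 1:500)
  wins <- 0
  for (s in 1:40) {
    set.seed(1000 + s)
    query <- sample(universe, 40)
    lib <- gen_annotation_library(universe, n_terms = 20,
                                  term_size_range = c(20, 40),
                                  planted_query = query, n_planted = 3,
                                  enrichment_factor = 8, seed = s)
    res <- top_k(fisher_enrich(query, lib), 3)
    if (all(grepl("^PLANTED", res$term_id))) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)
})
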