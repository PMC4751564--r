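edge_tbl <- function(a, b, cls = rep("other", length(a))) {
  tibble::tibble(gene_a = a, gene_b = b, evidence_class = cls)
}

test_that("graph building induces, de-loops and merges by evidence precedence", {
  edges <- edge_tbl(c("A", "B", "C", "A", "A", "A", "B"),
                    c("B", "C", "D", "E", "A", "B", "A"),
                    c("Two-hybrid", "other", "other", "other", "affinity",
                      "Affinity Capture-MS", "Two-hybrid"))
  g <- build_graph(edges, hit_set = c("A", "B", "C"))
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 2)                      # (A,B) merged, (B,C); no loop
  ab <- el[el$from %in% c("A", "B") & el$to %in% c("A", "B"), ]
  expect_equal(ab$evidence_class, "affinity")    # affinity beats two-hybrid
  expect_warning(
    build_graph(edges, hit_set = c("A", "zz"), gene_universe = c("A", "B")),
    "isolated"
  )
})

test_that("reference nodes merge their member genes' interactions", {
  edges <- edge_tbl(c("TOR1", "KOG1", "X"), c("X", "Y", "Y"))
  g <- build_graph(edges, hit_set = c("X", "Y"),
                   reference_nodes = list(TORC1 = c("TOR1", "KOG1")))
  expect_true("TORC1" %in% igraph::V(g)$name)
  expect_true(igraph::are_adjacent(g, "TORC1", "X"))
  expect_true(igraph::are_adjacent(g, "TORC1", "Y"))
  expect_true(igraph::V(g)$is_reference[igraph::V(g)$name == "TORC1"])
})

test_that("induced edge counting matches the toy examples", {
  edges <- edge_tbl(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(count_induced_edges(edges, c("A", "B", "C")), 2)
  expect_equal(count_induced_edges(edges, character(0)), 0)
  expect_equal(count_induced_edges(edge_tbl("A", "A"), "A"), 0)
})

test_that("graph statistics match brute-force oracles on small graphs", {
  set.seed(71)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    genes <- sprintf("g%02d", seq_len(n))
    m <- sample(5:60, 1)
    a <- sample(genes, m, replace = TRUE)
    b <- sample(genes, m, replace = TRUE)
    edges <- edge_tbl(a, b)
    set <- sample(genes, sample(3:n, 1))
    expect_equal(count_induced_edges(edges, set),
                 brute_induced_edges(edges, set))

    g <- build_graph(edges, hit_set = genes)
    hubs <- sample(genes, 2)
    pruned <- prune_hubs(g, hubs)
    el <- ribiscreen:::canonical_edges(edges)
    expect_setequal(igraph::V(pruned)$name, brute_prune(genes, el, hubs))

    cs <- component_stats(g)
    expect_equal(cs$component_sizes, brute_components(genes, el))
    expect_equal(cs$major_component_size, max(brute_components(genes, el)))
    expect_equal(sum(cs$component_sizes), cs$n_nodes)
  }
})

test_that("hub pruning removes hubs and hub-only neighbors, nothing else", {
  edges <- edge_tbl(c("H", "H", "X"), c("X", "Y", "Z"))
  g <- build_graph(edges, hit_set = c("H", "X", "Y", "Z"))
  pruned <- prune_hubs(g, "H")
  expect_setequal(igraph::V(pruned)$name, c("X", "Z"))
  expect_true(igraph::are_adjacent(pruned, "X", "Z"))
  expect_equal(igraph::V(prune_hubs(g, "absent"))$name,
               igraph::V(g)$name)
})

test_that("component statistics handle edgeless and path graphs", {
  g0 <- build_graph(edge_tbl(character(0), character(0)),
                    hit_set = sprintf("n%d", 1:5))
  cs0 <- component_stats(g0)
  expect_equal(cs0$major_component_size, 1)
  expect_equal(cs0$isolated_count, 5)

  g1 <- build_graph(edge_tbl(c("A", "B"), c("B", "C")),
                    hit_set = c("A", "B", "C", "D"))
  cs1 <- component_stats(g1)
  expect_equal(cs1$major_component_size, 3)
  expect_equal(cs1$isolated_count, 1)
})

test_that("permutation null mean matches the uniform-placement expectation", {
  sim <- random_edge_list(1000, 2000, seed = 5)
  res <- permutation_test(sim$edges, sim$genes,
                          observed_set = sim$genes[1:100],
                          n_permutations = 2000, seed = 12)
  analytic <- 2000 * 100 * 99 / (1000 * 999)
  expect_lt(abs(res$null_mean - analytic) / analytic, 0.02)
})

test_that("empirical p is calibrated when the observed set is a null draw", {
  sim <- random_edge_list(200, 400, seed = 6)
  set.seed(88)
  ps <- vapply(1:100, function(i) {
    obs <- sample(sim$genes, 30)
    permutation_test(sim$edges, sim$genes, observed_set = obs,
                     n_permutations = 150, seed = i)$empirical_p
  }, numeric(1))
  expect_true(all(ps > 0))
  expect_lt(abs(mean(ps) - 0.5), 0.1)
})

test_that("planted enrichment reaches the minimum reportable p", {
  cfg <- graph_config(n_genes = 500, background_edges = 2000,
                      planted_set_size = 60, planted_extra_edges = 200,
                      seed = 31)
  planted <- sprintf("gene%05d", 1:60)
  sim <- simulate_graph(cfg, planted_genes = planted)
  res <- permutation_test(sim$edges, sim$genes, observed_set = planted,
                          n_permutations = 2000, seed = 9)
  expect_equal(res$empirical_p, 1 / 2001)
  expect_lt(res$null_max, res$observed_edges)
})

test_that("a whole-universe set degenerates to p = 1 with zero null spread", {
  sim <- random_edge_list(30, 40, seed = 7)
  res <- permutation_test(sim$edges, sim$genes, observed_set = sim$genes,
                          n_permutations = 50, seed = 3)
  expect_equal(res$null_sd, 0)
  expect_equal(res$observed_edges, 40)
  expect_equal(res$empirical_p, 1)
})

test_that("hypergeometric enrichment matches direct enumeration", {
  u <- sprintf("u%02d", 1:10)
  p <- hypergeometric_enrichment(u[1:4], u[c(1:3, 9, 10)], u)
  # overlap 3 of possible: C(5,3)C(5,1)/C(10,4) + C(5,4)C(5,0)/C(10,4)
  expect_equal(p, (choose(5, 3) * choose(5, 1) + choose(5, 4)) / choose(10, 4))
  # universe 10, hits 4, annotation 5, overlap 4 -> C(5,4)C(5,0)/C(10,4)
  expect_equal(hypergeometric_enrichment(u[1:4], u[c(1:4, 10)], u), 5 / 210)
  expect_equal(hypergeometric_enrichment(u[1:4], u, u), 1)
  expect_equal(hypergeometric_enrichment(u[1:4], u[5:7], u),
               enum_hyper_upper(0, 3, 7, 4))
  expect_error(hypergeometric_enrichment("a", "a", character(0)), "non-empty")

  set.seed(19)
  for (i in 1:10) {
    N <- sample(8:20, 1)
    uni <- sprintf("x%02d", seq_len(N))
    hits <- sample(uni, sample(2:(N - 2), 1))
    anno <- sample(uni, sample(2:(N - 2), 1))
    q <- length(intersect(hits, anno))
    expect_equal(
      hypergeometric_enrichment(hits, anno, uni),
      enum_hyper_upper(q, length(anno), N - length(anno), length(hits)),
      tolerance = 1e-12
    )
  }
})

test_that("GraphML export round-trips structure and attributes", {
  edges <- edge_tbl(c("A", "B"), c("B", "C"), c("affinity", "other"))
  anno <- tibble::tibble(gene = c("A", "B"),
                         tag = c("downstream_TORC1", "nucleus"))
  g <- build_graph(edges, hit_set = c("A", "B", "C", "D"), annotations = anno)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, path, "graphml")
  back <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(back), 2)
  expect_equal(
    igraph::V(back)$downstream_torc1[igraph::V(back)$name == "A"], 1)
  expect_equal(
    igraph::V(back)$localization[igraph::V(back)$name == "B"], "nucleus")
  expect_setequal(igraph::E(back)$evidence_class, c("affinity", "other"))

  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), 3)            # 2 edges + 1 isolated node
  expect_true("D" %in% lines)

  # empty graph: valid files
  g0 <- build_graph(edge_tbl(character(0), character(0)), hit_set = character(0))
  p0 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g0, p0, "graphml")
  expect_equal(igraph::vcount(igraph::read_graph(p0, format = "graphml")), 0)
})
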