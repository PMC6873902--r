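toy_background <- function(edges_df) {
  edges_to_network(edges_df, min_score = 0)
}

test_that("seed set is the tagged union of abundance and phospho lists", {
  s <- build_seed_set(c("A", "B"), c("B", "C"))
  expect_setequal(s$protein_id, c("A", "B", "C"))
  expect_equal(s$change_kind[match(c("A", "B", "C"), s$protein_id)],
               c("abundance", "both", "phospho"))
  big <- build_seed_set(sprintf("a%d", 1:98), sprintf("p%d", 1:190))
  expect_equal(nrow(big), 288)
  expect_error(build_seed_set(character(0), character(0)), "empty")
})

test_that("expansion adds direct neighbors and induced edges only", {
  star <- toy_background(data.frame(
    protein_a = "HUB", protein_b = c("A", "B", "C"), combined_score = 0.95))
  net <- expand_network("HUB", star)
  expect_setequal(net$nodes$protein_id, c("HUB", "A", "B", "C"))
  expect_equal(igraph::ecount(net$graph), 3)

  expect_warning(iso <- expand_network("ZZZ", star), "no seed")
  expect_equal(iso$nodes$protein_id, "ZZZ")
  expect_equal(iso$nodes$degree, 0L)

  # two seeds sharing a neighbor: neighbor once, spokes + neighbor edge
  toy <- toy_background(data.frame(
    protein_a = c("S1", "S2", "N", "X"),
    protein_b = c("N", "N", "M", "Y"),
    combined_score = 0.95))
  net2 <- expand_network(c("S1", "S2"), toy)
  expect_setequal(net2$nodes$protein_id, c("S1", "S2", "N"))
  expect_equal(igraph::ecount(net2$graph), 2)

  # idempotence: expanding the expanded node set adds nothing new for
  # the same seed set
  again <- expand_network(c("S1", "S2"), toy)
  expect_setequal(again$nodes$protein_id, net2$nodes$protein_id)
})

test_that("Poisson enrichment equals brute-force pmf summation", {
  expect_equal(edge_enrichment(0, 5), 1.0)
  expect_equal(edge_enrichment(10, 10), 0.5420703, tolerance = 1e-6)
  for (lam in c(0.5, 5, 50, 189, 300)) {
    for (x in c(1, 10, 100, 850, 1000)) {
      expect_equal(edge_enrichment(x, lam), pois_tail_bruteforce(x, lam),
                   tolerance = 1e-10)
    }
  }
  expect_error(edge_enrichment(-1, 5), "nonnegative")
  expect_error(edge_enrichment(5, 0), "positive")
})

test_that("expected edge count scales with background density", {
  # complete graph on 4 nodes: density 1, so any m nodes expect m(m-1)/2
  k4 <- toy_background(data.frame(
    protein_a = c("A", "A", "A", "B", "B", "C"),
    protein_b = c("B", "C", "D", "C", "D", "D"),
    combined_score = 0.95))
  expect_equal(expected_edge_count(3, k4), 3)
  expect_equal(expected_edge_count(3, k4, universe = c("A", "B", "C", "D")), 3)
  expect_error(expected_edge_count(3, k4, universe = "A"), "fewer than 2")
})

test_that("degree fits recover parameters and respect pmf structure", {
  set.seed(51)
  k <- r_ztpois(500, 5)
  fit <- fit_degree_distribution(k)
  expect_equal(fit$family, "poisson")
  expect_lt(abs(fit$params[["lambda"]] - 5), 0.3)

  kl <- r_dlnorm(500, 1.5, 0.6)
  expect_equal(fit_degree_distribution(kl)$family, "lognormal")

  # every family's truncated pmf starts with full mass at k = 1 and its
  # tail is non-increasing
  for (fam in c("poisson", "exponential", "power_law", "lognormal")) {
    tp <- degree_tail_p(fit, 1:200, family = fam)
    expect_equal(tp[1], 1, tolerance = 1e-9)
    expect_true(all(diff(tp) <= 1e-12))
  }
  # light-tailed families concentrate their mass below k = 2000
  for (fam in c("poisson", "exponential", "lognormal")) {
    expect_lt(degree_tail_p(fit, 2000, family = fam), 1e-6)
  }
  # zeta-family mass checked against the zeta normalization on its own data
  fitz <- fit_degree_distribution(r_zeta(500, 2.5))
  alpha <- fitz$fits$power_law$params[["alpha"]]
  ks <- 1:1e6
  expect_equal(sum(ks^(-alpha)) / pracma::zeta(alpha), 1, tolerance = 1e-6)
  expect_lte(degree_tail_p(fit, max(k)), degree_tail_p(fit, 1))

  expect_error(fit_degree_distribution(rep(3, 50)), "degenerate")
  expect_error(fit_degree_distribution(1:5), "at least 10")
})

test_that("planted high-degree nodes are called as hubs", {
  ids <- sprintf("P%03d", 1:300)
  net <- generate_network(ids, n_extra_nodes = 190, n_planted_hubs = 10,
                          hub_degree = 35, seed = 27)
  bg <- edges_to_network(net$edges, min_score = 0)
  fit <- fit_degree_distribution(bg$nodes$degree)
  bg$nodes$tail_p <- degree_tail_p(fit, bg$nodes$degree)
  hubs <- hub_calls(bg$nodes, alpha = 0.05)
  planted <- net$truth$node[net$truth$is_planted_hub]
  expect_gte(length(intersect(hubs$protein_id, planted)), 8)
  expect_equal(nrow(hub_calls(bg$nodes, alpha = 0)), 0)
  # ordering: degree descending, ties lexicographic
  expect_true(all(diff(hubs$degree) <= 0))
})

test_that("subset degree permutation behaves at the extremes", {
  ids <- sprintf("P%03d", 1:200)
  net <- generate_network(ids, n_extra_nodes = 0, seed = 29)
  bg <- edges_to_network(net$edges, min_score = 0)
  whole <- subgraph_degree_permutation(bg, bg$nodes$protein_id,
                                       n_perm = 200, seed = 1)
  expect_equal(whole$p, 1.0)
  top <- bg$nodes$protein_id[order(-bg$nodes$degree)][1:15]
  res <- subgraph_degree_permutation(bg, top, n_perm = 1000, seed = 1)
  expect_lte(res$p, 0.01)
  expect_error(
    subgraph_degree_permutation(bg, c(bg$nodes$protein_id, "XX"), 200, 1),
    "outside")
  expect_error(subgraph_degree_permutation(bg, "P001", n_perm = 10, seed = 1),
               "n_perm")
})

test_that("edge-type counts enumerate endpoint kinds and conserve totals", {
  tri <- toy_background(data.frame(
    protein_a = c("A", "B", "C"), protein_b = c("B", "C", "A"),
    combined_score = 0.95))
  seeds <- data.frame(protein_id = c("A", "B", "C"),
                      change_kind = c("phospho", "phospho", "abundance"))
  net <- expand_network(seeds, tri)
  ct <- count_edge_types(net)
  expect_equal(ct[["pp"]], 1)
  expect_equal(ct[["aa"]], 0)
  expect_equal(ct[["mixed"]], 2)
  expect_equal(ct[["total"]], sum(ct[c("pp", "aa", "mixed")]))

  empty <- phosphoRescue:::new_interaction_network(
    igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(count_edge_types(empty)[["total"]], 0)
})

test_that("hub table columns reproduce the published accounting shape", {
  hub_tab <- read.delim(path_hub_table(), stringsAsFactors = FALSE)
  hubs <- hub_calls(hub_tab, alpha = 0.05)
  expect_true(all(c("protein_id", "degree", "tail_p") %in% names(hubs)))
  expect_true(all(hubs$tail_p < 0.05))
  expect_true(all(diff(hubs$degree) <= 0))
})
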