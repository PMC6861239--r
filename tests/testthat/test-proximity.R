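test_that("closest distance follows the mean-of-minima definition", {
  lcc <- path4_lcc()
  expect_equal(closest_distance(lcc, c("a", "b"), c("a", "b", "c")), 0)
  expect_equal(closest_distance(lcc, c("c", "d"), "a"), 2.5)
  expect_equal(closest_distance(lcc, c("b", "c"), c("a", "d")), 1.0)
  expect_error(closest_distance(lcc, character(0), "a"), "nonempty")
  expect_error(closest_distance(lcc, "a", character(0)), "nonempty")
})

test_that("network score is the diameter-normalized linear transform", {
  expect_equal(network_score(0, 3), 1.0)
  expect_equal(network_score(3, 3), 0.0)
  expect_equal(network_score(2.5, 3), 1 - 2.5 / 3)
  expect_equal(round(network_score(2.5, 3), 4), 0.1667)
  expect_error(network_score(4, 3), "d_c")
})

test_that("closest distance matches the BFS oracle on random graphs", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    g <- igraph::sample_gnp(n, 2.5 / n)
    igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
    lcc <- lcc_and_diameter(g)
    nodes <- igraph::V(lcc$graph)$name
    if (length(nodes) < 6) next
    edges <- graph_edges(lcc$graph)
    dists <- node_distances(lcc$graph)
    for (draw in 1:5) {
      t_set <- sample(nodes, sample(2:4, 1))
      s_set <- sample(nodes, sample(2:4, 1))
      expect_equal(closest_distance(lcc, t_set, s_set, dists = dists),
                   oracle_closest_distance(edges, nodes, t_set, s_set))
    }
  }
})

test_that("adding an edge never increases the closest distance", {
  set.seed(23)
  g <- igraph::sample_gnp(30, 0.12)
  igraph::V(g)$name <- sprintf("v%02d", 1:30)
  lcc <- lcc_and_diameter(g)
  nodes <- igraph::V(lcc$graph)$name
  t_set <- sample(nodes, 4); s_set <- sample(nodes, 4)
  d0 <- closest_distance(lcc, t_set, s_set)
  for (rep in 1:10) {
    pair <- sample(nodes, 2)
    g2 <- igraph::add_edges(lcc$graph, match(pair, nodes))
    g2 <- igraph::simplify(g2)
    expect_lte(closest_distance(list(graph = g2), t_set, s_set), d0 + 1e-12)
  }
})

test_that("the combined score attains its bounds on constructed cases", {
  lcc <- path4_lcc()
  dag <- go_dag_from_edges(sibling_edges())
  annot <- gene_annotation(list(a = "A", b = "A", c = "B", d = "B"), dag)

  both <- proximity_score(lcc, dag, annot, c("a", "b"), c("a", "b"))
  expect_equal(both$total, 2.0)  # T = S, identical annotations

  # maximally distant with zero semantic overlap: two DAG components
  dag2 <- go_dag_from_edges(data.frame(
    child = c("A", "B"), parent = c("R1", "R2"), relation = "is_a"))
  annot2 <- gene_annotation(list(a = "A", d = "B"), dag2)
  far <- proximity_score(lcc, dag2, annot2, "a", "d")
  expect_equal(far$total, 0.0)

  # components recombine to the reported total
  b <- generate_fixture_bundle(19L, "tiny")
  net <- integrate_network(load_regulatory(b$regulatory),
                           suppressMessages(load_ppi(b$ppi, b$expression)))
  lccf <- lcc_and_diameter(net)
  nodes <- igraph::V(lccf$graph)$name
  set.seed(3)
  t_set <- sample(nodes, 5); s_set <- sample(nodes, 6)
  ps <- proximity_score(lccf, b$dag, b$annotations, t_set, s_set)
  expect_equal(ps$total, ps$network_score + ps$semantic_score)
  expect_equal(ps$network_score,
               1 - closest_distance(lccf, t_set, s_set) / lccf$diameter)
  expect_equal(ps$semantic_score,
               gene_set_similarity(b$dag, b$annotations, t_set, s_set))
})

test_that("greedy degree bins respect occupancy and degree boundaries", {
  bins <- netrepurpose:::.greedy_bins(
    stats::setNames(1:10, letters[1:10]), 3L)
  expect_equal(unname(bins), c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L))

  # a degree value is never split across bins
  deg <- stats::setNames(c(1, 1, 1, 1, 2, 2, 3), sprintf("n%d", 1:7))
  b2 <- netrepurpose:::.greedy_bins(deg, 2L)
  expect_equal(length(unique(b2[deg == 1])), 1L)

  star <- igraph::make_star(8, mode = "undirected")
  igraph::V(star)$name <- letters[1:8]
  expect_equal(length(degree_bins(star, 1L)$levels), 2L)  # leaves vs hub
  expect_warning(one <- degree_bins(star, 100L), "single bin")
  expect_equal(length(one$levels), 1L)
})

test_that("random modules are degree-matched, distance-preserving, seeded", {
  b <- generate_fixture_bundle(5L, "small")
  net <- integrate_network(load_regulatory(b$regulatory),
                           suppressMessages(load_ppi(b$ppi, b$expression)))
  lcc <- lcc_and_diameter(net)
  dists <- node_distances(lcc$graph)
  bins <- suppressMessages(degree_bins(lcc))
  nodes <- igraph::V(lcc$graph)$name
  target <- b$ground_truth$positive_target
  retained <- names(sort(dists[target, ])[3:8])
  dm <- build_drug_module(lcc, target, retained, "D", dists = dists)

  set.seed(101)
  r1 <- random_drug_module(lcc, dm, bins, dists = dists)
  set.seed(101)
  r2 <- random_drug_module(lcc, dm, bins, dists = dists)
  expect_identical(r1$nodes, r2$nodes)  # seeded determinism

  set.seed(77)
  for (i in 1:20) {
    r <- random_drug_module(lcc, dm, bins, dists = dists)
    expect_equal(bins$bin[[r$target]], bins$bin[[target]])
    # distance multiset preserved when every shell is nonempty
    shells_ok <- all(vapply(unname(dm$distances), function(d) {
      sum(dists[r$target, ] == d) >= sum(dm$distances == d)
    }, TRUE))
    if (shells_ok) {
      expect_equal(sort(unname(r$distances)), sort(unname(dm$distances)))
    }
  }
})

test_that("significance uses the add-one p and the strict quantile rule", {
  b <- generate_fixture_bundle(5L, "small")
  net <- integrate_network(load_regulatory(b$regulatory),
                           suppressMessages(load_ppi(b$ppi, b$expression)))
  lcc <- lcc_and_diameter(net)
  part <- detect_communities(lcc)
  mods <- call_disease_modules(part, b$ground_truth$disease_genes)
  S <- disease_module_members(mods)[[1]]
  dists <- node_distances(lcc$graph)
  bins <- suppressMessages(degree_bins(lcc))
  cache <- wang_cache(b$dag, b$annotations)

  sig <- select_signature(
    b$signatures[b$signatures$drug_id == "D_POS", ])
  flt <- filter_signature(b$ground_truth$positive_target, sig, lcc,
                          b$dag, b$annotations, cache = cache)
  dm <- build_drug_module(lcc, b$ground_truth$positive_target,
                          flt$gene[flt$retained], "D_POS", dists = dists)
  sg <- proximity_significance(lcc, b$dag, b$annotations, dm, S,
                               bins = bins, n_random = 200, seed = 42,
                               dists = dists, cache = cache)
  expect_equal(sg$empirical_p,
               (1 + sum(sg$null_scores >= sg$total)) / (1 + 200))
  thr <- sort(sg$null_scores)[ceiling(0.95 * 200)]
  expect_equal(sg$null_quantile, thr)
  expect_equal(sg$significant, sg$total > thr)
  expect_true(all(sg$null_scores >= 0 & sg$null_scores <= 2))

  sg2 <- proximity_significance(lcc, b$dag, b$annotations, dm, S,
                                bins = bins, n_random = 200, seed = 42,
                                dists = dists, cache = cache)
  expect_identical(sg$null_scores, sg2$null_scores)  # seeded determinism
})

test_that("the fast scoring path agrees with the reference computation", {
  b <- generate_fixture_bundle(29L, "tiny")
  net <- integrate_network(load_regulatory(b$regulatory),
                           suppressMessages(load_ppi(b$ppi, b$expression)))
  lcc <- lcc_and_diameter(net)
  nodes <- igraph::V(lcc$graph)$name
  dists <- node_distances(lcc$graph)
  cache <- wang_cache(b$dag, b$annotations)
  set.seed(13)
  S <- sample(nodes, 8)
  engine <- netrepurpose:::.module_score_engine(lcc, S, dists, cache)
  for (i in 1:25) {
    T <- sample(nodes, sample(3:7, 1))
    ref <- proximity_score(lcc, b$dag, b$annotations, T, S,
                           dists = dists, cache = cache)
    expect_equal(engine(T), ref$total, tolerance = 1e-12)
  }
})
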