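test_that("graph construction and giant component follow the tie rules", {
  edges <- data.frame(node1 = c("A", "B", "C", "X"),
                      node2 = c("B", "C", "A", "Y"),
                      weight = c(0.9, 0.8, 0.7, 0.5))
  g <- build_graph(edges)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  gc <- giant_component(g)
  expect_setequal(igraph::V(gc)$name, c("A", "B", "C"))
  # connected graph is its own giant component
  expect_equal(igraph::vcount(giant_component(gc)), 3)
  # equal-size components: the one holding the alphabetically first node
  e2 <- data.frame(node1 = c("M", "N", "A", "B"),
                   node2 = c("N", "O", "B", "C"),
                   weight = rep(0.5, 4))
  gc2 <- giant_component(build_graph(e2))
  expect_setequal(igraph::V(gc2)$name, c("A", "B", "C"))
  expect_error(giant_component(igraph::make_empty_graph(0)), "empty")
  expect_error(build_graph(data.frame(node1 = "A", node2 = "B",
                                      weight = 1.2)), "\\(0, 1\\]")
})

test_that("TOM reproduces hand-evaluated cases and the naive oracle", {
  # isolated pair with weight 0.5
  a2 <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_equal(tom_similarity(a2)["a", "b"], 0.5)
  # unit-weight triangle: off-diagonal TOM exactly 1
  a3 <- matrix(1, 3, 3) - diag(3)
  dimnames(a3) <- list(letters[1:3], letters[1:3])
  t3 <- tom_similarity(a3)
  expect_equal(t3[upper.tri(t3)], rep(1, 3))
  # no edge, no shared neighbor -> 0
  a4 <- diag(0, 2); dimnames(a4) <- list(c("a", "b"), c("a", "b"))
  expect_equal(tom_similarity(a4)["a", "b"], 0)
  # complete unit-weight K_n: every off-diagonal TOM equals 1
  for (n in c(4, 7)) {
    kn <- matrix(1, n, n) - diag(n)
    dimnames(kn) <- list(paste0("v", 1:n), paste0("v", 1:n))
    tk <- tom_similarity(kn)
    expect_equal(tk[upper.tri(tk)], rep(1, choose(n, 2)))
  }
  # naive triple-loop oracle on random weighted graphs
  set.seed(42)
  for (i in 1:20) {
    a <- random_adjacency(sample(5:20, 1), p_edge = runif(1, 0.2, 0.8))
    tom <- tom_similarity(a)
    expect_lt(max(abs(tom - naive_tom(a))), 1e-10)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("TOM distance is the off-diagonal complement", {
  set.seed(1)
  a <- random_adjacency(8)
  d <- tom_distance(tom_similarity(a))
  expect_equal(diag(d), setNames(rep(0, 8), rownames(a)))
  expect_true(all(d >= -1e-12 & d <= 1))
  expect_equal(d, t(d))
})

test_that("all-pairs shortest paths match a Floyd-Warshall oracle", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    a <- random_adjacency(n, p_edge = runif(1, 0.3, 0.9))
    d <- tom_distance(tom_similarity(a))
    sp <- all_shortest_paths_matrix(d, mode = "complete")
    expect_lt(max(abs(sp - floyd_warshall(d))), 1e-12)
    expect_true(all(sp <= 1 + 1e-12))        # direct step always available
    expect_equal(sp, t(sp))
  }
  # two-hop relaxation beats the direct edge
  d3 <- matrix(c(0, .3, .9, .3, 0, .3, .9, .3, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(all_shortest_paths_matrix(d3)["A", "C"], 0.6)
  # two-node case
  d2 <- matrix(c(0, .3, .3, 0), 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  expect_equal(all_shortest_paths_matrix(d2)["A", "B"], 0.3)
  expect_error(all_shortest_paths_matrix(-d2), "negative")
})

test_that("edges_only mode restricts traversal to PPI edges", {
  # path A-B-C; A-C absent from the graph
  edges <- data.frame(node1 = c("A", "B"), node2 = c("B", "C"),
                      weight = c(0.5, 0.5))
  g <- build_graph(edges)
  tom <- tom_similarity(g)
  d <- tom_distance(tom)
  sp_e <- all_shortest_paths_matrix(d, mode = "edges_only", graph = g)
  expect_equal(sp_e["A", "C"], d["A", "B"] + d["B", "C"])
  sp_c <- all_shortest_paths_matrix(d, mode = "complete")
  expect_lte(sp_c["A", "C"], min(d["A", "C"], sp_e["A", "C"]) + 1e-12)
})

test_that("Dj reproduces hand-worked cases and the direct formula", {
  # unit-weight 4-cycle, core {A, C}: B equidistant -> Dj = 0
  sp4 <- rbind(c(0, 1, 2, 1), c(1, 0, 1, 2), c(2, 1, 0, 1), c(1, 2, 1, 0))
  dimnames(sp4) <- list(LETTERS[1:4], LETTERS[1:4])
  dj4 <- dj_scores(sp4, c("A", "C"))
  expect_equal(dj4$Dj[dj4$node == "B"], 0)
  # 3-node path A-j-B with unit distances, core {A}: Dj(j) = -0.75
  sp3 <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  dimnames(sp3) <- list(c("A", "j", "B"), c("A", "j", "B"))
  dj3 <- dj_scores(sp3, "A")
  expect_equal(dj3$Dj[dj3$node == "j"], -0.75)
  # brute-force formula evaluation on random graphs
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    a <- random_adjacency(n, p_edge = 0.6)
    sp <- all_shortest_paths_matrix(tom_distance(tom_similarity(a)))
    core <- sample(rownames(a), sample(1:(n - 1), 1))
    dj <- dj_scores(sp, core)
    expect_lt(max(abs(dj$Dj - naive_dj(sp, core))), 1e-12)
    # swapping core and non-core flips the numerator sign: check via the
    # reconstructed numerators
    C <- sum(dj$is_core); NC <- n - C
    num1 <- colSums(sp[dj$is_core, , drop = FALSE]) / C
    num2 <- colSums(sp[!dj$is_core, , drop = FALSE]) / NC
    dj_swap <- dj_scores(sp, setdiff(rownames(a), core))
    den <- colSums(sp) / n
    ok <- den > 0
    expect_equal(dj_swap$Dj[ok], unname((num1 - num2) / den)[ok],
                 tolerance = 1e-12)
  }
  expect_error(dj_scores(sp3, character()), "empty")
  expect_error(dj_scores(sp3, c("A", "j", "B")), "proper subset")
})

test_that("core-network extraction keeps cores plus strictly positive Dj", {
  edges <- data.frame(node1 = c("A", "B", "C", "D"),
                      node2 = c("B", "C", "D", "E"),
                      weight = rep(0.8, 4))
  g <- build_graph(edges)
  scores <- structure(
    data.frame(node = c("A", "B", "C", "D", "E"),
               Dj = c(0.5, 0.2, 0, -0.1, -0.5),
               is_core = c(TRUE, FALSE, FALSE, FALSE, FALSE)),
    class = c("core_scores", "data.frame"))
  cn <- extract_core_network(g, scores)
  expect_setequal(igraph::V(cn)$name, c("A", "B"))   # C has Dj exactly 0
  scores$Dj <- c(0.5, -1, -1, -1, -1)
  cn2 <- extract_core_network(g, scores)
  expect_setequal(igraph::V(cn2)$name, "A")          # cores always kept
})

test_that("Dj separates planted module nodes from the background", {
  mod_hits <- numeric(20)
  separated <- 0
  bg_rate <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(seed = 9000 + s, ppi_n_nodes = 60, ppi_core_size = 4,
                      ppi_module_size = 10, ppi_background_p = 0.05)
    ppi <- simulate_ppi(cfg)
    g <- giant_component(build_graph(ppi$edges))
    core <- intersect(ppi$truth$core_nodes, igraph::V(g)$name)
    sp <- all_shortest_paths_matrix(tom_distance(tom_similarity(g)))
    dj <- dj_scores(sp, core)
    pos <- dj$node[dj$Dj > 0]
    module <- intersect(ppi$truth$module_nodes, igraph::V(g)$name)
    bg <- intersect(ppi$truth$background_nodes, igraph::V(g)$name)
    mod_hits[s] <- length(intersect(pos, module))
    bg_rate[s] <- length(intersect(pos, bg)) / max(1, length(bg))
    # module-node scores dominate background scores
    separated <- separated +
      (median(dj$Dj[dj$node %in% module]) > median(dj$Dj[dj$node %in% bg]))
  }
  expect_gte(median(mod_hits), 8)        # of the 10 planted module nodes
  expect_equal(separated, 20)
  # the positive-score rule excludes the majority of background nodes in
  # the typical replicate
  expect_lt(median(bg_rate), 0.5)
})

test_that("network descriptives match enumeration on small graphs", {
  tri <- build_graph(data.frame(node1 = c("A", "B", "C"),
                                node2 = c("B", "C", "A"),
                                weight = rep(0.5, 3)))
  d <- network_descriptives(tri)
  expect_equal(d$transitivity, 1)
  expect_equal(d$density, 1)
  expect_equal(d$diameter, 1)

  path3 <- build_graph(data.frame(node1 = c("A", "B"), node2 = c("B", "C"),
                                  weight = c(0.5, 0.5)))
  dp <- network_descriptives(path3)
  expect_equal(dp$transitivity, 0)
  expect_equal(dp$density, 2 / 3)
  expect_equal(dp$diameter, 2)
  expect_equal(dp$mean_distance, 4 / 3)
  expect_equal(unname(dp$degree[c("A", "B", "C")]), c(1, 2, 1))
  # B lies on the single A-C geodesic: normalized betweenness 1
  expect_equal(unname(dp$betweenness["B"]), 1)

  # degree matches naive enumeration on random graphs
  set.seed(4)
  for (i in 1:10) {
    a <- random_adjacency(sample(4:8, 1), p_edge = 0.5)
    if (!any(a > 0)) next
    g <- build_graph(adjacency_to_edges(a))
    dd <- network_descriptives(g)
    manual_deg <- rowSums(a > 0)[igraph::V(g)$name]
    expect_equal(unname(dd$degree[names(manual_deg)]),
                 unname(manual_deg))
  }
})
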