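test_that("interactome loading filters, dedupes and drops self-loops", {
  df <- data.frame(geneA = c("a", "b", "a", "c", "d"),
                   geneB = c("b", "a", "a", "d", "e"),
                   combined_score = c(0.9, 0.7, 0.99, 0.41, 0.39))
  net <- load_interactome(df, min_confidence = 0.4)
  g <- net$graph
  expect_equal(igraph::ecount(g), 2)  # a-b merged, c-d kept, d-e filtered, a-a dropped
  ab <- igraph::E(g, P = c("a", "b"))
  expect_equal(igraph::edge_attr(g, "score", ab), 0.9)  # max of 0.9/0.7
  expect_equal(net$log$n_self_loops, 1)
  expect_equal(net$log$n_below_confidence, 1)
  expect_equal(net$log$n_duplicates, 1)
  # strict threshold: 0.41 kept, 0.39 and exactly-0.4 dropped
  df2 <- data.frame(geneA = "x", geneB = "y", combined_score = 0.4)
  expect_equal(igraph::ecount(load_interactome(df2)$graph), 0)
  expect_error(load_interactome(data.frame(geneA = "a", geneB = "b",
                                           combined_score = "oops")),
               "line 1")
})

test_that("module construction maps signatures and reports fractions", {
  net <- edge_net(cbind(c("a", "b", "c"), c("b", "c", "a")))  # triangle
  sig <- gene_signature(c("a", "b", "c", "zz"), "up", label = "tri")
  mod <- build_module(sig, net)
  expect_equal(sort(mod$mapped), c("a", "b", "c"))
  expect_equal(mod$unmapped, "zz")
  expect_equal(igraph::ecount(mod$subgraph), 3)
  expect_equal(mod$mapped_fraction, 75)
  expect_warning(build_module(gene_signature("qq", "up"), net), "empty module")
})

test_that("module statistics match hand values on a path graph", {
  net <- edge_net(cbind(c("a", "b"), c("b", "c")))
  st <- module_stats(build_module(c("a", "b", "c"), net))
  expect_equal(st$avg_degree, 4 / 3)
  expect_equal(st$avg_clustering, 0)
  expect_equal(st$nodes$betweenness[st$nodes$gene == "b"], 1)
  expect_equal(st$lcc_nodes, 3)
  # isolated node
  net2 <- edge_net(cbind("a", "b"), all_nodes = c("a", "b", "z"))
  st2 <- module_stats(build_module("z", net2))
  expect_equal(st2$avg_degree, 0)
  expect_equal(st2$avg_clustering, 0)
})

test_that("betweenness and clustering match brute-force oracles on random graphs", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    adj <- matrix(0L, n, n)
    prs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- stats::runif(nrow(prs)) < 0.35
    for (r in which(on)) adj[prs[r, 1], prs[r, 2]] <- adj[prs[r, 2], prs[r, 1]] <- 1L
    nodes <- sprintf("n%02d", 1:n)
    el <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
    if (!nrow(el)) next
    net <- edge_net(cbind(nodes[el[, 1]], nodes[el[, 2]]), all_nodes = nodes)
    st <- module_stats(build_module(nodes, net))
    ord <- match(st$nodes$gene, nodes)
    expect_equal(st$nodes$betweenness, betweenness_oracle(adj)[ord],
                 tolerance = 1e-10)
    # local clustering oracle: fraction of connected neighbour pairs
    cc <- vapply(seq_len(n), function(v) {
      nb <- which(adj[v, ] == 1L)
      if (length(nb) < 2) return(0)
      prs2 <- combn(nb, 2)
      mean(adj[t(prs2)] == 1L)
    }, numeric(1))
    expect_equal(st$nodes$clustering, cc[ord], tolerance = 1e-10)
  }
})

test_that("LCC extraction is deterministic with a lexicographic tie-break", {
  net <- edge_net(cbind(c("a", "e", "c"), c("b", "f", "d")),
                  all_nodes = c("a", "b", "c", "d", "e", "f", "g"))
  mod <- build_module(c("c", "d", "e", "f"), net)   # two 2-node components
  lcc <- largest_connected_component(mod)
  expect_setequal(lcc$mapped, c("c", "d"))
  # clear size ordering
  mod2 <- build_module(c("a", "b", "g"), net)
  expect_setequal(largest_connected_component(mod2)$mapped, c("a", "b"))
  # fully connected module is its own LCC
  tri <- edge_net(cbind(c("a", "b", "c"), c("b", "c", "a")))
  m3 <- build_module(c("a", "b", "c"), tri)
  expect_setequal(largest_connected_component(m3)$mapped, m3$mapped)
})

test_that("edge enrichment flags planted cliques and is null on random sets", {
  # sparse background + planted 8-clique
  nodes <- sprintf("G%05d", 1:300)
  clique <- nodes[1:8]
  net <- simulate_interactome(300, "erdos_renyi", planted_modules = list(clique),
                              boost = 1, p_edge = 0.01, seed = 2)
  mod <- build_module(clique, net)
  enr <- edge_enrichment_test(mod, net, n_iter = 999, seed = 3)
  expect_equal(enr$p, 1 / 1000)     # minimum attainable at n_iter = 999
  expect_gt(enr$z, 3)
  expect_error(edge_enrichment_test(mod, net, n_iter = 50), ">= 100")

  # self-null: modules drawn by the null sampler give centred z
  zs <- vapply(1:30, function(s) {
    set.seed(s)
    vs <- sample(nodes, 8)
    edge_enrichment_test(build_module(vs, net), net, n_iter = 200,
                         seed = s + 100, degree_binned = FALSE)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.5)
})

test_that("degree-binned sampling approximates the module degree profile", {
  net <- simulate_interactome(1500, "powerlaw_cluster", m_attach = 3, seed = 9)
  deg <- igraph::degree(net$graph)
  set.seed(1)
  for (vids in list(sample(1500, 50),                      # typical module
                    order(deg, decreasing = TRUE)[301:350])) { # upper-degree
    mean_deg <- replicate(50, {
      s <- pesignet:::sample_matched_set(net, vids, degree_binned = TRUE,
                                         min_bin_size = 100)
      mean(deg[s])
    })
    expect_equal(mean(mean_deg), mean(deg[vids]), tolerance = 0.1)
  }
})

test_that("module closeness matches hand distances and detects planted proximity", {
  # path graph 1-2-3: d(A={1}, B={3}) = 2
  net <- edge_net(cbind(c("n1", "n2"), c("n2", "n3")),
                  all_nodes = sprintf("n%d", 1:3))
  a <- build_module("n1", net); b <- build_module("n3", net)
  expect_equal(pesignet:::cross_distance(
    net, match("n1", interactome_nodes(net)),
    match("n3", interactome_nodes(net)))$d, 2)
  # identical singleton modules are at distance zero
  v <- match("n1", interactome_nodes(net))
  expect_equal(pesignet:::cross_distance(net, v, v)$d, 0)

  # planted adjacent cliques in a background graph are significantly close
  nodes <- sprintf("G%05d", 1:400)
  m1 <- nodes[1:12]; m2 <- nodes[7:18]          # overlapping planted cliques
  net2 <- simulate_interactome(400, "powerlaw_cluster",
                               planted_modules = list(m1, m2),
                               boost = 0.9, seed = 5)
  z_close <- module_closeness(build_module(m1, net2), build_module(m2, net2),
                              net2, n_iter = 300, seed = 7)
  expect_lt(z_close$z, -1.65)
  expect_true(z_close$significantly_close)

  # random same-size modules are not systematically close
  set.seed(20)
  r1 <- build_module(sample(nodes, 12), net2)
  r2 <- build_module(sample(nodes, 12), net2)
  z_rand <- module_closeness(r1, r2, net2, n_iter = 300, seed = 8)
  expect_gt(z_rand$z, -1.65)
})

test_that("closeness is symmetric in its module arguments", {
  nodes <- sprintf("G%05d", 1:200)
  net <- simulate_interactome(200, "powerlaw_cluster", seed = 3)
  a <- build_module(nodes[1:10], net); b <- build_module(nodes[50:64], net)
  for (conv in c("all_pairs", "closest")) {
    ab <- module_closeness(a, b, net, n_iter = 100, seed = 1, convention = conv)
    ba <- module_closeness(b, a, net, n_iter = 100, seed = 1, convention = conv)
    expect_equal(ab$d_obs, ba$d_obs, tolerance = 1e-12)
  }
})

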