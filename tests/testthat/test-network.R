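test_that("expression restriction keeps nodes above threshold in any condition", {
  el <- edge_list(c("a", "b", "c"), c("b", "c", "d"))
  expr <- data.frame(feature_id = c("a", "b", "c"),
                     control = c(0.4, 0.5, 2.0),
                     treated = c(0.6, 0.5, 1.0))
  expect_warning(out <- restrict_to_expressed(el, expr, threshold = 0.5),
                 "no edges remain")
  nodes <- attr(out, "nodes")
  expect_true("a" %in% nodes)     # 0.6 in one condition
  expect_false("b" %in% nodes)    # exactly 0.5 in both: strict
  expect_false("d" %in% nodes)    # absent from the table
  expect_equal(attr(out, "n_dropped"), 2L)
})

test_that("connector enrichment reproduces exact tails and admission rules", {
  # star node v with 6 edges, all into a 10-node module, on 100 nodes total
  module <- sprintf("m%02d", 1:10)
  others <- sprintf("o%02d", 1:89)
  from <- c(rep("v", 6), others[1:60])
  to <- c(module[1:6], rep(module[1], 30), rep(others[80], 30))
  el <- edge_list(from, to)
  # ensure all 100 nodes exist in the graph
  missing <- setdiff(c(module, others, "v"), edge_list_nodes(el))
  el2 <- edge_list(c(el$from, missing), c(el$to, rep(module[2], length(missing))))
  expect_equal(length(edge_list_nodes(el2)), 100L)
  res <- connector_enrichment(el2, module, min_connections = 5,
                              fdr_threshold = 0.01)
  v_row <- res[res$node == "v", ]
  want <- sum(sapply(6:6, function(j)
    choose(10, j) * choose(89, 6 - j))) / choose(99, 6)
  expect_equal(v_row$p, want, tolerance = 1e-10)
  expect_lt(v_row$p, 1e-6)
  expect_true(v_row$admitted)

  # zero neighbours in the module: p = 1, not admitted
  iso <- res[res$node == "o80", ]
  expect_equal(iso$k_to_module, 0L)
  expect_equal(iso$p, 1)
  expect_false(iso$admitted)

  # count gate: k = 4 with tiny p still rejected at min 5
  from4 <- c(rep("w", 4), el2$from)
  to4 <- c(module[1:4], el2$to)
  el3 <- edge_list(from4, to4)
  res4 <- connector_enrichment(el3, module, min_connections = 5,
                               fdr_threshold = 0.5)
  w_row <- res4[res4$node == "w", ]
  expect_equal(w_row$k_to_module, 4L)
  expect_false(w_row$admitted)

  expect_error(connector_enrichment(edge_list("a", "b"),
                                    c("a", "b", "c")), "larger")
})

test_that("directed networks use out-degree for regulator enrichment", {
  module <- c("t1", "t2", "t3", "t4")
  el <- edge_list(c(rep("tf", 4), "t1", "x"), c(module, "tf", "t9"),
                  directed = TRUE)
  res <- connector_enrichment(el, module, min_connections = 4,
                              fdr_threshold = 0.05)
  tf <- res[res$node == "tf", ]
  expect_equal(tf$degree, 4L)         # out-degree only
  expect_equal(tf$k_to_module, 4L)
})

test_that("module networks contain members plus admitted connectors only", {
  mod <- sprintf("n%04d", 1:20)
  sim <- simulate_background_network(300, 0.01, mod, connectors = 3,
                                     k_connector = 8, seed = 5)
  conn <- connector_enrichment(sim$edges, mod, 5, 0.01)
  sub <- build_module_network(sim$edges, mod, conn)
  expect_setequal(setdiff(sub$nodes$node, mod), sim$truth$connectors)
  expect_true(all(sub$nodes$role[sub$nodes$node %in% sim$truth$connectors] ==
                    "connector"))
  # every admitted connector keeps its in-module edges in the subgraph
  g <- as_igraph(sub$edges)
  for (cid in sim$truth$connectors)
    expect_gte(sum(igraph::neighbors(g, cid)$name %in% mod), 5)
  # with no admitted connectors the subgraph is the module itself
  none <- conn; none$admitted <- FALSE
  sub0 <- build_module_network(sim$edges, mod, none)
  expect_true(all(sub0$nodes$node %in% mod))
})

test_that("clique agglomeration yields overlapping communities cut by EQ", {
  clique_edges <- function(ids) {
    pairs <- t(combn(ids, 2))
    list(from = pairs[, 1], to = pairs[, 2])
  }
  # two 7-cliques sharing one node
  e1 <- clique_edges(paste0("a", 1:7))
  e2 <- clique_edges(c("a1", paste0("b", 1:6)))
  el <- edge_list(c(e1$from, e2$from), c(e1$to, e2$to))
  cs <- detect_communities(el, clique_size = 6, complex_size = 2)
  expect_length(cs$communities, 2L)
  sizes <- sort(lengths(cs$communities))
  expect_equal(sizes, c(7L, 7L))
  expect_true(all(vapply(cs$communities, function(C) "a1" %in% C, TRUE)))
  # the chosen cut maximises extended modularity vs the merged alternative
  eq_two <- brute_force_eq(el, cs$communities)
  eq_one <- brute_force_eq(el, list(unique(c(e1$from, e1$to, e2$from, e2$to))))
  expect_equal(cs$eq, eq_two, tolerance = 1e-12)
  expect_gte(eq_two, eq_one)

  # a single 6-clique is one community
  e3 <- clique_edges(paste0("c", 1:6))
  cs2 <- detect_communities(edge_list(e3$from, e3$to), 6, 2)
  expect_length(cs2$communities, 1L)
  expect_setequal(cs2$communities[[1]], paste0("c", 1:6))

  # a ring has no clique of size 6
  ring <- edge_list(paste0("r", 1:8), paste0("r", c(2:8, 1)))
  expect_warning(cs3 <- detect_communities(ring, 6, 2), "no maximal clique")
  expect_length(cs3$communities, 0L)

  # subordinate node attaches to the community it shares most edges with
  e4 <- clique_edges(paste0("a", 1:7))
  sub_edges <- list(from = c("s", "s"), to = c("a1", "a2"))
  el4 <- edge_list(c(e4$from, sub_edges$from), c(e4$to, sub_edges$to))
  cs4 <- detect_communities(el4, 6, 2)
  expect_true(any(vapply(cs4$communities, function(C) "s" %in% C, TRUE)))
})

test_that("planted connectors are recovered with no false admissions", {
  mod <- sprintf("n%04d", 1:20)
  ok <- sapply(1:15, function(seed) {
    sim <- simulate_background_network(500, 0.01, mod, connectors = 3,
                                       k_connector = 8, seed = seed)
    res <- connector_enrichment(sim$edges, mod, 5, 0.01)
    adm <- res$node[res$admitted]
    setequal(adm, sim$truth$connectors)
  })
  expect_gte(mean(ok), 0.9)
})
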