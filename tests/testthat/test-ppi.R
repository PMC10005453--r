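# PPI graph construction, centralities and key-target selection.

test_that("build_ppi_graph collapses orientations, drops loops, filters score", {
  g <- build_ppi_graph(data.frame(protein1 = c("A", "B"), protein2 = c("B", "A"),
                                  combined_score = c(0.9, 0.8)))
  expect_identical(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$score, 0.9)

  g2 <- build_ppi_graph(data.frame(protein1 = "A", protein2 = "A",
                                   combined_score = 0.99))
  expect_identical(igraph::ecount(g2), 0)

  withr::with_seed(14, {
    syms <- sprintf("P%02d", 1:40)
    df <- data.frame(protein1 = sample(syms, 500, TRUE),
                     protein2 = sample(syms, 500, TRUE),
                     combined_score = runif(500))
    g3 <- build_ppi_graph(df, min_score = 0.7)
    # oracle: direct scan after canonicalizing pairs
    keep <- df[df$protein1 != df$protein2, ]
    key <- paste(pmin(keep$protein1, keep$protein2),
                 pmax(keep$protein1, keep$protein2))
    best <- tapply(keep$combined_score, key, max)
    expect_equal(igraph::ecount(g3), sum(best >= 0.7))
  })
})

test_that("STRING 0-1000 score dialect is auto-detected", {
  g <- build_ppi_graph(data.frame(protein1 = c("A", "B"), protein2 = c("B", "C"),
                                  combined_score = c(900, 400)))
  expect_identical(igraph::ecount(g), 1)
  expect_error(
    build_ppi_graph(data.frame(protein1 = c("A", ""), protein2 = c("B", "C"),
                               combined_score = c(0.9, 0.9))),
    class = "herbnet_parse_error")
})

test_that("centralities match hand-derived values on canonical graphs", {
  # star K1,4: all paths pass the hub, all distances 1
  star <- build_ppi_graph(data.frame(protein1 = "HUB",
                                     protein2 = c("A", "B", "C", "D"),
                                     combined_score = 1))
  cs <- ppi_centralities(star)
  hub <- cs[cs$gene_symbol == "HUB", ]
  expect_identical(hub$degree, 4L)
  expect_equal(hub$betweenness, 1)
  expect_equal(hub$closeness, 1)
  leaf <- cs[cs$gene_symbol == "A", ]
  expect_equal(leaf$betweenness, 0)

  # path a-b-c-d: node b carries (a,c) and (a,d) of the 3 non-incident pairs
  path <- build_ppi_graph(data.frame(protein1 = c("A", "B", "C"),
                                     protein2 = c("B", "C", "D"),
                                     combined_score = 1))
  cp <- ppi_centralities(path)
  expect_equal(cp$betweenness[cp$gene_symbol == "B"], 2 / 3)
})

test_that("centralities agree with the brute-force oracle on small graphs", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      n <- sample(3:8, 1)
      edges <- random_graph_edges(n, p = runif(1, 0.2, 0.8))
      if (nrow(edges) == 0) next
      df <- data.frame(protein1 = sprintf("N%d", edges[, 1]),
                       protein2 = sprintf("N%d", edges[, 2]),
                       combined_score = 1)
      g <- build_ppi_graph(df, min_score = 0)
      got <- ppi_centralities(g)
      want <- oracle_for_edges(edges)
      merged <- merge(got, want, by = "gene_symbol")
      expect_identical(nrow(merged), nrow(got))
      expect_equal(merged$degree.x, merged$degree.y)
      expect_equal(merged$betweenness.x, merged$betweenness.y, tolerance = 1e-12)
      expect_equal(merged$closeness.x, merged$closeness.y, tolerance = 1e-12)
    }
  })
})

test_that("key-target thresholds are inclusive conjunctions", {
  recs <- data.frame(
    gene_symbol = c("ON_BOUNDARY", "HIGH_BC_LOW_DEG"),
    degree = c(10L, 9L),
    betweenness = c(0.001, 0.9),
    closeness = c(0.430, 0.9))
  expect_identical(select_key_targets(recs), "ON_BOUNDARY")

  withr::with_seed(9, {
    n <- 200
    recs <- data.frame(gene_symbol = sprintf("T%03d", 1:n),
                       degree = sample(0:40, n, TRUE),
                       betweenness = runif(n, 0, 0.01),
                       closeness = runif(n, 0, 1))
    got <- select_key_targets(recs)
    want <- recs$gene_symbol[recs$degree >= 10 & recs$betweenness >= 0.001 &
                               recs$closeness >= 0.430]
    expect_setequal(got, want)
    # descending-degree order
    expect_identical(got, got[order(-recs$degree[match(got, recs$gene_symbol)],
                                    got)])
  })
})

test_that("induced subgraphs keep only internal edges and shrink degrees", {
  tri <- build_ppi_graph(data.frame(protein1 = c("A", "B", "C"),
                                    protein2 = c("B", "C", "A"),
                                    combined_score = 1))
  all_nodes <- igraph::V(tri)$name
  same <- induced_subgraph_recompute(tri, all_nodes)
  expect_identical(igraph::ecount(same$graph), igraph::ecount(tri))
  expect_equal(ppi_centralities(tri), same$centralities)

  two <- induced_subgraph_recompute(tri, c("A", "B"))
  expect_identical(igraph::ecount(two$graph), 1)

  expect_error(induced_subgraph_recompute(tri, c("A", "Z")),
               class = "herbnet_input_error")
})

test_that("subgraph degrees never exceed parent degrees", {
  withr::with_seed(18, {
    edges <- random_graph_edges(12, 0.4)
    df <- data.frame(protein1 = sprintf("N%d", edges[, 1]),
                     protein2 = sprintf("N%d", edges[, 2]), combined_score = 1)
    g <- build_ppi_graph(df, min_score = 0)
    keep <- sample(igraph::V(g)$name, 6)
    sub <- induced_subgraph_recompute(g, keep)
    full <- ppi_centralities(g)
    for (s in sub$centralities$gene_symbol) {
      expect_lte(sub$centralities$degree[sub$centralities$gene_symbol == s],
                 full$degree[full$gene_symbol == s])
    }
    # two non-adjacent survivors are isolated: closeness 0 by convention
    pair <- induced_subgraph_recompute(g, igraph::V(g)$name[1])
    expect_equal(pair$centralities$closeness, 0)
  })
})

test_that("edge counts follow the handshake lemma", {
  expect_identical(edge_count_from_degrees(c(1, 1)), 1)
  expect_identical(edge_count_from_degrees(c(2, 2, 2)), 3)
  expect_error(edge_count_from_degrees(c(1, 2)),
               class = "herbnet_consistency_error")
  expect_error(edge_count_from_degrees(c(-1, 1)),
               class = "herbnet_input_error")
})
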