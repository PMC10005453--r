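# Integrated herb-compound-target-pathway network construction and ranking.

# deterministic fixture with the requested class sizes; every node appears
make_hctp_fixture <- function(n_h, n_c, n_t, n_p) {
  herbs <- sprintf("H%02d", seq_len(n_h))
  cpds <- sprintf("C%03d", seq_len(n_c))
  tgts <- sprintf("T%02d", seq_len(n_t))
  paths <- sprintf("P%02d", seq_len(n_p))
  hc <- data.frame(herb = herbs[(seq_len(n_c) - 1) %% n_h + 1], compound = cpds)
  ct <- data.frame(compound = cpds[(seq_len(max(n_c, n_t)) - 1) %% n_c + 1],
                   target = tgts[(seq_len(max(n_c, n_t)) - 1) %% n_t + 1])
  tp <- data.frame(target = tgts[(seq_len(max(n_t, n_p)) - 1) %% n_t + 1],
                   pathway = paths[(seq_len(max(n_t, n_p)) - 1) %% n_p + 1])
  build_hctp(hc, ct, tp)
}

test_that("node accounting sums the four class counts", {
  net <- make_hctp_fixture(9, 94, 42, 20)
  expect_identical(igraph::vcount(net), 9 + 94 + 42 + 20)
  cls <- table(igraph::V(net)$node_class)
  expect_identical(as.integer(cls[c("herb", "compound", "target", "pathway")]),
                   c(9L, 94L, 42L, 20L))
  # handshake lemma on the multipartite edge set
  expect_identical(sum(igraph::degree(net)), 2 * igraph::ecount(net))
})

test_that("empty inputs give an empty network", {
  net <- build_hctp(data.frame(herb = character(), compound = character()),
                    data.frame(compound = character(), target = character()),
                    data.frame(target = character(), pathway = character()))
  expect_identical(igraph::vcount(net), 0)
})

test_that("node and edge counts match a brute-force union/dedup oracle", {
  withr::with_seed(26, {
    hc <- data.frame(herb = sample(sprintf("H%d", 1:4), 30, TRUE),
                     compound = sample(sprintf("C%d", 1:10), 30, TRUE))
    ct <- data.frame(compound = sample(sprintf("C%d", 1:10), 40, TRUE),
                     target = sample(sprintf("T%d", 1:8), 40, TRUE))
    tp <- data.frame(target = sample(sprintf("T%d", 1:8), 20, TRUE),
                     pathway = sample(sprintf("P%d", 1:5), 20, TRUE))
    net <- build_hctp(hc, ct, tp)
    nodes <- unique(c(hc$herb, hc$compound, ct$compound, ct$target,
                      tp$target, tp$pathway))
    edges <- unique(rbind(setNames(hc, c("a", "b")), setNames(ct, c("a", "b")),
                          setNames(tp, c("a", "b"))))
    expect_equal(igraph::vcount(net), length(nodes))
    expect_equal(igraph::ecount(net), nrow(edges))
  })
})

test_that("an id cannot belong to two classes", {
  expect_error(
    build_hctp(data.frame(herb = "X", compound = "C1"),
               data.frame(compound = "C1", target = "X"),
               data.frame(target = "X", pathway = "P1")),
    class = "herbnet_structural_error")
  expect_error(
    build_hctp(data.frame(herb = "A", compound = "A"),
               data.frame(compound = character(), target = character()),
               data.frame(target = character(), pathway = character())),
    class = "herbnet_structural_error")
})

test_that("degree ranking aggregates both edge types and finds the max tie", {
  hc <- data.frame(herb = "H1", compound = c("CPD_A", "CPD_B"))
  ct <- data.frame(compound = c(rep("CPD_A", 13), "CPD_B"),
                   target = c(sprintf("T%02d", 1:13), "T01"))
  tp <- data.frame(target = "T01", pathway = "P1")
  net <- build_hctp(hc, ct, tp)
  rk <- rank_by_degree(net, "compound")
  expect_identical(rk$degree[rk$id == "CPD_A"], 14L)
  expect_identical(rk$id[rk$is_key], "CPD_A")

  # top-k variant and other classes
  rk2 <- rank_by_degree(net, "compound", top = 2)
  expect_identical(sum(rk2$is_key), 2L)
  rkp <- rank_by_degree(net, "pathway")
  expect_identical(rkp$id, "P1")
  expect_true(rkp$is_key)
  expect_error(rank_by_degree(net, "metabolite"),
               class = "herbnet_parameter_error")
})

test_that("ranking is invariant under node relabeling", {
  withr::with_seed(27, {
    hc <- data.frame(herb = sample(sprintf("H%d", 1:3), 10, TRUE),
                     compound = sample(sprintf("C%d", 1:6), 10, TRUE))
    ct <- data.frame(compound = sample(sprintf("C%d", 1:6), 25, TRUE),
                     target = sample(sprintf("T%d", 1:9), 25, TRUE))
    tp <- data.frame(target = sample(sprintf("T%d", 1:9), 12, TRUE),
                     pathway = sample(sprintf("P%d", 1:4), 12, TRUE))
    rk <- rank_by_degree(build_hctp(hc, ct, tp), "compound")
    relabel <- function(x) sub("^C", "CC", x)
    rk2 <- rank_by_degree(
      build_hctp(transform(hc, compound = relabel(compound)),
                 transform(ct, compound = relabel(compound)), tp),
      "compound")
    expect_identical(relabel(rk$id), rk2$id)
    expect_identical(rk$degree, rk2$degree)
  })
})

test_that("a hub pathway wired to most targets ranks first in its class", {
  # analog of a dominant signaling pathway: one pathway linked to nearly all
  # targets, the rest sparsely wired
  tgts <- sprintf("T%02d", 1:20)
  tp <- rbind(data.frame(target = tgts[1:18], pathway = "HUB_PATH"),
              data.frame(target = tgts[1:2], pathway = "P2"),
              data.frame(target = tgts[3], pathway = "P3"))
  net <- build_hctp(data.frame(herb = "H1", compound = "C1"),
                    data.frame(compound = "C1", target = tgts),
                    tp)
  rkp <- rank_by_degree(net, "pathway")
  expect_identical(rkp$id[rkp$is_key], "HUB_PATH")
  expect_identical(rkp$degree[1], 18L)
})
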