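test_that("corpus generation is deterministic and structurally sound", {
  cfg <- benchmark_config(n_background_nodes = 100, n_pathways = 5, seed = 13)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$network$edges, c2$network$edges)
  expect_identical(lapply(c1$pathways, `[[`, "truth_edges"),
                   lapply(c2$pathways, `[[`, "truth_edges"))
  for (pw in c1$pathways) {
    expect_gt(length(pw$anchors), 0)
    expect_gt(length(pw$terminals), 0)
    expect_length(intersect(pw$anchors, pw$terminals), 0)
    # planted subgraph is connected after undirected conversion
    g <- igraph::graph_from_data_frame(pw$truth_edges, directed = FALSE,
                                       vertices = data.frame(
                                         name = pw$truth_nodes))
    expect_equal(igraph::components(g)$no, 1)
    # planted edges present in the background network with high confidence
    keys <- paste(c1$network$edges$u, c1$network$edges$v)
    expect_true(all(paste(pw$truth_edges$u, pw$truth_edges$v) %in% keys))
  }
  # pathway larger than background is rejected
  expect_error(benchmark_config(n_background_nodes = 10,
                                pathway_size_range = c(11, 12)),
               "larger than background")
})

test_that("anchors and terminals come from the planted DAG degree rule", {
  corpus <- generate_corpus(benchmark_config(n_background_nodes = 80,
                                             n_pathways = 4, seed = 3))
  for (pw in corpus$pathways) {
    de <- pw$graph$directed_edges
    expect_true(all(!pw$anchors %in% de$to))       # no inward edges
    expect_true(all(!pw$terminals %in% de$from))   # no outward edges
    expect_true(all(c(pw$anchors, pw$terminals) %in% pw$truth_nodes))
  }
})

test_that("reconstruction recovers planted pathways in the noise-free limit", {
  cfg <- benchmark_config(n_background_nodes = 60, background_edge_prob = 1e-4,
                          n_pathways = 2, pathway_size_range = c(6, 8),
                          decoy_edge_factor = 0, seed = 21)
  corpus <- generate_corpus(cfg)
  for (pw in corpus$pathways) {
    q <- query_instance(corpus$network, pw$anchors, pw$terminals,
                        alpha = 0.5, margin = 1)
    H <- reconstruct(q)
    rec <- score_recovery(H$nodes, pw)
    # with no decoys and an empty background, every recovered
    # intermediate node is a true pathway node
    inter <- setdiff(H$nodes, c(pw$anchors, pw$terminals))
    if (length(inter) > 0) expect_equal(unname(rec[["precision"]]), 1)
    expect_true(all(H$nodes %in% pw$truth_nodes))
  }
})

test_that("the benchmark carries recovery signal over a random baseline", {
  set.seed(1)
  f1_run <- c(); f1_rand <- c()
  for (s in 1:5) {
    corpus <- generate_corpus(benchmark_config(
      n_background_nodes = 120, n_pathways = 4, seed = s))
    for (pw in corpus$pathways) {
      q <- query_instance(corpus$network, pw$anchors, pw$terminals,
                          alpha = 0.25, margin = 1)
      H <- reconstruct(q)
      f1_run <- c(f1_run, score_recovery(H$nodes, pw)[["f1"]])
      rand_nodes <- sample(corpus$network$nodes, length(H$nodes))
      f1_rand <- c(f1_rand, score_recovery(rand_nodes, pw)[["f1"]])
    }
  }
  expect_gte(mean(f1_run) - mean(f1_rand), 0.2)
})

test_that("recovery scoring has the expected closed forms", {
  truth <- list(truth_nodes = c("a", "t", "m1", "m2", "m3", "m4"),
                anchors = "a", terminals = "t")
  expect_equal(score_recovery(c("m1", "m2", "m3", "m4"), truth),
               c(precision = 1, recall = 1, f1 = 1))
  expect_equal(score_recovery(c("z1", "z2"), truth),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(score_recovery(c("m1", "m2"), truth),
               c(precision = 1, recall = 0.5, f1 = 2 / 3))
  # anchors/terminals excluded from both sides
  expect_equal(score_recovery(c("a", "t", "m1", "m2"), truth)[["recall"]],
               0.5)
  # scored input honours the threshold
  scored <- data.frame(node = c("m1", "m2"), score = c(0.9, 0.1))
  expect_equal(score_recovery(scored, truth, threshold = 0.5)[["recall"]],
               0.25)
  # empty truth after exclusion is flagged NaN
  empty <- list(truth_nodes = c("a", "t"), anchors = "a", terminals = "t")
  expect_warning(r <- score_recovery("m1", empty), "empty")
  expect_true(all(is.nan(r)))
})
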