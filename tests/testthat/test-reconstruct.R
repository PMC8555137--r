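test_that("the objective matches hand-computed values at the alpha endpoints", {
  # single anchor-terminal edge of length 1 at alpha = 0.25:
  # f = 0.5 * 1 + 0.5 * 1 = 1
  net <- interaction_network(data.frame(u = "a", v = "t",
                                        confidence = exp(-1)))
  q <- query_instance(net, "a", "t", alpha = 0.25)
  H <- manual_subnetwork("a", "t", exp(-1))
  expect_equal(objective(H, q), 1.0)

  # star with two unit leaves, alpha = 0: local term only -> 2
  star <- interaction_network(data.frame(
    u = c("a", "a"), v = c("t1", "t2"), confidence = exp(-1)))
  q0 <- query_instance(star, "a", c("t1", "t2"), alpha = 0)
  H0 <- manual_subnetwork(c("a", "a"), c("t1", "t2"), exp(-1))
  expect_equal(objective(H0, q0), 2)

  # triangle, H = {a-t1, a-t2}, alpha = 0.5: global term only -> 2
  tri <- interaction_network(data.frame(
    u = c("a", "a", "t1"), v = c("t1", "t2", "t2"), confidence = exp(-1)))
  q5 <- query_instance(tri, "a", c("t1", "t2"), alpha = 0.5)
  expect_equal(objective(H0, q5), 2)

  # disconnected terminal errors
  expect_error(objective(manual_subnetwork("a", "t1", exp(-1)), q5),
               "disconnected")
})

test_that("the worked 4-node instance selects the alpha-dependent tree", {
  net <- star_vs_direct_network()
  # alpha = 0.5: Steiner tree through x, objective 2*0.5*3 = 3
  q5 <- query_instance(net, "a", c("t1", "t2"), alpha = 0.5)
  expect_equal(reconstruct(q5)$objective, 3, tolerance = 1e-12)
  expect_equal(brute_force_optimum(q5)$objective, 3, tolerance = 1e-12)
  # alpha = 0: union of direct shortest paths (1.5 each), objective 3.0
  q0 <- query_instance(net, "a", c("t1", "t2"), alpha = 0)
  H0 <- reconstruct(q0)
  expect_equal(H0$objective, 3.0, tolerance = 1e-12)
  expect_setequal(paste(H0$edges$u, H0$edges$v), c("a t1", "a t2"))
  expect_equal(unname(H0$terminal_distances), c(1.5, 1.5))
  # alpha = 0.25: enumerate both candidate trees by hand
  q25 <- query_instance(net, "a", c("t1", "t2"), alpha = 0.25)
  cand_star <- 0.5 * (2 + 2) + 0.5 * 3       # via x: distances 2, edges 3
  cand_direct <- 0.5 * 3 + 0.5 * 3           # direct: distances 1.5, edges 3
  expect_equal(reconstruct(q25)$objective, min(cand_star, cand_direct))
})

test_that("single anchor-terminal queries return the most reliable path", {
  net <- interaction_network(data.frame(
    u = c("a", "x", "a"), v = c("x", "t", "t"),
    confidence = c(0.9, 0.9, 0.5)))
  for (al in c(0, 0.25, 0.5)) {
    H <- reconstruct(query_instance(net, "a", "t", alpha = al))
    # via x: length 2*(-log .9) = 0.21 < -log .5 = 0.69
    expect_setequal(paste(H$edges$u, H$edges$v), c("a x", "t x"))
  }
})

test_that("reconstruct matches the exhaustive oracle on random instances", {
  set.seed(101)
  checked <- 0
  while (checked < 60) {
    net <- random_network(sample(5:12, 1))
    q <- random_query(net)
    if (is.null(q)) next
    checked <- checked + 1
    expect_equal(reconstruct(q)$objective, brute_force_optimum(q)$objective,
                 tolerance = 1e-9)
  }
})

test_that("alpha endpoints behave as pure local / pure global criteria", {
  set.seed(202)
  checked <- 0
  while (checked < 20) {
    net <- random_network(sample(6:12, 1))
    q0 <- random_query(net, alpha = 0)
    if (is.null(q0)) next
    checked <- checked + 1
    H0 <- reconstruct(q0)
    # every terminal's in-solution distance equals its network shortest
    # distance to the anchor set (independent check via igraph)
    g <- igraph::graph_from_data_frame(net$edges[, c("u", "v")],
                                       directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    d <- igraph::distances(g, v = q0$anchors, to = q0$terminals,
                           weights = -log(net$edges$confidence))
    expect_equal(unname(H0$terminal_distances),
                 unname(apply(d, 2, min)[q0$terminals]),
                 tolerance = 1e-9)
    # alpha = 0.5 equals the oracle Steiner optimum on the same query
    q5 <- query_instance(net, q0$anchors, q0$terminals, alpha = 0.5)
    expect_equal(reconstruct(q5)$objective, brute_force_optimum(q5)$objective,
                 tolerance = 1e-9)
  }
})

test_that("stored objectives are recomputable from the edge set", {
  set.seed(303)
  for (i in 1:10) {
    net <- random_network(sample(6:12, 1))
    q <- random_query(net)
    if (is.null(q)) next
    H <- reconstruct(q)
    expect_equal(H$objective, objective(H, q), tolerance = 1e-9)
  }
})

test_that("unreachable terminals are reported by name", {
  net <- interaction_network(data.frame(
    u = c("a", "x"), v = c("b", "y"), confidence = 0.9))
  expect_error(query_instance(net, "a", "y"), "unreachable.*y")
})

test_that("the oracle refuses large instances", {
  net <- random_network(15, p = 0.4)
  q <- random_query(net)
  skip_if(is.null(q))
  expect_error(brute_force_optimum(q), "12 nodes")
})

test_that("the heuristic fallback stays feasible on many-terminal instances", {
  set.seed(77)
  net <- random_network(40, p = 0.12, conf_range = c(0.3, 0.95))
  q <- random_query(net, n_anchors = 2, n_terminals = 10, alpha = 0.25,
                    tries = 50)
  skip_if(is.null(q))
  H <- reconstruct(q, exact_terminals = 4L)   # force the heuristic path
  expect_true(all(q$terminals %in% H$nodes))
  expect_equal(H$objective, objective(H, q), tolerance = 1e-9)
  # never better than the exact solver on the same instance
  expect_gte(H$objective, reconstruct(q)$objective - 1e-9)
})
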