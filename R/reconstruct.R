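# Anchored subnetwork reconstruction.
#
# A query connects every terminal to an anchor set through the weighted
# interaction network, minimizing
#   f_alpha(H) = (1 - 2*alpha) * sum_t d_H(A, t) + 2*alpha * sum_e len(e)
# over tree-shaped subnetworks H (trees after adding a virtual root joined
# to all anchors by zero-length edges). alpha = 0 is the pure local
# criterion (shortest anchor->terminal paths), alpha = 0.5 the pure global
# criterion (minimum total subnetwork weight, a Steiner tree), alpha = 0.25
# balances both. Edge lengths are -log(confidence).
#
# In a rooted tree, sum_t d_H(root, t) = sum_e len(e) * (#terminals below e),
# so f_alpha decomposes per edge as len * (2*alpha + (1-2*alpha)*k) with k
# the number of terminals routed through the edge. That makes a
# Dreyfus-Wagner-style dynamic program over (node, terminal subset) exact
# for tree solutions; it is used whenever the terminal set is small. An
# independent exhaustive branch-and-bound (C++) serves as oracle and as the
# exact ensemble enumerator on small instances.

#' Define an anchored reconstruction query
#'
#' @param network an [interaction_network()].
#' @param anchors,terminals non-empty disjoint character vectors of node
#'   identifiers present in the network; every terminal must be reachable
#'   from some anchor.
#' @param alpha trade-off in `[0, 0.5]` between the local criterion (short
#'   anchor-to-terminal paths, alpha near 0) and the global criterion (low
#'   total subnetwork weight, alpha near 0.5).
#' @param margin multiplicative slack (>= 1) over the optimal objective for
#'   ensemble membership; 1.2 admits solutions within 20% of the optimum.
#' @return object of class `query_instance`.
#' @export
query_instance <- function(network, anchors, terminals, alpha = 0.25,
                           margin = 1) {
  stopifnot(inherits(network, "interaction_network"))
  anchors <- unique(as.character(anchors))
  terminals <- unique(as.character(terminals))
  if (length(anchors) == 0 || length(terminals) == 0)
    stop("anchors and terminals must be non-empty")
  miss <- setdiff(c(anchors, terminals), network$nodes)
  if (length(miss))
    stop("node(s) absent from network: ", paste(miss, collapse = ", "))
  if (length(intersect(anchors, terminals)))
    stop("anchors and terminals must be disjoint")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 0.5)
    stop("alpha must lie in [0, 0.5]")
  if (!is.numeric(margin) || margin < 1)
    stop("margin must be >= 1")
  g <- as_igraph(network)
  d <- igraph::distances(g, v = anchors, to = terminals)
  unreach <- terminals[apply(d, 2, min) == Inf]
  if (length(unreach))
    stop("terminal(s) unreachable from the anchor set: ",
         paste(unreach, collapse = ", "))
  structure(list(network = network, anchors = anchors,
                 terminals = terminals, alpha = alpha, margin = margin),
            class = "query_instance")
}

#' @export
print.query_instance <- function(x, ...) {
  cat("Anchored query:", length(x$anchors), "anchor(s),",
      length(x$terminals), "terminal(s), alpha =", x$alpha,
      ", margin =", x$margin, "\n")
  invisible(x)
}

# indexed rooted graph: nodes 1..n are network nodes, n+1 is the virtual
# root, joined to each anchor by a zero-length edge
index_graph <- function(q, lengths = NULL) {
  nodes <- q$network$nodes
  n <- length(nodes)
  e <- q$network$edges
  len <- if (is.null(lengths)) edge_length(e$confidence) else lengths
  stopifnot(length(len) == nrow(e))
  ui <- match(e$u, nodes); vi <- match(e$v, nodes)
  ai <- match(q$anchors, nodes)
  root <- n + 1L
  und_from <- c(ui, rep(root, length(ai)))
  und_to <- c(vi, ai)
  und_len <- c(len, rep(0, length(ai)))
  m <- length(und_from)
  list(nodes = nodes, n = n, root = root,
       und_from = und_from, und_to = und_to, und_len = und_len,
       n_net_edges = nrow(e),
       from = c(und_from, und_to), to = c(und_to, und_from),
       dlen = c(und_len, und_len), eid = c(seq_len(m), seq_len(m)),
       term_idx = match(q$terminals, nodes), anchor_idx = ai)
}

# vectorized Bellman-Ford relaxation with predecessor tracking;
# safe with zero-length edges (strict improvement only)
relax_bf <- function(d, from, to, w, eid) {
  np <- length(d)
  pred <- integer(np); pedge <- integer(np)
  repeat {
    cand <- d[from] + w
    o <- order(to, cand)
    f <- !duplicated(to[o])
    tt <- to[o][f]; cb <- cand[o][f]; di <- o[f]
    imp <- cb < d[tt] - 1e-13
    if (!any(imp)) break
    d[tt[imp]] <- cb[imp]
    pred[tt[imp]] <- from[di[imp]]
    pedge[tt[imp]] <- eid[di[imp]]
  }
  list(d = d, pred = pred, pedge = pedge)
}

# build a classed subnetwork from chosen undirected edge indices of idx
subnetwork_from_eids <- function(q, idx, eids) {
  eids <- sort(unique(eids))
  net_eids <- eids[eids <= idx$n_net_edges]  # drop virtual root edges
  e <- q$network$edges[net_eids, , drop = FALSE]
  nodes <- sort(unique(c(e$u, e$v, q$terminals)))
  H <- structure(list(nodes = nodes,
                      edges = e[order(e$u, e$v), , drop = FALSE],
                      alpha = q$alpha),
                 class = "subnetwork")
  dist <- subnetwork_distances(H, q)
  H$terminal_distances <- dist
  H$objective <- objective(H, q)
  H
}

# shortest -log-confidence distance from the anchor set to each terminal
# within the subnetwork
subnetwork_distances <- function(H, q) {
  nodes <- H$nodes
  n <- length(nodes)
  anchors_in <- intersect(q$anchors, nodes)
  if (length(anchors_in) == 0)
    stop("subnetwork contains no anchor")
  e <- H$edges
  len <- edge_length(e$confidence)
  ui <- match(e$u, nodes); vi <- match(e$v, nodes)
  root <- n + 1L
  ai <- match(anchors_in, nodes)
  from <- c(ui, vi, rep(root, length(ai)), ai)
  to <- c(vi, ui, ai, rep(root, length(ai)))
  w <- c(len, len, rep(0, 2 * length(ai)))
  d <- rep(Inf, n + 1L); d[root] <- 0
  d <- relax_bf(d, from, to, w, seq_along(from))$d
  ti <- match(q$terminals, nodes)
  if (anyNA(ti) || any(!is.finite(d[ti])))
    stop("terminal(s) disconnected in subnetwork: ",
         paste(q$terminals[is.na(ti) | !is.finite(d[stats::na.omit(ti)])],
               collapse = ", "))
  setNames(d[ti], q$terminals)
}

#' Objective value of a subnetwork
#'
#' Computes `f_alpha(H) = (1 - 2 alpha) * sum_t d_H(A, t) +
#' 2 alpha * sum_e length(e)` where `d_H(A, t)` is the shortest
#' `-log(confidence)` distance within `H` from any anchor to terminal `t`.
#'
#' @param H a `subnetwork` (list with `edges`; see [reconstruct()]).
#' @param q the [query_instance()] supplying anchors, terminals and alpha.
#' @return the objective value (numeric scalar).
#' @export
objective <- function(H, q) {
  dist <- subnetwork_distances(H, q)
  len <- edge_length(H$edges$confidence)
  (1 - 2 * q$alpha) * sum(dist) + 2 * q$alpha * sum(len)
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Subnetwork:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges, objective", format(x$objective, digits = 6),
      "(alpha =", paste0(x$alpha, ")"), "\n")
  invisible(x)
}

# exact Dreyfus-Wagner-style DP over (node, terminal subset)
reconstruct_dp <- function(q, idx) {
  K <- length(idx$term_idx)
  n1 <- idx$n + 1L
  nmask <- bitwShiftL(1L, K)
  full <- nmask - 1L
  bits <- bitwShiftL(1L, seq_len(K) - 1L)
  popc <- vapply(0:(nmask - 1L),
                 function(m) sum(bitwAnd(m, bits) > 0L), 0L)
  C <- matrix(Inf, n1, nmask)
  predN <- matrix(0L, n1, nmask)
  predE <- matrix(0L, n1, nmask)
  splitM <- matrix(0L, n1, nmask)
  a <- q$alpha
  masks <- order(popc)
  for (mask in (0:(nmask - 1L))[masks]) {
    k <- popc[mask + 1L]
    if (k == 0L) next
    col <- mask + 1L
    if (k == 1L) {
      t <- idx$term_idx[which(bits == mask)]
      C[t, col] <- 0
    } else {
      low <- bitwAnd(mask, -mask)
      s <- bitwAnd(mask - 1L, mask)
      while (s > 0L) {
        if (bitwAnd(s, low) != 0L) {
          comp <- mask - s
          cand <- C[, s + 1L] + C[, comp + 1L]
          imp <- cand < C[, col] - 1e-13
          if (any(imp)) {
            C[imp, col] <- cand[imp]
            splitM[imp, col] <- s
            predN[imp, col] <- 0L
            predE[imp, col] <- 0L
          }
        }
        s <- bitwAnd(s - 1L, mask)
      }
    }
    w <- (2 * a + (1 - 2 * a) * k) * idx$dlen
    res <- relax_bf(C[, col], idx$from, idx$to, w, idx$eid)
    imp <- res$d < C[, col] - 1e-15
    C[, col] <- res$d
    predN[imp, col] <- res$pred[imp]
    predE[imp, col] <- res$pedge[imp]
    splitM[imp, col] <- 0L
  }
  if (!is.finite(C[idx$root, full + 1L]))
    stop("no feasible anchored tree found")
  # traceback
  eids <- integer()
  stack <- list(c(idx$root, full))
  while (length(stack)) {
    st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- st[1]; mask <- st[2]
    col <- mask + 1L
    while (predN[v, col] > 0L) {
      eids <- c(eids, predE[v, col])
      v <- predN[v, col]
    }
    s <- splitM[v, col]
    if (s > 0L) {
      stack[[length(stack) + 1L]] <- c(v, s)
      stack[[length(stack) + 1L]] <- c(v, mask - s)
    }
  }
  list(eids = unique(eids), dp_objective = C[idx$root, full + 1L])
}

# heuristic for large terminal sets: best of (i) the shortest-path tree to
# all terminals and (ii) a metric-closure Steiner approximation, both pruned
reconstruct_heuristic <- function(q) {
  g <- as_igraph(q$network)
  nodes <- q$network$nodes
  root_g <- igraph::add_vertices(g, 1, name = "..root..")
  root_g <- igraph::add_edges(root_g,
                              rbind("..root..", q$anchors),
                              weight = 0, confidence = 1)
  # (i) shortest-path tree
  sp <- igraph::shortest_paths(root_g, from = "..root..", to = q$terminals,
                               output = "both")
  e1 <- unique(unlist(lapply(sp$epath, as.integer)))
  # (ii) metric closure MST over root + terminals, expanded
  req <- c("..root..", q$terminals)
  dmat <- igraph::distances(root_g, v = req, to = req)
  dmat <- (dmat + t(dmat)) / 2  # exact symmetry despite float round-off
  mc <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(mc)
  e2 <- integer()
  ends2 <- igraph::ends(mst, igraph::E(mst))
  if (nrow(ends2)) for (i in seq_len(nrow(ends2))) {
    p <- igraph::shortest_paths(root_g, from = ends2[i, 1], to = ends2[i, 2],
                                output = "epath")$epath[[1]]
    e2 <- union(e2, as.integer(p))
  }
  best <- NULL
  for (eset in list(e1, e2)) {
    if (length(eset) == 0) next
    sub <- igraph::subgraph_from_edges(root_g, eset)
    # shortest-path tree within the union, then prune non-terminal leaves
    spt <- igraph::shortest_paths(sub, from = "..root..", to = q$terminals,
                                  output = "epath")
    keep <- unique(unlist(lapply(spt$epath, as.integer)))
    sub <- igraph::subgraph_from_edges(sub, keep)
    ends <- igraph::ends(sub, igraph::E(sub))
    ee <- data.frame(u = ends[, 1], v = ends[, 2],
                     stringsAsFactors = FALSE)
    ee$confidence <- igraph::E(sub)$confidence
    ee <- ee[ee$u != "..root.." & ee$v != "..root..", , drop = FALSE]
    ee <- prune_leaves(ee, keep_nodes = c(q$terminals, q$anchors))
    p <- canonical_pairs(ee$u, ee$v)
    ee$u <- p$u; ee$v <- p$v
    H <- structure(list(nodes = sort(unique(c(ee$u, ee$v, q$terminals))),
                        edges = ee[order(ee$u, ee$v), , drop = FALSE],
                        alpha = q$alpha),
                   class = "subnetwork")
    H$terminal_distances <- subnetwork_distances(H, q)
    H$objective <- objective(H, q)
    if (is.null(best) || H$objective < best$objective) best <- H
  }
  best
}

# iteratively remove degree-1 nodes not in keep_nodes
prune_leaves <- function(edges, keep_nodes) {
  repeat {
    deg <- table(c(edges$u, edges$v))
    leaves <- setdiff(names(deg)[deg == 1], keep_nodes)
    if (length(leaves) == 0) break
    edges <- edges[!(edges$u %in% leaves) & !(edges$v %in% leaves), ,
                   drop = FALSE]
  }
  edges
}

#' Reconstruct the optimal anchored subnetwork
#'
#' Finds a tree-shaped subnetwork connecting every terminal to the anchor
#' set, minimizing the alpha-weighted combination of per-terminal path
#' lengths and total subnetwork weight (see [objective()]). The search is
#' exact (dynamic programming over terminal subsets) whenever the number of
#' terminals is at most `exact_terminals`; larger instances fall back to a
#' shortest-path-tree / Steiner-approximation hybrid whose result is an
#' upper bound.
#'
#' @param q a [query_instance()].
#' @param lengths optional replacement edge lengths (same order as
#'   `q$network$edges`), used internally for ensemble diversification.
#' @param exact_terminals exact-search threshold on `|terminals|`.
#' @return a `subnetwork`: list with `nodes`, `edges` (with confidences),
#'   `objective`, `terminal_distances`, `alpha`.
#' @examples
#' net <- interaction_network(data.frame(
#'   u = c("a", "x", "x"), v = c("x", "t1", "t2"),
#'   confidence = exp(-1)))
#' q <- query_instance(net, "a", c("t1", "t2"), alpha = 0.5)
#' reconstruct(q)
#' @export
reconstruct <- function(q, lengths = NULL, exact_terminals = 8L) {
  stopifnot(inherits(q, "query_instance"))
  if (length(q$terminals) <= exact_terminals ||
      length(q$network$nodes) <= 12L) {
    idx <- index_graph(q, lengths)
    dp <- reconstruct_dp(q, idx)
    subnetwork_from_eids(q, idx, dp$eids)
  } else {
    if (!is.null(lengths)) {
      qj <- q
      qj$network$edges$confidence <- exp(-pmax(lengths, 0))
      H <- reconstruct_heuristic(qj)
      # report true-confidence objective
      key <- edge_key(H$edges$u, H$edges$v)
      H$edges$confidence <-
        q$network$edges$confidence[match(key, edge_key(q$network$edges$u,
                                                       q$network$edges$v))]
      H$terminal_distances <- subnetwork_distances(H, q)
      H$objective <- objective(H, q)
      H
    } else reconstruct_heuristic(q)
  }
}

#' Exhaustive optimum by branch-and-bound enumeration (oracle)
#'
#' Enumerates every leaf-minimal rooted subtree containing all terminals on
#' instances of at most 12 network nodes and returns the minimum-objective
#' one (ties: fewer edges, then lexicographically smallest edge list). This
#' is an independent check on [reconstruct()], not a scalable solver.
#'
#' @param q a [query_instance()] whose network has at most 12 nodes.
#' @return a `subnetwork`.
#' @export
brute_force_optimum <- function(q) {
  stopifnot(inherits(q, "query_instance"))
  if (length(q$network$nodes) > 12L)
    stop("brute_force_optimum refuses instances with more than 12 nodes")
  idx <- index_graph(q)
  res <- .tree_search_cpp(idx$n + 1L, idx$und_from - 1L, idx$und_to - 1L,
                          idx$und_len, idx$root - 1L, idx$term_idx - 1L,
                          idx$anchor_idx - 1L, q$alpha, Inf, FALSE, 1e8)
  if (!is.finite(res$objective))
    stop("no feasible anchored tree found")
  subnetwork_from_eids(q, idx, res$edges + 1L)
}
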