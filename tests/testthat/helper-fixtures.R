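# fixtures built in code: small random networks and query instances

# connected-ish Erdos-Renyi network with random confidences
random_network <- function(n, p = 0.35, conf_range = c(0.05, 0.99)) {
  repeat {
    m <- matrix(runif(n * n) < p, n, n)
    ij <- which(upper.tri(m) & m, arr.ind = TRUE)
    if (nrow(ij) >= n - 1) break
  }
  ids <- sprintf("v%02d", seq_len(n))
  interaction_network(data.frame(
    u = ids[ij[, 1]], v = ids[ij[, 2]],
    confidence = runif(nrow(ij), conf_range[1], conf_range[2]),
    stringsAsFactors = FALSE), nodes = ids)
}

# random feasible query on a network (NULL if none found)
random_query <- function(net, n_anchors = 1:2, n_terminals = 1:3,
                         alpha = c(0, 0.25, 0.5), margin = 1,
                         tries = 20) {
  pick1 <- function(x) x[sample.int(length(x), 1)]
  for (i in seq_len(tries)) {
    na <- pick1(n_anchors)
    nt <- pick1(n_terminals)
    if (na + nt > length(net$nodes)) next
    picks <- sample(net$nodes, na + nt)
    q <- tryCatch(
      query_instance(net, picks[seq_len(na)], picks[na + seq_len(nt)],
                     alpha = pick1(alpha), margin = margin),
      error = function(e) NULL)
    if (!is.null(q)) return(q)
  }
  NULL
}

# the 4-node worked instance: a-x(1), x-t1(1), x-t2(1), a-t1(1.5), a-t2(1.5)
star_vs_direct_network <- function() {
  interaction_network(data.frame(
    u = c("a", "x", "x", "a", "a"),
    v = c("x", "t1", "t2", "t1", "t2"),
    confidence = exp(-c(1, 1, 1, 1.5, 1.5)),
    stringsAsFactors = FALSE))
}

# diamond ontology: root -> {p, q}; a is_a {p, q}; b is_a p
diamond_ontology <- function() {
  method_ontology(list(root = character(), p = "root", q = "root",
                       a = c("p", "q"), b = "p"))
}

# hand-rolled subnetwork wrapper for objective() tests
manual_subnetwork <- function(u, v, confidence) {
  structure(list(nodes = sort(unique(c(u, v))),
                 edges = data.frame(u = u, v = v, confidence = confidence,
                                    stringsAsFactors = FALSE)),
            class = "subnetwork")
}

extdata <- function(f) system.file("extdata", f, package = "anchornet")

# exhaustive AUROC: mean over all positive-negative pairs (ties 0.5)
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive minimum spanning forest weight on a small edge set
brute_msf_weight <- function(nodes, edges) {
  n <- length(nodes)
  if (nrow(edges) == 0) return(0)
  w <- -log(edges$confidence)
  comp_count <- function(keep) {
    g <- igraph::graph_from_data_frame(edges[keep, c("u", "v")],
                                       directed = FALSE,
                                       vertices = data.frame(name = nodes))
    igraph::components(g)$no
  }
  base_comp <- comp_count(rep(TRUE, nrow(edges)))
  k <- n - base_comp  # edges in any spanning forest
  if (k == 0) return(0)
  best <- Inf
  for (sel in utils::combn(nrow(edges), k, simplify = FALSE)) {
    keep <- logical(nrow(edges)); keep[sel] <- TRUE
    if (comp_count(keep) == base_comp) best <- min(best, sum(w[sel]))
  }
  best
}
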