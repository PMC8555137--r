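# Synthetic benchmark: random background networks with planted ground-truth
# pathways, so the reconstruction and refinement layers can be trained and
# evaluated without any database download.

#' Benchmark generator configuration
#'
#' Defaults emulate a desk-scale corpus of signalling-pathway-like planted
#' subnetworks: a sparse random background with moderate-confidence edges,
#' and layered source-to-sink pathways inserted with high-confidence edges,
#' plus high-confidence decoy edges that make recovery nontrivial.
#'
#' @param n_background_nodes background network size.
#' @param background_edge_prob Erdos-Renyi edge probability.
#' @param n_pathways number of planted pathways.
#' @param pathway_size_range integer range of planted pathway node counts.
#' @param n_anchors_range,n_terminals_range integer ranges for the source
#'   and sink layer sizes.
#' @param confidence_noise width of the planted-edge confidence band below
#'   0.99 (planted confidences ~ U(0.99 - noise, 0.99)).
#' @param decoy_edge_factor number of decoy high-confidence edges as a
#'   multiple of the total planted edge count.
#' @param seed integer seed; the whole corpus is deterministic per seed.
#' @return object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_background_nodes = 250L,
                             background_edge_prob = 0.02,
                             n_pathways = 10L,
                             pathway_size_range = c(8L, 14L),
                             n_anchors_range = c(1L, 2L),
                             n_terminals_range = c(2L, 3L),
                             confidence_noise = 0.19,
                             decoy_edge_factor = 1.5,
                             seed = 1L) {
  stopifnot(n_background_nodes >= 4,
            background_edge_prob > 0, background_edge_prob < 1,
            n_pathways >= 1,
            pathway_size_range[1] >= 3,
            diff(pathway_size_range) >= 0,
            n_anchors_range[1] >= 1, n_terminals_range[1] >= 1,
            confidence_noise >= 0, confidence_noise < 0.99,
            decoy_edge_factor >= 0)
  if (pathway_size_range[2] > n_background_nodes)
    stop("pathway larger than background")
  structure(list(n_background_nodes = as.integer(n_background_nodes),
                 background_edge_prob = background_edge_prob,
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 n_anchors_range = as.integer(n_anchors_range),
                 n_terminals_range = as.integer(n_terminals_range),
                 confidence_noise = confidence_noise,
                 decoy_edge_factor = decoy_edge_factor,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

# sample one value from a vector / inclusive integer range (length-1 safe)
resample1 <- function(x) x[sample.int(length(x), 1)]
range1 <- function(r) resample1(seq(r[1], r[2]))

# one planted pathway: a layered DAG (anchor layer -> cascade -> terminal
# layer); returns node ids, directed edges, anchors/terminals by degree rule
plant_pathway <- function(name, node_pool, cfg) {
  size <- range1(cfg$pathway_size_range)
  na <- range1(cfg$n_anchors_range)
  nt <- range1(cfg$n_terminals_range)
  n_mid <- max(1L, size - na - nt)
  nodes <- sample(node_pool, na + n_mid + nt)
  layers <- list(nodes[seq_len(na)])
  mid <- nodes[na + seq_len(n_mid)]
  while (length(mid)) {
    w <- min(length(mid), range1(c(1, 3)))
    layers[[length(layers) + 1L]] <- mid[seq_len(w)]
    mid <- mid[-seq_len(w)]
  }
  layers[[length(layers) + 1L]] <- nodes[na + n_mid + seq_len(nt)]
  from <- character(); to <- character()
  for (i in seq_len(length(layers) - 1L)) {
    a <- layers[[i]]; b <- layers[[i + 1L]]
    # every child gets >= 1 parent; every parent gets >= 1 child
    nf <- vapply(b, function(child) resample1(a), "")
    nt2 <- b
    childless <- setdiff(a, nf)
    nf <- c(nf, childless)
    nt2 <- c(nt2, vapply(childless, function(p) resample1(b), ""))
    # extra forward wiring
    extra <- expand.grid(f = a, t = b, stringsAsFactors = FALSE)
    pick <- runif(nrow(extra)) < 0.3
    from <- c(from, nf, extra$f[pick])
    to <- c(to, nt2, extra$t[pick])
  }
  keep <- !duplicated(paste(from, to))
  pg <- pathway_graph(name,
                      data.frame(id = nodes, kind = "protein",
                                 stringsAsFactors = FALSE),
                      data.frame(from = from[keep], to = to[keep],
                                 stringsAsFactors = FALSE))
  at <- extract_anchors_terminals(pg)
  p <- canonical_pairs(from[keep], to[keep])
  ekeep <- !duplicated(paste(p$u, p$v))
  structure(list(name = name, truth_nodes = sort(nodes),
                 truth_edges = data.frame(u = p$u[ekeep], v = p$v[ekeep],
                                          stringsAsFactors = FALSE),
                 anchors = at$anchors, terminals = at$terminals,
                 graph = pg),
            class = c("planted_pathway", "training_pathway"))
}

#' Generate a benchmark corpus
#'
#' Builds an Erdos-Renyi background network with confidences
#' ~ U(0.3, 0.95), plants each pathway as a layered DAG whose undirected
#' edges are inserted with high confidence (U(0.99 - noise, 0.99)), and adds
#' `decoy_edge_factor` x (planted edge count) random high-confidence decoy
#' edges. Deterministic per `cfg$seed`.
#'
#' @param cfg a [benchmark_config()].
#' @return list with `network` (an [interaction_network()]) and `pathways`
#'   (list of `planted_pathway` objects, usable directly as
#'   [training_pathway()] inputs).
#' @export
generate_corpus <- function(cfg = benchmark_config()) {
  stopifnot(inherits(cfg, "benchmark_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_background_nodes
    ids <- sprintf("N%04d", seq_len(n))
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    pick <- runif(nrow(pairs)) < cfg$background_edge_prob
    bg <- if (any(pick))
      data.frame(u = ids[pairs[pick, 1]], v = ids[pairs[pick, 2]],
                 confidence = runif(sum(pick), 0.3, 0.95),
                 source = "background", method = NA_character_,
                 stringsAsFactors = FALSE)
    else NULL
    pathways <- lapply(seq_len(cfg$n_pathways), function(i)
      plant_pathway(sprintf("pathway_%02d", i), ids, cfg))
    lo <- 0.99 - cfg$confidence_noise
    planted <- do.call(rbind, lapply(pathways, function(pw) {
      data.frame(u = pw$truth_edges$u, v = pw$truth_edges$v,
                 confidence = runif(nrow(pw$truth_edges), lo, 0.99),
                 source = "planted", method = NA_character_,
                 stringsAsFactors = FALSE)
    }))
    # decoys: high-confidence two-edge bypasses routing between two truth
    # nodes of a pathway through a background node, so that reconstructions
    # face plausible false-positive detours (uniform random decoys at this
    # density almost never intersect an anchor-terminal route)
    n_decoy_edges <- round(cfg$decoy_edge_factor * nrow(planted))
    decoy <- NULL
    if (n_decoy_edges > 0) {
      rows <- list()
      for (b in seq_len(ceiling(n_decoy_edges / 2))) {
        pw <- pathways[[sample.int(length(pathways), 1)]]
        xy <- sample(pw$truth_nodes, 2)
        mid <- sample(setdiff(ids, pw$truth_nodes), 1)
        rows[[b]] <- data.frame(u = c(xy[1], mid), v = c(mid, xy[2]),
                                confidence = runif(2, lo, 0.99),
                                source = "decoy", method = NA_character_,
                                stringsAsFactors = FALSE)
      }
      decoy <- do.call(rbind, rows)
      p <- canonical_pairs(decoy$u, decoy$v)
      decoy$u <- p$u; decoy$v <- p$v
      decoy <- decoy[!duplicated(paste(decoy$u, decoy$v)), , drop = FALSE]
    }
    all_edges <- rbind(planted, decoy, bg)
    # planted/decoy confidences take precedence over background duplicates
    key <- edge_key(all_edges$u, all_edges$v)
    all_edges <- all_edges[!duplicated(key), , drop = FALSE]
    net <- interaction_network(all_edges, nodes = ids)
    list(network = net, pathways = pathways)
  })
}

#' Precision / recall / F1 of recovered pathway nodes
#'
#' Compares predicted nodes (those scored at or above `threshold`) with the
#' planted truth, excluding anchors and terminals from both sides since
#' they are inputs, not predictions. If the truth set is empty after
#' exclusion, all three values are returned as `NaN` with a warning.
#'
#' @param predicted a `scored_nodes` data frame (see [refine()]), a named
#'   numeric score vector, or a character vector of node ids (scores 1).
#' @param truth a `planted_pathway` (or any list with `truth_nodes`,
#'   `anchors`, `terminals`).
#' @param threshold score threshold for inclusion.
#' @return named numeric: `precision`, `recall`, `f1`.
#' @export
score_recovery <- function(predicted, truth, threshold = 0.5) {
  if (inherits(predicted, "scored_nodes") || is.data.frame(predicted)) {
    pred <- predicted$node[predicted$score >= threshold]
  } else if (!is.null(names(predicted)) && is.numeric(predicted)) {
    pred <- names(predicted)[predicted >= threshold]
  } else {
    pred <- as.character(predicted)
  }
  given <- c(truth$anchors, truth$terminals)
  pred <- setdiff(pred, given)
  truth_nodes <- setdiff(truth$truth_nodes, given)
  if (length(truth_nodes) == 0) {
    warning("truth set empty after excluding anchors/terminals")
    return(c(precision = NaN, recall = NaN, f1 = NaN))
  }
  tp <- length(intersect(pred, truth_nodes))
  precision <- if (length(pred) == 0) 0 else tp / length(pred)
  recall <- tp / length(truth_nodes)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}
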