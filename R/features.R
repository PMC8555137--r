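# Feature construction for the refinement layer: per (pathway, node) rows
# of 5 features — ensemble confidences at alpha = 0, 0.25, 0.5 and the two
# propagation proximities — plus a binary true-pathway label.

#' Describe a training pathway
#'
#' @param name pathway identifier.
#' @param truth_nodes character vector: the true pathway node set (labels).
#' @param anchors,terminals the query node sets extracted for this pathway.
#' @return object of class `training_pathway`.
#' @export
training_pathway <- function(name, truth_nodes, anchors, terminals) {
  stopifnot(length(anchors) >= 1, length(terminals) >= 1)
  structure(list(name = as.character(name),
                 truth_nodes = unique(as.character(truth_nodes)),
                 anchors = unique(as.character(anchors)),
                 terminals = unique(as.character(terminals))),
            class = "training_pathway")
}

CONF_COLS <- c("f_a0", "f_a25", "f_a50")
PROP_COLS <- c("prop_anchor", "prop_terminal")
FEATURE_COLS <- c(CONF_COLS, PROP_COLS)

# per-pathway candidate features: 3 ensembles + 2 propagations
pathway_features <- function(anchors, terminals, net, margin, seed,
                             n_samples = 20L, alpha_grid = c(0, 0.25, 0.5),
                             prop_cfg = propagation_config()) {
  stopifnot(length(alpha_grid) == 3)
  confs <- vector("list", 3)
  for (j in seq_along(alpha_grid)) {
    q <- query_instance(net, anchors, terminals, alpha = alpha_grid[j],
                        margin = margin)
    ens <- enumerate_ensemble(q, n_samples = n_samples, seed = seed + j)
    confs[[j]] <- ens$node_confidence
  }
  candidates <- sort(unique(unlist(lapply(confs, names))))
  prox <- proximity_features(net, anchors, terminals, prop_cfg)
  out <- data.frame(node = candidates, stringsAsFactors = FALSE)
  for (j in 1:3) {
    v <- confs[[j]][candidates]
    v[is.na(v)] <- 0
    out[[CONF_COLS[j]]] <- unname(v)
  }
  m <- match(candidates, prox$node)
  out$prop_anchor <- prox$prop_anchor[m]
  out$prop_terminal <- prox$prop_terminal[m]
  out
}

#' Build the training feature table
#'
#' For each pathway, runs one solution ensemble per alpha in
#' `{0, 0.25, 0.5}` (three base reconstructions) and two network
#' propagations (from anchors and from terminals). Candidate nodes are the
#' union of nodes appearing in any of the three ensembles; each candidate
#' row carries the three ensemble confidences (0 where absent) and the two
#' propagation coefficients, labelled 1 iff the node belongs to the true
#' pathway. True-pathway nodes missed by every ensemble are appended as
#' all-zero feature rows with label 1. A node shared by k pathways
#' contributes k rows. Pathways whose terminals are unreachable are skipped
#' with a warning and recorded in the `skipped` attribute.
#'
#' @param pathways list of [training_pathway()] objects.
#' @param net background [interaction_network()].
#' @param margin ensemble admission margin (>= 1).
#' @param seed integer seed driving all ensemble sampling.
#' @param n_samples restarts per sampled ensemble.
#' @param prop_cfg a [propagation_config()].
#' @return a `feature_table`: data frame with columns `pathway`, `node`,
#'   `f_a0`, `f_a25`, `f_a50`, `prop_anchor`, `prop_terminal`, `label`;
#'   attributes `margin` and `skipped`.
#' @export
build_feature_table <- function(pathways, net, margin = 1, seed = 1L,
                                n_samples = 20L,
                                prop_cfg = propagation_config()) {
  stopifnot(length(pathways) >= 1)
  rows <- list()
  skipped <- character()
  for (i in seq_along(pathways)) {
    pw <- pathways[[i]]
    feats <- tryCatch(
      pathway_features(pw$anchors, pw$terminals, net, margin,
                       seed = seed + 1000L * i, n_samples = n_samples,
                       prop_cfg = prop_cfg),
      error = function(e) {
        warning("skipping pathway '", pw$name, "': ", conditionMessage(e))
        NULL
      })
    if (is.null(feats)) { skipped <- c(skipped, pw$name); next }
    feats$pathway <- pw$name
    feats$label <- as.integer(feats$node %in% pw$truth_nodes)
    missed <- setdiff(pw$truth_nodes, feats$node)
    if (length(missed)) {
      inj <- data.frame(node = missed, f_a0 = 0, f_a25 = 0, f_a50 = 0,
                        prop_anchor = 0, prop_terminal = 0,
                        pathway = pw$name, label = 1L,
                        stringsAsFactors = FALSE)
      feats <- rbind(feats, inj)
    }
    rows[[length(rows) + 1L]] <- feats
  }
  if (length(rows) == 0) stop("all pathways were skipped")
  tbl <- do.call(rbind, rows)
  tbl <- tbl[, c("pathway", "node", FEATURE_COLS, "label")]
  rownames(tbl) <- NULL
  structure(tbl, margin = margin, skipped = skipped,
            class = c("feature_table", "data.frame"))
}

#' Normalize feature columns to mean 0, variance 1
#'
#' Z-scores each of the five feature columns using the population standard
#' deviation of the table (captured for reuse at inference time). Constant
#' columns (sd = 0) are mapped to all zeros and flagged.
#'
#' @param table a `feature_table` (or the normalization statistics of a
#'   trained model via `stats`).
#' @param stats optional previously captured statistics (list with `mean`,
#'   `sd`, `constant`); when supplied, those are applied instead of
#'   refitting.
#' @return the normalized table, with attribute `normalization`.
#' @export
normalize_features <- function(table, stats = NULL) {
  stopifnot(all(FEATURE_COLS %in% names(table)))
  if (nrow(table) < 2 && is.null(stats))
    stop("cannot estimate normalization from a single-row table")
  if (is.null(stats)) {
    mu <- vapply(FEATURE_COLS, function(cl) mean(table[[cl]]), 0)
    sdv <- vapply(FEATURE_COLS, function(cl) pop_sd(table[[cl]]), 0)
    stats <- list(mean = mu, sd = sdv, constant = sdv == 0)
  }
  for (cl in FEATURE_COLS) {
    if (stats$constant[[cl]]) table[[cl]] <- rep(0, nrow(table))
    else table[[cl]] <- (table[[cl]] - stats$mean[[cl]]) / stats$sd[[cl]]
  }
  attr(table, "normalization") <- stats
  table
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x), "rows,",
      length(unique(x$pathway)), "pathway(s),",
      sum(x$label == 1), "positive label(s)",
      if (!is.null(attr(x, "normalization"))) "(normalized)", "\n")
  invisible(x)
}

#' Write / read a feature table as tsv
#'
#' @param table a `feature_table`.
#' @param path file path.
#' @return `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("pathway", "node", FEATURE_COLS, "label") %in% names(tbl)))
  structure(tbl, class = c("feature_table", "data.frame"))
}
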