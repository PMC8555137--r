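# Random-forest refinement layer: training, cross-validated evaluation
# (AUROC / AUPRC), margin tuning and node rescoring at query time.

feature_cols_for <- function(feature_set) {
  switch(feature_set,
         all5 = FEATURE_COLS,
         conf3 = CONF_COLS,
         prop2 = PROP_COLS,
         stop("unknown feature_set: ", feature_set))
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney); tied scores contribute 0.5 per
#' positive-negative pair.
#'
#' @param scores numeric ranking scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUROC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated integration over score thresholds; tied scores are
#' grouped so the curve is threshold-consistent.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || sum(labels == 0) == 0)
    stop("both classes required for AUPRC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index per score
  tp <- cumsum(y)[grp_end]
  np <- grp_end  # predictions made at each threshold
  prec <- tp / np
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Train the node rescoring classifier
#'
#' Fits a random forest (100 trees, otherwise implementation defaults) on
#' the selected feature columns of a normalized feature table.
#'
#' @param table a normalized `feature_table` (see [normalize_features()])
#'   containing both labels.
#' @param feature_set `"all5"` (default), `"conf3"` (ensemble confidences
#'   only) or `"prop2"` (propagation proximities only).
#' @param seed integer seed pinning the forest.
#' @return object of class `node_classifier` carrying the forest, the
#'   normalization statistics, the training margin and the feature set.
#' @export
train_classifier <- function(table, feature_set = "all5", seed = 1L) {
  cols <- feature_cols_for(feature_set)
  norm <- attr(table, "normalization")
  if (is.null(norm))
    stop("table must be normalized with normalize_features() before training")
  y <- factor(table$label, levels = c(0, 1))
  if (length(unique(table$label)) < 2)
    stop("training table must contain both classes")
  x <- as.data.frame(table)[, cols, drop = FALSE]
  forest <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = 100))
  structure(list(forest = forest, normalization = norm,
                 margin = attr(table, "margin") %||% NA_real_,
                 feature_set = feature_set, cols = cols, seed = seed),
            class = "node_classifier")
}

#' @export
print.node_classifier <- function(x, ...) {
  cat("Node classifier: random forest (", x$forest$ntree, " trees), ",
      "feature set '", x$feature_set, "', training margin ",
      format(x$margin), "\n", sep = "")
  invisible(x)
}

#' Score nodes with a trained classifier
#'
#' @param object a `node_classifier`.
#' @param newdata data frame with the five raw (unnormalized) feature
#'   columns; the model's stored normalization is applied.
#' @param ... unused.
#' @return numeric vector of class-1 probabilities in `[0, 1]`.
#' @export
predict.node_classifier <- function(object, newdata, ...) {
  nd <- normalize_features(as.data.frame(newdata), stats = object$normalization)
  p <- predict(object$forest, newdata = nd[, object$cols, drop = FALSE],
               type = "prob")
  unname(p[, "1"])
}

# stratified k-fold assignment; redraw if some training fold lacks a class
stratified_folds <- function(labels, k, seed, max_redraw = 20L) {
  with_seed(seed, {
    for (attempt in seq_len(max_redraw)) {
      fold <- integer(length(labels))
      for (cls in unique(labels)) {
        ix <- which(labels == cls)
        fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
      }
      ok <- all(vapply(seq_len(k), function(f) {
        tr <- labels[fold != f]
        length(unique(tr)) == 2
      }, TRUE))
      if (ok) return(fold)
    }
    stop("could not produce folds with both classes in every training fold")
  })
}

#' Cross-validated evaluation of a feature set
#'
#' Stratified k-fold cross-validation; out-of-fold probabilities are pooled
#' before computing AUROC and AUPRC.
#'
#' @param table a normalized `feature_table`.
#' @param feature_set see [train_classifier()].
#' @param k number of folds (default 5).
#' @param seed integer seed for fold assignment and forests.
#' @return one-row data frame: `feature_set`, `auroc`, `auprc`, `folds`.
#' @export
cross_validate <- function(table, feature_set = "all5", k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  if (length(unique(table$label)) < 2)
    stop("both classes required for cross-validation")
  cols <- feature_cols_for(feature_set)
  fold <- stratified_folds(table$label, k, seed)
  oof <- rep(NA_real_, nrow(table))
  x <- as.data.frame(table)[, cols, drop = FALSE]
  y <- factor(table$label, levels = c(0, 1))
  for (f in seq_len(k)) {
    tr <- fold != f
    forest <- with_seed(seed + f, randomForest::randomForest(
      x = x[tr, , drop = FALSE], y = y[tr], ntree = 100))
    p <- predict(forest, newdata = x[!tr, , drop = FALSE], type = "prob")
    oof[!tr] <- p[, "1"]
  }
  data.frame(feature_set = feature_set,
             auroc = auroc(oof, table$label),
             auprc = auprc(oof, table$label),
             folds = k, stringsAsFactors = FALSE)
}

#' Tune the ensemble margin over a grid
#'
#' For each margin, builds a feature table, cross-validates the three
#' feature sets (`all5`, `conf3`, `prop2`) and evaluates the single-run
#' baseline (the raw ensemble confidence at alpha = 0.25 used directly as
#' the ranking score, no classifier). The selected margin maximizes the
#' mean of AUROC and AUPRC of the `all5` model (ties: smallest margin).
#'
#' @param pathways list of [training_pathway()] objects.
#' @param net background [interaction_network()].
#' @param margins margin grid (default `{1, 1.2, 1.4, 1.6, 1.8, 2}`).
#' @param seed integer seed.
#' @param n_samples restarts per sampled ensemble.
#' @param k CV folds.
#' @param prop_cfg a [propagation_config()].
#' @return object of class `margin_tuning`: list with `report` (an
#'   `eval_report` data frame over margin x feature set), `best_margin`,
#'   and `tables` (the per-margin feature tables, normalized).
#' @export
tune_margin <- function(pathways, net,
                        margins = c(1, 1.2, 1.4, 1.6, 1.8, 2),
                        seed = 1L, n_samples = 20L, k = 5L,
                        prop_cfg = propagation_config()) {
  stopifnot(length(margins) >= 1, all(margins >= 1))
  rows <- list()
  tables <- list()
  for (m in margins) {
    tbl <- build_feature_table(pathways, net, margin = m, seed = seed,
                               n_samples = n_samples, prop_cfg = prop_cfg)
    ntbl <- normalize_features(tbl)
    tables[[as.character(m)]] <- ntbl
    for (fs in c("all5", "conf3", "prop2")) {
      r <- cross_validate(ntbl, fs, k = k, seed = seed)
      r$margin <- m
      rows[[length(rows) + 1L]] <- r
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature_set = "baseline",
      auroc = auroc(tbl$f_a25, tbl$label),
      auprc = auprc(tbl$f_a25, tbl$label),
      folds = NA_integer_, margin = m, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  report <- report[, c("margin", "feature_set", "auroc", "auprc", "folds")]
  class(report) <- c("eval_report", "data.frame")
  all5 <- report[report$feature_set == "all5", ]
  score <- (all5$auroc + all5$auprc) / 2
  best <- all5$margin[order(-score, all5$margin)][1]
  structure(list(report = report, best_margin = best, tables = tables),
            class = "margin_tuning")
}

#' @export
print.margin_tuning <- function(x, ...) {
  cat("Margin tuning over {", paste(unique(x$report$margin), collapse = ", "),
      "}; selected margin:", x$best_margin, "\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' @export
plot.eval_report <- function(x, metric = c("auroc", "auprc"), ...) {
  metric <- match.arg(metric)
  sets <- unique(x$feature_set)
  margins <- sort(unique(x$margin))
  mat <- sapply(sets, function(fs) {
    sub <- x[x$feature_set == fs, ]
    sub[[metric]][match(margins, sub$margin)]
  })
  graphics::matplot(margins, mat, type = "b", pch = seq_along(sets),
                    lty = seq_along(sets), col = seq_along(sets),
                    xlab = "margin", ylab = toupper(metric),
                    ylim = c(0, 1), ...)
  graphics::legend("bottomleft", legend = sets, pch = seq_along(sets),
                   lty = seq_along(sets), col = seq_along(sets), bty = "n")
  invisible(x)
}

#' Rescore candidate nodes for a query with a trained classifier
#'
#' Generates the five features for the query's candidate nodes (three
#' ensembles over the alpha grid at the model's training margin, plus the
#' two propagation proximities), applies the stored normalization, and
#' scores each node with the classifier. Anchors and terminals are always
#' retained regardless of score.
#'
#' @param q a [query_instance()].
#' @param model a `node_classifier`.
#' @param threshold retention probability threshold in `[0, 1]`.
#' @param seed integer seed for ensemble sampling.
#' @param n_samples restarts per sampled ensemble.
#' @param prop_cfg a [propagation_config()].
#' @return object of class `scored_nodes`: data frame `node`, `score`,
#'   `is_anchor`, `is_terminal`, `kept`.
#' @export
refine <- function(q, model, threshold = 0.5, seed = 1L, n_samples = 20L,
                   prop_cfg = propagation_config()) {
  stopifnot(inherits(q, "query_instance"),
            inherits(model, "node_classifier"),
            threshold >= 0, threshold <= 1)
  margin <- if (is.na(model$margin)) q$margin else model$margin
  feats <- pathway_features(q$anchors, q$terminals, q$network, margin,
                            seed = seed, n_samples = n_samples,
                            prop_cfg = prop_cfg)
  score <- predict(model, feats)
  out <- data.frame(node = feats$node, score = score,
                    is_anchor = feats$node %in% q$anchors,
                    is_terminal = feats$node %in% q$terminals,
                    stringsAsFactors = FALSE)
  out$kept <- out$score >= threshold | out$is_anchor | out$is_terminal
  out <- out[order(-out$score, out$node), ]
  rownames(out) <- NULL
  class(out) <- c("scored_nodes", "data.frame")
  out
}

#' @export
print.scored_nodes <- function(x, ...) {
  cat("Scored nodes:", nrow(x), "candidates,", sum(x$kept), "kept\n")
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Persist / restore a trained classifier with its normalization
#'
#' @param model a `node_classifier`.
#' @param path archive path (RDS).
#' @return `load_classifier` returns the `node_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "node_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "node_classifier"))
    stop("file does not contain a node_classifier")
  model
}
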