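# Orchestration: run configuration, training-job scheduling (resumable by
# content hash), minimum-spanning-tree finalization, and the end-to-end
# anchored run that writes SIF / tsv / JSON outputs.

#' Run configuration
#'
#' @param alpha_grid alpha values for base reconstructions
#'   (default `{0, 0.25, 0.5}`).
#' @param margin_grid margin values for tuning
#'   (default `{1, 1.2, 1.4, 1.6, 1.8, 2}`).
#' @param n_samples restarts per sampled ensemble.
#' @param seed top-level seed; all randomness flows from it.
#' @param propagation a [propagation_config()].
#' @param threshold refinement retention threshold.
#' @return object of class `run_config`.
#' @export
run_config <- function(alpha_grid = c(0, 0.25, 0.5),
                       margin_grid = c(1, 1.2, 1.4, 1.6, 1.8, 2),
                       n_samples = 20L, seed = 1L,
                       propagation = propagation_config(),
                       threshold = 0.5) {
  stopifnot(length(alpha_grid) >= 1, all(alpha_grid >= 0 & alpha_grid <= 0.5),
            length(margin_grid) >= 1, all(margin_grid >= 1),
            n_samples >= 1, threshold >= 0, threshold <= 1)
  structure(list(alpha_grid = alpha_grid, margin_grid = margin_grid,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 propagation = propagation, threshold = threshold),
            class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Recognized keys: `alpha_grid`, `margin_grid`, `n_samples`, `seed`,
#' `beta`, `tol`, `max_iter`, `threshold`. Missing keys keep defaults.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- run_config()
  prop <- propagation_config(
    beta = y$beta %||% defaults$propagation$beta,
    tol = y$tol %||% defaults$propagation$tol,
    max_iter = y$max_iter %||% defaults$propagation$max_iter)
  run_config(alpha_grid = unlist(y$alpha_grid) %||% defaults$alpha_grid,
             margin_grid = unlist(y$margin_grid) %||% defaults$margin_grid,
             n_samples = y$n_samples %||% defaults$n_samples,
             seed = y$seed %||% defaults$seed,
             propagation = prop,
             threshold = y$threshold %||% defaults$threshold)
}

#' Plan the training jobs for a pathway corpus
#'
#' Enumerates one reconstruction job per (pathway, alpha, margin) and two
#' propagation jobs per pathway (one seeded at anchors, one at terminals).
#' The plan is inspectable before execution and each job carries a content
#' hash so completed jobs can be skipped on resume.
#'
#' @param pathways non-empty list of [training_pathway()] objects.
#' @param cfg a [run_config()].
#' @return object of class `job_plan`: data frame with columns `job_id`,
#'   `type`, `pathway`, `alpha`, `margin`, `seeds`, `hash`.
#' @export
schedule_training <- function(pathways, cfg = run_config()) {
  if (length(pathways) == 0) stop("empty pathway list")
  stopifnot(inherits(cfg, "run_config"))
  names_pw <- vapply(pathways, `[[`, "", "name")
  grid <- expand.grid(pathway = names_pw, alpha = cfg$alpha_grid,
                      margin = cfg$margin_grid, stringsAsFactors = FALSE)
  rec <- data.frame(type = "reconstruct", pathway = grid$pathway,
                    alpha = grid$alpha, margin = grid$margin,
                    seeds = NA_character_, stringsAsFactors = FALSE)
  prop <- data.frame(type = "propagate",
                     pathway = rep(names_pw, each = 2),
                     alpha = NA_real_, margin = NA_real_,
                     seeds = rep(c("anchors", "terminals"),
                                 length(names_pw)),
                     stringsAsFactors = FALSE)
  plan <- rbind(rec, prop)
  plan$job_id <- seq_len(nrow(plan))
  plan$hash <- vapply(seq_len(nrow(plan)), function(i)
    content_hash(c(plan$type[i], plan$pathway[i],
            format(plan$alpha[i]), format(plan$margin[i]),
            plan$seeds[i], format(cfg$seed), format(cfg$n_samples))), "")
  plan <- plan[, c("job_id", "type", "pathway", "alpha", "margin",
                   "seeds", "hash")]
  structure(plan, cfg = cfg, class = c("job_plan", "data.frame"))
}

#' Job counts of a plan
#'
#' @param plan a `job_plan`.
#' @return named integer vector: `reconstruct`, `propagate`, `total`.
#' @export
job_counts <- function(plan) {
  stopifnot(inherits(plan, "job_plan"))
  r <- sum(plan$type == "reconstruct")
  p <- sum(plan$type == "propagate")
  c(reconstruct = r, propagate = p, total = r + p)
}

#' @export
print.job_plan <- function(x, ...) {
  jc <- job_counts(x)
  cat("Job plan:", jc[["reconstruct"]], "reconstruction job(s),",
      jc[["propagate"]], "propagation job(s)\n")
  invisible(x)
}

#' Execute a job plan (resumable)
#'
#' Runs each job and stores its result as `<hash>.rds` under `out_dir`;
#' jobs whose result file already exists are skipped, making interrupted
#' training resumable.
#'
#' @param plan a `job_plan` from [schedule_training()].
#' @param pathways the pathway list the plan was built from.
#' @param net background [interaction_network()].
#' @param out_dir results directory (created if needed).
#' @return invisibly, a logical vector: which jobs were executed (vs
#'   skipped).
#' @export
execute_plan <- function(plan, pathways, net, out_dir) {
  stopifnot(inherits(plan, "job_plan"))
  cfg <- attr(plan, "cfg")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pw_by_name <- setNames(pathways, vapply(pathways, `[[`, "", "name"))
  ran <- logical(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    path <- file.path(out_dir, paste0(plan$hash[i], ".rds"))
    if (file.exists(path)) next
    pw <- pw_by_name[[plan$pathway[i]]]
    res <- if (plan$type[i] == "reconstruct") {
      q <- query_instance(net, pw$anchors, pw$terminals,
                          alpha = plan$alpha[i], margin = plan$margin[i])
      enumerate_ensemble(q, n_samples = cfg$n_samples,
                         seed = cfg$seed + plan$job_id[i])
    } else {
      seeds <- if (plan$seeds[i] == "anchors") pw$anchors else pw$terminals
      propagate(net, seeds, cfg$propagation)
    }
    saveRDS(res, path)
    ran[i] <- TRUE
  }
  invisible(ran)
}

#' Connect scored nodes as a minimum spanning forest
#'
#' Takes the subgraph of the background network induced by the given nodes
#' and keeps a minimum spanning forest under `-log(confidence)` edge
#' lengths (Kruskal order, ties broken lexicographically by edge
#' endpoints). If the induced subgraph is disconnected, a forest with more
#' than one component is returned and a warning names the component count.
#'
#' @param nodes scored node set: a `scored_nodes` data frame from
#'   [refine()] (kept rows are used), a named numeric score vector, or a
#'   character vector (scores 1).
#' @param net background [interaction_network()].
#' @return object of class `refined_network`: list with `nodes` (named
#'   score vector), `edges` (data frame `u`, `v`, `confidence`, `length`),
#'   `components`.
#' @export
finalize_mst <- function(nodes, net) {
  stopifnot(inherits(net, "interaction_network"))
  if (inherits(nodes, "scored_nodes") || is.data.frame(nodes)) {
    kept <- nodes[nodes$kept %||% rep(TRUE, nrow(nodes)), , drop = FALSE]
    scores <- setNames(kept$score, kept$node)
  } else if (!is.null(names(nodes)) && is.numeric(nodes)) {
    scores <- nodes
  } else {
    scores <- setNames(rep(1, length(nodes)), as.character(nodes))
  }
  if (length(scores) == 0) stop("empty node set")
  miss <- setdiff(names(scores), net$nodes)
  if (length(miss)) stop("node(s) absent from network: ",
                         paste(miss, collapse = ", "))
  e <- induced_edges(net, names(scores))
  e$length <- edge_length(e$confidence)
  # Kruskal with lexicographic tie-break on (u, v)
  e <- e[order(e$length, e$u, e$v), , drop = FALSE]
  ids <- names(scores)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- logical(nrow(e))
  if (nrow(e) > 0) for (i in seq_len(nrow(e))) {
    a <- find(match(e$u[i], ids)); b <- find(match(e$v[i], ids))
    if (a != b) { parent[a] <- b; keep[i] <- TRUE }
  }
  edges <- e[keep, c("u", "v", "confidence", "length"), drop = FALSE]
  rownames(edges) <- NULL
  components <- length(ids) - nrow(edges)
  if (components > 1)
    warning("refined node set induces a disconnected subgraph: ",
            components, " components in the spanning forest")
  structure(list(nodes = scores[order(names(scores))], edges = edges,
                 components = components),
            class = "refined_network")
}

#' @export
print.refined_network <- function(x, ...) {
  cat("Refined network:", length(x$nodes), "nodes,", nrow(x$edges),
      "spanning-forest edges,", x$components, "component(s)\n")
  invisible(x)
}

#' @export
plot.refined_network <- function(x, ...) {
  g <- igraph::graph_from_data_frame(
    x$edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = names(x$nodes)))
  plot(g, vertex.size = 18, vertex.label.cex = 0.7,
       vertex.color = grDevices::gray(1 - 0.7 * unname(x$nodes)), ...)
  invisible(x)
}

#' Run an anchored reconstruction end to end
#'
#' Reads the network and node lists, reconstructs the solution ensemble at
#' `alpha`, and — when `ml_based` is set and a model is supplied — rescores
#' candidates with the classifier and finalizes a minimum spanning tree.
#' Writes `solution.sif` (+ `.attrs`), `nodes.tsv` (node, confidence or
#' score, is_anchor, is_terminal), `summary.json` and `run.log` under
#' `out_dir`. Result artifacts are byte-identical across runs with the same
#' inputs and seed (the log carries a timestamp).
#'
#' @param network_file tsv edge list path.
#' @param anchors_file,terminals_file node list paths (one id per line).
#' @param out_dir output directory.
#' @param alpha,margin query parameters (defaults 0.25 and the config's
#'   first margin).
#' @param ml_based logical; rescore with a trained model.
#' @param model a `node_classifier` or a path to one saved with
#'   [save_classifier()]; required when `ml_based`.
#' @param cfg a [run_config()].
#' @return invisibly, a list with the ensemble and (if `ml_based`) the
#'   `scored_nodes` and `refined_network`.
#' @export
run_anchored <- function(network_file, anchors_file, terminals_file,
                         out_dir, alpha = 0.25, margin = 1,
                         ml_based = FALSE, model = NULL,
                         cfg = run_config()) {
  net <- read_edge_list(network_file)
  anchors <- read_node_list(anchors_file)
  terminals <- read_node_list(terminals_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  q <- query_instance(net, anchors, terminals, alpha = alpha,
                      margin = margin)
  ens <- enumerate_ensemble(q, n_samples = cfg$n_samples, seed = cfg$seed)
  out <- list(ensemble = ens)
  if (ml_based) {
    if (is.character(model)) model <- load_classifier(model)
    if (is.null(model)) stop("ml_based requires a trained model")
    if (!identical(sort(unname(model$cols)),
                   sort(feature_cols_for(model$feature_set))) ||
        length(model$normalization$mean) != length(FEATURE_COLS))
      stop("incompatible model: unexpected feature set or normalization width")
    scored <- refine(q, model, threshold = cfg$threshold, seed = cfg$seed,
                     n_samples = cfg$n_samples, prop_cfg = cfg$propagation)
    refined <- finalize_mst(scored, net)
    out$scored <- scored
    out$refined <- refined
    sol_net <- interaction_network(
      if (nrow(refined$edges)) cbind(refined$edges[, c("u", "v",
                                                       "confidence")],
                                     source = NA, method = NA)
      else NULL,
      nodes = names(refined$nodes))
    node_tbl <- data.frame(node = names(refined$nodes),
                           confidence = unname(refined$nodes),
                           is_anchor = names(refined$nodes) %in% anchors,
                           is_terminal = names(refined$nodes) %in% terminals,
                           stringsAsFactors = FALSE)
    summary_json <- list(mode = "ml_based", alpha = alpha, margin = margin,
                         threshold = cfg$threshold, seed = cfg$seed,
                         optimum_objective = ens$optimum$objective,
                         ensemble_members = length(ens$members),
                         n_candidates = nrow(scored),
                         n_kept = sum(scored$kept),
                         mst_components = refined$components)
  } else {
    sol_net <- interaction_network(
      cbind(ens$optimum$edges[, c("u", "v", "confidence")],
            source = NA, method = NA))
    node_tbl <- confidence_table(ens)
    summary_json <- list(mode = "ensemble", alpha = alpha, margin = margin,
                         seed = cfg$seed,
                         optimum_objective = ens$optimum$objective,
                         ensemble_members = length(ens$members))
  }
  write_network(sol_net, file.path(out_dir, "solution.sif"), format = "sif")
  utils::write.table(node_tbl, file.path(out_dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(paste("time:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               paste("package version:",
                     as.character(utils::packageVersion("anchornet"))),
               paste("network:", network_file),
               paste("anchors:", length(anchors), "| terminals:",
                     length(terminals)),
               paste("alpha:", alpha, "| margin:", margin,
                     "| seed:", cfg$seed, "| n_samples:", cfg$n_samples),
               paste("mode:", if (ml_based) "ml_based" else "ensemble"),
               paste("plan hash:",
                     content_hash(c(network_file, anchors, terminals,
                             format(alpha), format(margin),
                             format(cfg$seed))))),
             file.path(out_dir, "run.log"))
  invisible(out)
}

#' Read / write a node list (one identifier per line)
#'
#' @param path file path.
#' @param nodes character vector.
#' @return `read_node_list` returns a character vector.
#' @export
read_node_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_node_list
#' @export
write_node_list <- function(nodes, path) {
  writeLines(as.character(nodes), path)
  invisible(path)
}
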