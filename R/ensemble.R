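# Margin-bounded ensembles of near-optimal solutions and the node
# confidences derived from them.

#' Enumerate a margin-bounded ensemble of near-optimal subnetworks
#'
#' Collects distinct solutions whose objective is at most
#' `margin * optimum`; a margin of 1.2 admits solutions within 20% of the
#' optimum. On instances small enough for exhaustive search (<= 12 network
#' nodes) the ensemble is the complete set of leaf-minimal solutions within
#' the margin. Larger instances are sampled by `n_samples`
#' randomized restarts of [reconstruct()] under multiplicative edge-length
#' jitter (`length * exp(U(-0.1, 0.1))`), filtered by the margin threshold
#' on the true lengths and deduplicated by edge set. Each node's confidence
#' is the fraction of ensemble members containing it. Deterministic for a
#' fixed seed: the candidate pool is drawn first and filtered afterwards, so
#' the member set grows monotonically with the margin.
#'
#' @param q a [query_instance()] (its `margin` field is used).
#' @param n_samples number of randomized restarts (sampled mode).
#' @param seed integer seed for the jitter stream.
#' @return object of class `solution_ensemble`: list with `instance`,
#'   `optimum`, `members` (list of subnetworks), `node_confidence` (named
#'   numeric in `[0, 1]`), and `exact` (logical).
#' @export
enumerate_ensemble <- function(q, n_samples = 20L, seed = 1L) {
  stopifnot(inherits(q, "query_instance"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  exact <- length(q$network$nodes) <= 12L
  if (exact) {
    idx <- index_graph(q)
    opt_res <- .tree_search_cpp(idx$n + 1L, idx$und_from - 1L,
                                idx$und_to - 1L, idx$und_len, idx$root - 1L,
                                idx$term_idx - 1L, idx$anchor_idx - 1L,
                                q$alpha, Inf, FALSE, 1e8)
    if (!is.finite(opt_res$objective)) stop("no feasible anchored tree found")
    bound <- q$margin * opt_res$objective + 1e-9
    all_res <- .tree_search_cpp(idx$n + 1L, idx$und_from - 1L,
                                idx$und_to - 1L, idx$und_len, idx$root - 1L,
                                idx$term_idx - 1L, idx$anchor_idx - 1L,
                                q$alpha, bound, TRUE, 1e8)
    members <- lapply(all_res$members,
                      function(e) subnetwork_from_eids(q, idx, e + 1L))
    optimum <- subnetwork_from_eids(q, idx, opt_res$edges + 1L)
  } else {
    optimum <- reconstruct(q)
    base_len <- edge_length(q$network$edges$confidence)
    pool <- list(optimum)
    with_seed(seed, {
      for (i in seq_len(n_samples)) {
        jit <- base_len * exp(runif(length(base_len), -0.1, 0.1))
        H <- tryCatch(reconstruct(q, lengths = jit), error = function(e) NULL)
        if (!is.null(H)) pool[[length(pool) + 1L]] <- H
      }
    })
    keys <- vapply(pool, function(H) paste(edge_key(H$edges$u, H$edges$v),
                                           collapse = ";"), "")
    pool <- pool[!duplicated(keys)]
    objs <- vapply(pool, function(H) H$objective, 0)
    # a jittered restart can beat the heuristic baseline on large instances
    if (min(objs) < optimum$objective) optimum <- pool[[which.min(objs)]]
    members <- pool[objs <= q$margin * optimum$objective + 1e-9]
  }
  # order members for reproducible output
  mkey <- vapply(members, function(H) paste(edge_key(H$edges$u, H$edges$v),
                                            collapse = ";"), "")
  members <- members[order(vapply(members, `[[`, 0, "objective"), mkey)]
  counts <- table(unlist(lapply(members, `[[`, "nodes")))
  conf <- setNames(as.numeric(counts) / length(members), names(counts))
  structure(list(instance = q, optimum = optimum, members = members,
                 node_confidence = conf, exact = exact, seed = seed),
            class = "solution_ensemble")
}

#' @export
print.solution_ensemble <- function(x, ...) {
  cat("Solution ensemble:", length(x$members), "member(s) within margin",
      x$instance$margin, if (x$exact) "(exhaustive)" else "(sampled)", "\n")
  cat("  optimum objective:", format(x$optimum$objective, digits = 6), "\n")
  cat("  nodes with confidence 1:",
      sum(x$node_confidence >= 1 - 1e-12), "of", length(x$node_confidence),
      "\n")
  invisible(x)
}

#' @export
summary.solution_ensemble <- function(object, ...) {
  conf <- sort(object$node_confidence, decreasing = TRUE)
  out <- list(n_members = length(object$members),
              margin = object$instance$margin,
              optimum_objective = object$optimum$objective,
              node_confidence = conf)
  class(out) <- "summary.solution_ensemble"
  out
}

#' @export
print.summary.solution_ensemble <- function(x, ...) {
  cat("Ensemble of", x$n_members, "solution(s), margin", x$margin,
      ", optimum objective", format(x$optimum_objective, digits = 6), "\n")
  print(round(x$node_confidence, 3))
  invisible(x)
}

# node confidences of an ensemble as a data frame (plumbing for outputs)
confidence_table <- function(ens) {
  q <- ens$instance
  nodes <- names(ens$node_confidence)
  data.frame(node = nodes,
             confidence = unname(ens$node_confidence),
             is_anchor = nodes %in% q$anchors,
             is_terminal = nodes %in% q$terminals,
             stringsAsFactors = FALSE)
}
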