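# Weighted undirected interaction networks: construction, I/O, merging.

#' Construct an interaction network
#'
#' An interaction network is an undirected weighted graph over protein
#' identifiers. Each edge carries a confidence in (0, 1], an optional source
#' tag (e.g. `"biogrid"`, `"intact"`, `"kegg"`) and an optional
#' detection-method ontology term. Edges are stored with at most one entry
#' per unordered pair; duplicate pairs are collapsed to the maximum
#' confidence with a warning.
#'
#' @param edges data frame with columns `u`, `v`, `confidence` and optionally
#'   `source`, `method`. Self loops are rejected.
#' @param nodes optional character vector of node identifiers; edge endpoints
#'   are always included.
#' @return an object of class `interaction_network` with elements `nodes`
#'   (character) and `edges` (data frame `u`, `v`, `confidence`, `source`,
#'   `method`, with `u < v` lexicographically).
#' @examples
#' net <- interaction_network(data.frame(u = "A", v = "B", confidence = 0.9))
#' net
#' @export
interaction_network <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(u = character(), v = character(),
                        confidence = numeric(), source = character(),
                        method = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("u", "v", "confidence") %in% names(edges)))
    edges$u <- as.character(edges$u)
    edges$v <- as.character(edges$v)
    edges$confidence <- as.numeric(edges$confidence)
    if (is.null(edges$source)) edges$source <- NA_character_
    if (is.null(edges$method)) edges$method <- NA_character_
    edges <- edges[, c("u", "v", "confidence", "source", "method")]
    bad_id <- !nzchar(edges$u) | !nzchar(edges$v) |
      grepl("\\s", edges$u) | grepl("\\s", edges$v)
    if (any(bad_id))
      stop("invalid node identifier (empty or contains whitespace) in edge ",
           which(bad_id)[1])
    if (any(edges$u == edges$v))
      stop("self-loop rejected: node ", edges$u[edges$u == edges$v][1])
    if (any(edges$confidence <= 0 | edges$confidence > 1 |
            !is.finite(edges$confidence)))
      stop("edge confidence must lie in (0, 1]")
    p <- canonical_pairs(edges$u, edges$v)
    edges$u <- p$u; edges$v <- p$v
    key <- paste(edges$u, edges$v, sep = "\t")
    if (anyDuplicated(key)) {
      warning(sum(duplicated(key)),
              " duplicate edge pair(s) collapsed; keeping maximum confidence")
      ord <- order(key, -edges$confidence)
      edges <- edges[ord, , drop = FALSE]
      edges <- edges[!duplicated(key[ord]), , drop = FALSE]
    }
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), edges$u, edges$v)))
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0) {
    cat("  confidence range: [", format(min(x$edges$confidence)), ", ",
        format(max(x$edges$confidence)), "]\n", sep = "")
    src <- table(x$edges$source, useNA = "ifany")
    cat("  sources:", paste(names(src), src, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Read a tab-separated edge list
#'
#' Columns are `u`, `v`, `confidence` and optionally `source` and
#' `method` (a detection-method ontology term). A header line is detected by
#' a non-numeric third field on the first line. Duplicate unordered pairs
#' within one file keep the maximum confidence (with a warning). Malformed
#' lines — wrong column count, confidence outside (0, 1], self loops — abort
#' with the offending line number.
#'
#' @param path file path.
#' @return an [interaction_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(interaction_network())
  fields <- strsplit(trimws(lines), "[\t ]+")
  start <- 1L
  first <- fields[[1]]
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3]))))
    start <- 2L
  if (start > length(lines)) return(interaction_network())
  rows <- vector("list", length(lines) - start + 1L)
  for (i in seq(start, length(lines))) {
    f <- fields[[i]]
    if (length(f) < 3 || length(f) > 5)
      stop("malformed edge list line ", i, " in ", path,
           ": expected 3-5 tab-separated fields, got ", length(f))
    conf <- suppressWarnings(as.numeric(f[3]))
    if (is.na(conf) || conf <= 0 || conf > 1)
      stop("malformed edge list line ", i, " in ", path,
           ": confidence must be a number in (0, 1], got '", f[3], "'")
    if (f[1] == f[2])
      stop("malformed edge list line ", i, " in ", path,
           ": self-loop on node '", f[1], "'")
    rows[[i - start + 1L]] <- data.frame(
      u = f[1], v = f[2], confidence = conf,
      source = if (length(f) >= 4) f[4] else NA_character_,
      method = if (length(f) >= 5) f[5] else NA_character_,
      stringsAsFactors = FALSE)
  }
  interaction_network(do.call(rbind, rows))
}

#' Write an interaction network to disk
#'
#' `tsv` writes the same dialect [read_edge_list()] consumes and round-trips
#' node set, edge set and confidences exactly. `sif` writes `u pp v` lines
#' with confidences in a sidecar `<path>.attrs` tsv.
#'
#' @param net an [interaction_network()].
#' @param path output file path.
#' @param format `"tsv"` or `"sif"`.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "interaction_network"))
  e <- net$edges
  if (format == "tsv") {
    lines <- c("u\tv\tconfidence\tsource\tmethod",
               if (nrow(e) > 0)
                 paste(e$u, e$v, sprintf("%.17g", e$confidence),
                       ifelse(is.na(e$source), "NA", e$source),
                       ifelse(is.na(e$method), "NA", e$method), sep = "\t"))
    writeLines(lines, path)
  } else {
    writeLines(if (nrow(e) > 0) paste(e$u, "pp", e$v, sep = "\t")
               else character(), path)
    writeLines(c("u\tv\tconfidence",
                 if (nrow(e) > 0)
                   paste(e$u, e$v, sprintf("%.17g", e$confidence), sep = "\t")),
               paste0(path, ".attrs"))
  }
  invisible(NULL)
}

#' Merge two interaction networks
#'
#' Takes the union of edges of both networks. For unordered pairs present in
#' both, the merged confidence is the maximum of the two, the source tag
#' becomes `"both"`, and discordant detection-method terms are reconciled to
#' their lowest common ancestor in the method ontology
#' (see [lowest_common_method()]).
#'
#' @param primary,secondary [interaction_network()] objects.
#' @param ont a [method_ontology()], required only when shared pairs carry
#'   discordant method terms.
#' @return the merged [interaction_network()].
#' @export
merge_networks <- function(primary, secondary, ont = NULL) {
  stopifnot(inherits(primary, "interaction_network"),
            inherits(secondary, "interaction_network"))
  e1 <- primary$edges; e2 <- secondary$edges
  k1 <- paste(e1$u, e1$v, sep = "\t")
  k2 <- paste(e2$u, e2$v, sep = "\t")
  shared <- intersect(k1, k2)
  out <- rbind(e1[!(k1 %in% shared), , drop = FALSE],
               e2[!(k2 %in% shared), , drop = FALSE])
  if (length(shared)) {
    a <- e1[match(shared, k1), , drop = FALSE]
    b <- e2[match(shared, k2), , drop = FALSE]
    method <- mapply(function(ma, mb) {
      if (is.na(ma)) return(mb)
      if (is.na(mb)) return(ma)
      if (ma == mb) return(ma)
      if (is.null(ont))
        stop("discordant method terms on a shared pair require an ontology")
      lowest_common_method(ma, mb, ont)
    }, a$method, b$method, USE.NAMES = FALSE)
    merged <- data.frame(u = a$u, v = a$v,
                         confidence = pmax(a$confidence, b$confidence),
                         source = "both", method = method,
                         stringsAsFactors = FALSE)
    out <- rbind(out, merged)
  }
  interaction_network(out, nodes = union(primary$nodes, secondary$nodes))
}

# igraph view of a network, with -log(confidence) edge lengths
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  igraph::E(g)$confidence <- net$edges$confidence
  igraph::E(g)$weight <- edge_length(net$edges$confidence)
  g
}

# induced subgraph edges of `net` on a node set (data frame subset)
induced_edges <- function(net, nodes) {
  e <- net$edges
  e[e$u %in% nodes & e$v %in% nodes, , drop = FALSE]
}
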