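# Directed pathway graphs: KGML reader, conversion to undirected interaction
# edges, and degree-based anchor/terminal extraction for training sets.

#' Construct a directed pathway graph
#'
#' @param name pathway name.
#' @param nodes data frame with columns `id` and `kind` in
#'   `{"protein", "group", "compound"}`.
#' @param directed_edges data frame with columns `from`, `to` referencing
#'   declared nodes.
#' @param group_members named list: group node id -> character vector of
#'   member protein ids (non-empty for every group node).
#' @return object of class `pathway_graph`.
#' @export
pathway_graph <- function(name, nodes, directed_edges = NULL,
                          group_members = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "kind") %in% names(nodes)),
            all(nodes$kind %in% c("protein", "group", "compound")))
  if (anyDuplicated(nodes$id)) stop("duplicate pathway node id")
  if (is.null(directed_edges) || NROW(directed_edges) == 0) {
    directed_edges <- data.frame(from = character(), to = character(),
                                 stringsAsFactors = FALSE)
  } else {
    directed_edges <- as.data.frame(directed_edges, stringsAsFactors = FALSE)
    stopifnot(all(c("from", "to") %in% names(directed_edges)))
    miss <- setdiff(c(directed_edges$from, directed_edges$to), nodes$id)
    if (length(miss))
      stop("directed edge references undeclared node(s): ",
           paste(miss, collapse = ", "))
  }
  grp <- nodes$id[nodes$kind == "group"]
  for (g in grp) {
    if (length(group_members[[g]] %||% character()) < 1)
      stop("group node ", g, " has no members")
  }
  structure(list(name = name, nodes = nodes,
                 directed_edges = directed_edges,
                 group_members = group_members[grp]),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  k <- table(factor(x$nodes$kind, c("protein", "group", "compound")))
  cat("Pathway graph '", x$name, "': ", k[["protein"]], " proteins, ",
      k[["group"]], " groups, ", k[["compound"]], " compounds, ",
      nrow(x$directed_edges), " directed edges\n", sep = "")
  invisible(x)
}

#' Read a KGML pathway file
#'
#' Parses the KGML XML subset used for pathway exchange: `entry` elements of
#' type `gene`, `compound` or `group` (the latter with `component` children)
#' become nodes; `relation` elements with `entry1`/`entry2` become directed
#' edges. Gene entries use the first token of their `name` attribute as the
#' node identifier.
#'
#' @param path KGML file path.
#' @return a [pathway_graph()].
#' @export
read_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("KGML parse failure for ", path,
                                           ": ", conditionMessage(e)))
  pw_name <- xml2::xml_attr(doc, "title")
  if (is.na(pw_name)) pw_name <- xml2::xml_attr(doc, "name") %||% path
  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- character(); kinds <- character()
  entry_node <- character()  # KGML entry id -> our node id
  group_members <- list()
  for (e in entries) {
    type <- xml2::xml_attr(e, "type")
    eid <- xml2::xml_attr(e, "id")
    if (!type %in% c("gene", "compound", "group")) next
    if (type == "group") {
      comps <- xml2::xml_attr(xml2::xml_find_all(e, ".//component"), "id")
      nid <- paste0("group_", eid)
      ids <- c(ids, nid); kinds <- c(kinds, "group")
      entry_node[eid] <- nid
      group_members[[nid]] <- comps  # resolved to member ids below
    } else {
      nm <- xml2::xml_attr(e, "name")
      nid <- if (is.na(nm) || !nzchar(nm)) paste0("entry_", eid)
             else strsplit(nm, "\\s+")[[1]][1]
      ids <- c(ids, nid)
      kinds <- c(kinds, if (type == "gene") "protein" else "compound")
      entry_node[eid] <- nid
    }
  }
  # resolve group component entry ids to node ids
  for (g in names(group_members)) {
    comp_ids <- group_members[[g]]
    miss <- setdiff(comp_ids, names(entry_node))
    if (length(miss))
      stop("group ", g, " references unknown component entry id(s): ",
           paste(miss, collapse = ", "))
    group_members[[g]] <- unname(entry_node[comp_ids])
  }
  rel <- xml2::xml_find_all(doc, ".//relation")
  from <- character(); to <- character()
  for (r in rel) {
    e1 <- xml2::xml_attr(r, "entry1"); e2 <- xml2::xml_attr(r, "entry2")
    if (!e1 %in% names(entry_node) || !e2 %in% names(entry_node))
      stop("relation references unknown entry id (entry1=", e1,
           ", entry2=", e2, ")")
    from <- c(from, entry_node[[e1]]); to <- c(to, entry_node[[e2]])
  }
  keep <- !duplicated(ids)
  pathway_graph(pw_name,
                data.frame(id = ids[keep], kind = kinds[keep],
                           stringsAsFactors = FALSE),
                data.frame(from = from, to = to, stringsAsFactors = FALSE),
                group_members)
}

# expand group nodes (clique over members + re-attachment of incident edges)
# and drop compound nodes; returns a pathway_graph with protein nodes only
expand_pathway <- function(pw) {
  stopifnot(inherits(pw, "pathway_graph"))
  kind <- setNames(pw$nodes$kind, pw$nodes$id)
  # group members need not be declared as entries; default to protein
  kindof <- function(ids) ifelse(ids %in% names(kind), kind[ids], "protein")
  members_of <- function(id) {
    if (kindof(id) == "group") pw$group_members[[id]] else id
  }
  de <- pw$directed_edges
  from <- character(); to <- character()
  if (nrow(de) > 0) for (i in seq_len(nrow(de))) {
    fs <- members_of(de$from[i]); ts <- members_of(de$to[i])
    # edges touching compounds are dropped together with the compound
    fs <- fs[kindof(fs) != "compound"]; ts <- ts[kindof(ts) != "compound"]
    if (length(fs) && length(ts)) {
      grid <- expand.grid(f = fs, t = ts, stringsAsFactors = FALSE)
      grid <- grid[grid$f != grid$t, , drop = FALSE]
      from <- c(from, grid$f); to <- c(to, grid$t)
    }
  }
  dropped <- pw$nodes$id[pw$nodes$kind == "compound"]
  if (length(dropped))
    message("dropping ", length(dropped), " compound node(s): ",
            paste(dropped, collapse = ", "))
  proteins <- pw$nodes$id[pw$nodes$kind == "protein"]
  # intra-group cliques as symmetric directed pairs (undirected semantics)
  for (g in names(pw$group_members)) {
    mem <- pw$group_members[[g]]
    if (length(mem) >= 2) {
      cmb <- utils::combn(sort(mem), 2)
      from <- c(from, cmb[1, ], cmb[2, ])
      to <- c(to, cmb[2, ], cmb[1, ])
    }
    proteins <- union(proteins, mem)
  }
  keep <- !duplicated(paste(from, to))
  pathway_graph(pw$name,
                data.frame(id = sort(unique(proteins)), kind = "protein",
                           stringsAsFactors = FALSE),
                data.frame(from = from[keep], to = to[keep],
                           stringsAsFactors = FALSE))
}

#' Convert a pathway graph to undirected interaction edges
#'
#' Compound nodes (small metabolites) and their incident edges are dropped
#' without bridging their neighbours. Each group node is decomposed into a
#' fully connected subnetwork over its members, and every edge incident to
#' the group is re-attached to every member. All output edges are undirected
#' and carry the uniform pathway confidence (default 0.6) with source
#' `"kegg"`.
#'
#' @param pw a [pathway_graph()].
#' @param kegg_confidence uniform confidence for pathway-derived edges.
#' @return an [interaction_network()].
#' @export
pathway_to_network <- function(pw, kegg_confidence = 0.6) {
  stopifnot(kegg_confidence > 0, kegg_confidence <= 1)
  ex <- expand_pathway(pw)
  de <- ex$directed_edges
  if (nrow(de) == 0)
    return(interaction_network(nodes = ex$nodes$id))
  p <- canonical_pairs(de$from, de$to)
  keep <- !duplicated(paste(p$u, p$v))
  interaction_network(
    data.frame(u = p$u[keep], v = p$v[keep], confidence = kegg_confidence,
               source = "kegg", method = NA_character_,
               stringsAsFactors = FALSE),
    nodes = ex$nodes$id)
}

#' Extract anchors and terminals from a directed pathway
#'
#' After group expansion and compound removal, anchors are protein nodes
#' with no inward edges (and at least one outward edge) and terminals are
#' protein nodes with no outward edges (and at least one inward edge).
#' Isolated nodes belong to neither set and are reported with a warning.
#'
#' @param pw a [pathway_graph()].
#' @return list with character vectors `anchors` and `terminals`.
#' @export
extract_anchors_terminals <- function(pw) {
  ex <- expand_pathway(pw)
  ids <- ex$nodes$id
  de <- ex$directed_edges
  indeg <- table(factor(de$to, levels = ids))
  outdeg <- table(factor(de$from, levels = ids))
  isolated <- ids[indeg == 0 & outdeg == 0]
  if (length(isolated))
    warning("excluding ", length(isolated), " isolated pathway node(s): ",
            paste(isolated, collapse = ", "))
  anchors <- ids[indeg == 0 & outdeg > 0]
  terminals <- ids[outdeg == 0 & indeg > 0]
  if (length(anchors) == 0 || length(terminals) == 0)
    stop("pathway '", pw$name,
         "' yields an empty anchor or terminal set; unusable for training")
  list(anchors = anchors, terminals = terminals)
}
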