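# Detection-method ontology (PSI-MI style): OBO subset reader and
# lowest-common-ancestor reconciliation used when merging databases.

#' Construct a detection-method ontology
#'
#' A rooted DAG of term identifiers under an `is_a` relation. Every non-root
#' term must reach the single root (the term with no parents).
#'
#' @param is_a named list: term id -> character vector of parent term ids
#'   (empty for the root). All parents must themselves be terms.
#' @return object of class `method_ontology` with elements `terms`, `is_a`,
#'   `root`, and `depth` (longest is_a distance from the root).
#' @export
method_ontology <- function(is_a) {
  stopifnot(is.list(is_a), length(names(is_a)) == length(is_a))
  terms <- names(is_a)
  parents <- unique(unlist(is_a))
  if (!all(parents %in% terms))
    stop("unknown parent term(s): ",
         paste(setdiff(parents, terms), collapse = ", "))
  roots <- terms[vapply(is_a, length, 1L) == 0L]
  if (length(roots) != 1L)
    stop("ontology must have exactly one root, found ", length(roots))
  # verify acyclicity + reachability of root via ancestor closure
  anc <- ancestor_closure(is_a)
  root <- roots[1]
  if (!all(vapply(anc, function(a) root %in% a, TRUE)))
    stop("some terms do not reach the root")
  depth <- term_depths(is_a, root)
  structure(list(terms = terms, is_a = is_a, root = root,
                 ancestors = anc, depth = depth),
            class = "method_ontology")
}

# reflexive-transitive ancestor sets; stops on cycles
ancestor_closure <- function(is_a) {
  terms <- names(is_a)
  memo <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  rec <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (isTRUE(visiting[[t]])) stop("cycle detected at term ", t)
    visiting[[t]] <- TRUE
    out <- t
    for (p in is_a[[t]]) out <- union(out, rec(p))
    visiting[[t]] <- FALSE
    memo[[t]] <- out
    out
  }
  setNames(lapply(terms, rec), terms)
}

# longest path from root (root depth 0)
term_depths <- function(is_a, root) {
  memo <- new.env(parent = emptyenv())
  rec <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    d <- if (t == root) 0L else 1L + max(vapply(is_a[[t]], rec, 0L))
    memo[[t]] <- d
    d
  }
  setNames(vapply(names(is_a), rec, 0L), names(is_a))
}

#' @export
print.method_ontology <- function(x, ...) {
  cat("Method ontology:", length(x$terms), "terms, root", x$root,
      ", max depth", max(x$depth), "\n")
  invisible(x)
}

#' Read an OBO-format ontology (id / name / is_a stanzas)
#'
#' Minimal reader for the flat OBO dialect used by detection-method
#' vocabularies: only `[Term]` stanzas with `id:`, `name:` and `is_a:` lines
#' are interpreted; everything else is ignored.
#'
#' @param path OBO file path.
#' @return a [method_ontology()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  is_a <- list()
  names_map <- character()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {}
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; cur <- NULL; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
      if (is.null(is_a[[cur]])) is_a[[cur]] <- character()
    } else if (startsWith(ln, "name:") && !is.null(cur)) {
      names_map[[cur]] <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_a:") && !is.null(cur)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      is_a[[cur]] <- union(is_a[[cur]], parent)
    }
  }
  ont <- method_ontology(is_a)
  ont$names <- names_map
  ont
}

#' Lowest common ancestral detection method
#'
#' Returns the deepest common ancestor of two terms under the
#' reflexive-transitive `is_a` relation; used to reconcile discordant
#' experimental detection methods when the same interaction appears in two
#' databases. Ties on depth are broken by the lexicographically smallest
#' term id; `lowest_common_method(a, a)` is `a`.
#'
#' @param a,b term identifiers present in `ont`.
#' @param ont a [method_ontology()].
#' @return a term identifier.
#' @export
lowest_common_method <- function(a, b, ont) {
  stopifnot(inherits(ont, "method_ontology"))
  for (t in c(a, b)) if (!t %in% ont$terms)
    stop("unknown ontology term: ", t)
  common <- intersect(ont$ancestors[[a]], ont$ancestors[[b]])
  d <- ont$depth[common]
  deepest <- common[d == max(d)]
  sort(deepest)[1]
}
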