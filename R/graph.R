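#' Directed acyclic is_a graphs over ontology terms
#'
#' A `term_graph` models the subclass structure of an ontology as a DAG:
#' a node set of term ids and a set of direct `(child, parent)` is_a edges.
#' Only `is_a` edges participate in classification; other relationship types
#' are carried through I/O but ignored here, so no unsound part-of style
#' propagation can occur. Multiple roots are permitted (the GO itself has
#' three).
#'
#' @param nodes character vector of term ids.
#' @param edges data frame with columns `child` and `parent`.
#' @return an object of class `term_graph` with fields `nodes`, `edges` and
#'   `roots` (nodes with no parent).
#' @export
term_graph <- function(nodes, edges = empty_edges()) {
  nodes <- sort_c(unique(curie_short(nodes)))
  edges <- edge_df(curie_short(edges$child), curie_short(edges$parent))
  bad <- setdiff(unique(c(edges$child, edges$parent)), nodes)
  if (length(bad) > 0) {
    stop_eqonto("eqonto_unknown_id",
                paste0("edge endpoints not in node set: ",
                       paste(sort_c(bad), collapse = ", ")))
  }
  edges <- normalize_edges(edges)
  assert_acyclic(edges)
  structure(list(nodes = nodes, edges = edges,
                 roots = sort_c(setdiff(nodes, edges$child))),
            class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("<term_graph: %d nodes, %d edges, %d root(s)>\n",
              length(x$nodes), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Build a term graph from a parsed OBO document
#'
#' Uses the asserted `is_a` edges among the document's non-obsolete,
#' non-anonymous terms. Edges pointing at ids absent from the document are
#' dropped (they are reported separately by [document_findings()]).
#'
#' @param doc an [obo_document()].
#' @return a [term_graph()].
#' @export
graph_from_document <- function(doc) {
  keep <- Filter(function(t) !t$is_obsolete && !t$is_anonymous, doc$terms)
  ids <- vapply(keep, function(t) t$id, character(1))
  pairs <- do.call(rbind, c(list(empty_edges()), lapply(keep, function(t) {
    parents <- intersect(t$is_a, ids)
    if (length(parents) == 0) return(empty_edges())
    edge_df(t$id, parents)
  })))
  term_graph(ids, pairs)
}

# child -> character vector of direct parents
parent_map <- function(edges) {
  m <- new.env(parent = emptyenv())
  if (nrow(edges) > 0) {
    sp <- split(edges$parent, edges$child)
    for (ch in names(sp)) assign(ch, sp[[ch]], envir = m)
  }
  m
}

reach_up <- function(map, start) {
  seen <- character(0)
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(n) {
      if (exists(n, envir = map, inherits = FALSE))
        get(n, envir = map) else character(0)
    }), use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Ancestor and descendant queries
#'
#' `ancestors()` returns all strict ancestors of a term under the transitive
#' closure of the is_a relation; with `reflexive = TRUE` the term itself is
#' included. `descendants()` is the mirror image.
#'
#' @param graph a [term_graph()].
#' @param term a term id.
#' @param reflexive include the term itself?
#' @return a character vector of term ids, sorted.
#' @export
ancestors <- function(graph, term, reflexive = FALSE) {
  term <- curie_short(term)
  if (!(term %in% graph$nodes)) {
    stop_eqonto("eqonto_unknown_id", paste0("unknown term: ", term))
  }
  out <- reach_up(parent_map(graph$edges), term)
  if (reflexive) out <- c(out, term)
  sort_c(unique(out))
}

#' @rdname ancestors
#' @export
descendants <- function(graph, term, reflexive = FALSE) {
  term <- curie_short(term)
  if (!(term %in% graph$nodes)) {
    stop_eqonto("eqonto_unknown_id", paste0("unknown term: ", term))
  }
  flipped <- edge_df(graph$edges$parent, graph$edges$child)
  out <- reach_up(parent_map(flipped), term)
  if (reflexive) out <- c(out, term)
  sort_c(unique(out))
}

#' Paths-to-root module extraction
#'
#' Returns the sub-graph containing exactly the `used` terms plus every term
#' lying on some is_a path from a used term up to a root, with all edges
#' among the retained terms. This is the import strategy for external
#' ontologies: for every externally referenced term, import all terms and
#' axioms on its paths to root. With multiple roots, "root" means any root.
#'
#' @param graph a [term_graph()].
#' @param used character vector of term ids (must be nodes of `graph`).
#' @return a [term_graph()]; empty `used` yields the empty graph.
#' @export
extract_module <- function(graph, used) {
  used <- curie_short(used)
  bad <- setdiff(used, graph$nodes)
  if (length(bad) > 0) {
    stop_eqonto("eqonto_unknown_id",
                paste0("used terms not in graph: ",
                       paste(sort_c(bad), collapse = ", ")))
  }
  if (length(used) == 0) return(term_graph(character(0)))
  keep <- unique(c(used, unlist(lapply(used, ancestors, graph = graph),
                               use.names = FALSE)))
  edges <- graph$edges[graph$edges$child %in% keep &
                       graph$edges$parent %in% keep, , drop = FALSE]
  term_graph(keep, edges)
}

#' Transitive closure and reduction of a subclass edge set
#'
#' `transitive_closure_edges()` returns every `(child, ancestor)` pair
#' reachable through the input edges. `transitive_reduction()` returns the
#' unique minimal edge set with the same closure (for a DAG the reduction is
#' unique); its edges are the "direct" classifications reported in
#' inferred-vs-asserted statistics. Both produce deterministic ordering by
#' `(child, parent)`.
#'
#' @param edges data frame with columns `child`, `parent`; must be acyclic.
#' @return an edge data frame.
#' @export
transitive_closure_edges <- function(edges) {
  edges <- normalize_edges(edges)
  if (nrow(edges) == 0) return(edges)
  assert_acyclic(edges)
  map <- parent_map(edges)
  children <- sort_c(unique(edges$child))
  out <- lapply(children, function(ch) {
    anc <- reach_up(map, ch)
    edge_df(ch, anc)
  })
  normalize_edges(do.call(rbind, out))
}

#' @rdname transitive_closure_edges
#' @export
transitive_reduction <- function(edges) {
  edges <- normalize_edges(edges)
  if (nrow(edges) == 0) return(edges)
  assert_acyclic(edges)
  closure <- transitive_closure_edges(edges)
  ckeys <- edge_keys(closure)
  map <- parent_map(edges)
  keep <- vapply(seq_len(nrow(edges)), function(i) {
    ch <- edges$child[i]; pa <- edges$parent[i]
    others <- setdiff(get(ch, envir = map), pa)
    # (ch, pa) is redundant iff pa is reachable via some other direct parent
    !any(paste(others, pa, sep = "\r") %in% ckeys)
  }, logical(1))
  normalize_edges(edges[keep, , drop = FALSE])
}

# Raise a structured error naming one cycle if the edge set is cyclic.
assert_acyclic <- function(edges) {
  if (nrow(edges) == 0) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (igraph::is_dag(g)) return(invisible(TRUE))
  cyc <- find_one_cycle(edges)
  stop_eqonto("eqonto_cycle",
              paste0("cycle detected: ", paste(cyc, collapse = " -> ")))
}

find_one_cycle <- function(edges) {
  map <- parent_map(edges)
  color <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(n) {
    if (!is.null(found)) return()
    state <- if (exists(n, envir = color, inherits = FALSE))
      get(n, envir = color) else "white"
    if (state == "gray") {
      i <- match(n, path)
      found <<- c(path[seq(i, length(path))], n)
      return()
    }
    if (state == "black") return()
    assign(n, "gray", envir = color)
    path <<- c(path, n)
    for (p in if (exists(n, envir = map, inherits = FALSE))
         get(n, envir = map) else character(0)) {
      visit(p)
    }
    path <<- path[-length(path)]
    assign(n, "black", envir = color)
  }
  for (n in sort_c(unique(edges$child))) visit(n)
  found
}
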