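#' Structural subsumption between EQ definitions
#'
#' Decides `d1` is-subsumed-by `d2` in the existential-conjunctive fragment:
#' every conjunct of `d2` must be entailed by `d1`, where filler entailment
#' is reflexive ancestor containment in the imported DAGs. Concretely,
#' `quality(d1)` must be `quality(d2)` or one of its descendants; if `d2`
#' carries an `inheres_in` (or `towards`) filler then `d1` must carry one
#' subsumed by it; and an abnormal qualifier on `d2` requires one on `d1`.
#' Unions follow the usual rules: `(A or B)` is subsumed by `d2` iff both
#' operands are, and `d1` is subsumed by `(A or B)` iff it is subsumed by
#' either operand.
#'
#' @param d1,d2 [eq_definition()] objects.
#' @param imports named list of [term_graph()] objects; fillers are looked
#'   up across all of them.
#' @return `TRUE` or `FALSE`. Unresolved fillers raise an error rather than
#'   silently returning `FALSE`.
#' @export
eq_subsumes <- function(d1, d2, imports) {
  stopifnot(inherits(d1, "eq_definition"), inherits(d2, "eq_definition"))
  problems <- c(validate_definition(d1, imports),
                validate_definition(d2, imports))
  unresolved <- grep("unresolved", problems, value = TRUE)
  if (length(unresolved) > 0) {
    stop_eqonto("eqonto_unresolved", paste(unresolved, collapse = "; "))
  }
  known <- import_node_set(imports)
  map <- import_parent_map(imports)
  eq_subsumes_impl(d1, d2, known, map)
}

eq_subsumes_impl <- function(d1, d2, known, map) {
  if (is_eq_union(d1)) {
    return(all(vapply(d1$operands, eq_subsumes_impl, logical(1),
                      d2 = d2, known = known, map = map)))
  }
  if (is_eq_union(d2)) {
    return(any(vapply(d2$operands, eq_subsumes_impl, logical(1),
                      d1 = d1, known = known, map = map)))
  }
  if (!filler_subsumed(d1$quality, d2$quality, known, map)) return(FALSE)
  if (d2$abnormal && !d1$abnormal) return(FALSE)
  if (!is.null(d2$entity)) {
    if (is.null(d1$entity) ||
        !filler_subsumed(d1$entity, d2$entity, known, map)) return(FALSE)
  }
  if (!is.null(d2$towards)) {
    if (is.null(d1$towards) ||
        !filler_subsumed(d1$towards, d2$towards, known, map)) return(FALSE)
  }
  TRUE
}

# a subsumed-by b under reflexive transitive closure of is_a.
filler_subsumed <- function(a, b, known, map) {
  if (!(a %in% known)) {
    stop_eqonto("eqonto_unresolved", paste0("unresolved filler: ", a))
  }
  if (!(b %in% known)) {
    stop_eqonto("eqonto_unresolved", paste0("unresolved filler: ", b))
  }
  a == b || b %in% reach_up(map, a)
}

make_inferred_hierarchy <- function(direct_edges, provenance,
                                    equivalence_groups, closure_edges,
                                    nodes) {
  structure(list(direct_edges = direct_edges, provenance = provenance,
                 equivalence_groups = equivalence_groups,
                 closure_edges = closure_edges, nodes = nodes),
            class = "inferred_hierarchy")
}

#' @export
print.inferred_hierarchy <- function(x, ...) {
  cat(sprintf(paste0("<inferred_hierarchy: %d terms, %d direct edges ",
                     "(%d inferred), %d equivalence group(s)>\n"),
              length(x$nodes), nrow(x$direct_edges),
              sum(x$provenance == "inferred"), length(x$equivalence_groups)))
  invisible(x)
}

#' Classify a phenotype ontology against its imports
#'
#' Computes the inferred subclass hierarchy of a document whose terms carry
#' EQ pattern definitions. An inferred edge `X -> Y` exists (in the closure)
#' whenever `X`'s definition is structurally subsumed by `Y`'s and `Y`'s
#' definition is an equivalent-class axiom; terms with necessary-only
#' definitions gain inferred ancestors but never gain descendants through
#' their definition. Asserted `is_a` edges are retained and merged. The
#' result is transitively reduced, each surviving direct edge annotated with
#' `"asserted"` or `"inferred"` provenance. Pairs of terms that subsume each
#' other are reported as an equivalence group (with a warning -- curator
#' feedback, not an error) and collapsed onto their lexicographically least
#' member for the reduced edge set.
#'
#' @param doc an [obo_document()] whose terms carry pattern definitions.
#' @param imports named list of [term_graph()] objects for the entity
#'   ontologies referenced by the definitions.
#' @return an object of class `inferred_hierarchy` with fields
#'   `direct_edges`, `provenance`, `equivalence_groups`, `closure_edges`
#'   and `nodes`.
#' @export
classify <- function(doc, imports) {
  terms <- Filter(function(t) !t$is_obsolete && !t$is_anonymous, doc$terms)
  ids <- sort_c(vapply(terms, function(t) t$id, character(1)))
  defs <- lapply(ids, function(id) term_definition(doc, id))
  names(defs) <- ids

  # pre-validate so classification fails loudly on unresolved fillers
  for (id in ids) {
    d <- defs[[id]]
    if (is.null(d)) next
    problems <- validate_definition(d, imports)
    if (length(problems) > 0) {
      stop_eqonto("eqonto_unresolved",
                  paste0("definition of ", id, " does not validate: ",
                         paste(problems, collapse = "; ")))
    }
  }

  asserted <- do.call(rbind, c(list(empty_edges()), lapply(ids, function(id) {
    parents <- intersect(doc$terms[[id]]$is_a, ids)
    if (length(parents) == 0) return(empty_edges())
    edge_df(id, parents)
  })))
  asserted <- normalize_edges(asserted)
  assert_acyclic(asserted)

  known <- import_node_set(imports)
  map <- import_parent_map(imports)
  has_def <- !vapply(defs, is.null, logical(1))
  equivalent_def <- vapply(defs, function(d) {
    !is.null(d) && isTRUE(d$equivalence)
  }, logical(1))

  inferred <- empty_edges()
  def_ids <- ids[has_def]
  for (x in def_ids) {
    for (y in ids[equivalent_def]) {
      if (x == y) next
      if (eq_subsumes_impl(defs[[x]], defs[[y]], known, map)) {
        inferred <- rbind(inferred, edge_df(x, y))
      }
    }
  }

  combined <- normalize_edges(rbind(asserted, inferred))

  # mutual subsumption -> equivalence groups (over the raw closure, which
  # may be cyclic through them)
  closure_keys <- raw_closure_keys(combined)
  groups <- equivalence_groups_from(closure_keys)
  if (length(groups) > 0) {
    warning(sprintf("inferred equivalence between distinct ids: %s",
                    paste(vapply(groups, paste, character(1), collapse = " = "),
                          collapse = "; ")),
            call. = FALSE)
  }

  rep_of <- stats::setNames(as.list(ids), ids)
  for (g in groups) {
    r <- sort_c(g)[1]
    for (m in g) rep_of[[m]] <- r
  }
  remap <- function(e) {
    if (nrow(e) == 0) return(e)
    normalize_edges(edge_df(unlist(rep_of[e$child], use.names = FALSE),
                            unlist(rep_of[e$parent], use.names = FALSE)))
  }
  collapsed <- remap(combined)
  collapsed <- collapsed[collapsed$child != collapsed$parent, , drop = FALSE]

  direct <- transitive_reduction(collapsed)
  asserted_keys <- edge_keys(remap(asserted))
  provenance <- ifelse(edge_keys(direct) %in% asserted_keys,
                       "asserted", "inferred")

  closure <- closure_from_keys(closure_keys)
  make_inferred_hierarchy(direct, provenance, groups, closure, ids)
}

# Closure keys over a possibly-cyclic edge set (cycles arise only through
# mutually subsuming definitions); plain worklist reachability.
raw_closure_keys <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  map <- parent_map(edges)
  children <- sort_c(unique(edges$child))
  unlist(lapply(children, function(ch) {
    anc <- setdiff(reach_up_cyclic(map, ch), ch)
    if (length(anc) == 0) return(character(0))
    paste(ch, anc, sep = "\r")
  }), use.names = FALSE)
}

reach_up_cyclic <- function(map, start) {
  seen <- character(0)
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(n) {
      if (exists(n, envir = map, inherits = FALSE))
        get(n, envir = map) else character(0)
    }), use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, start))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

equivalence_groups_from <- function(closure_keys) {
  if (length(closure_keys) == 0) return(list())
  parts <- strsplit(closure_keys, "\r", fixed = TRUE)
  ch <- vapply(parts, `[`, character(1), 1)
  pa <- vapply(parts, `[`, character(1), 2)
  mutual <- closure_keys %in% paste(pa, ch, sep = "\r")
  if (!any(mutual)) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = ch[mutual], to = pa[mutual]), directed = FALSE)
  comps <- igraph::components(g)
  split(names(comps$membership), comps$membership) |>
    lapply(sort_c) |>
    unname()
}

closure_from_keys <- function(keys) {
  if (length(keys) == 0) return(empty_edges())
  parts <- strsplit(keys, "\r", fixed = TRUE)
  normalize_edges(edge_df(vapply(parts, `[`, character(1), 1),
                          vapply(parts, `[`, character(1), 2)))
}

#' Query subclasses in an inferred hierarchy
#'
#' @param hierarchy an `inferred_hierarchy` from [classify()] or
#'   [classify_lethal()].
#' @param id a term id.
#' @param direct if `TRUE`, only direct children from the transitively
#'   reduced edge set; otherwise all (transitive) subclasses from the
#'   closure.
#' @return sorted character vector of subclass ids.
#' @export
subclasses_of <- function(hierarchy, id, direct = FALSE) {
  id <- curie_short(id)
  edges <- if (direct) hierarchy$direct_edges else hierarchy$closure_edges
  sort_c(unique(edges$child[edges$parent == id]))
}

#' @rdname subclasses_of
#' @export
superclasses_of <- function(hierarchy, id, direct = FALSE) {
  id <- curie_short(id)
  edges <- if (direct) hierarchy$direct_edges else hierarchy$closure_edges
  sort_c(unique(edges$parent[edges$child == id]))
}

#' Asserted-versus-inferred classification statistics
#'
#' Counts the direct classifications (edges of the transitively reduced
#' hierarchy) and how many of them are inferred rather than asserted, the
#' headline measure of how much classification the pattern definitions buy.
#' The percentage uses half-up rounding. Counts can be supplied directly
#' (`n_direct`, `n_inferred`), or derived from a classification `result`,
#' in which case an edge counts as inferred when it is absent from the
#' asserted direct-edge set.
#'
#' @param result an `inferred_hierarchy`, or `NULL` when counts are given.
#' @param asserted optional [term_graph()] of the asserted hierarchy; when
#'   omitted, the result's own provenance annotation is used.
#' @param n_direct,n_inferred direct counts, bypassing `result`.
#' @return an object of class `inference_stats` with fields `n_direct`,
#'   `n_inferred`, `fraction_inferred`, `percent_inferred`.
#' @examples
#' inference_stats(n_direct = 305, n_inferred = 258)$percent_inferred  # 85
#' @export
inference_stats <- function(result = NULL, asserted = NULL,
                            n_direct = NULL, n_inferred = NULL) {
  if (is.null(n_direct)) {
    stopifnot(inherits(result, "inferred_hierarchy"))
    n_direct <- nrow(result$direct_edges)
    if (is.null(asserted)) {
      n_inferred <- sum(result$provenance == "inferred")
    } else {
      n_inferred <- sum(!(edge_keys(result$direct_edges) %in%
                            edge_keys(asserted$edges)))
    }
  }
  if (n_inferred > n_direct) {
    stop_eqonto("eqonto_usage_error",
                "n_inferred cannot exceed n_direct")
  }
  fraction <- if (n_direct == 0) 0 else n_inferred / n_direct
  structure(list(n_direct = as.integer(n_direct),
                 n_inferred = as.integer(n_inferred),
                 fraction_inferred = fraction,
                 percent_inferred = as.integer(floor(100 * fraction + 0.5))),
            class = "inference_stats")
}

#' @export
print.inference_stats <- function(x, ...) {
  cat(sprintf("%d/%d direct classifications inferred (%d%%)\n",
              x$n_inferred, x$n_direct, x$percent_inferred))
  invisible(x)
}
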