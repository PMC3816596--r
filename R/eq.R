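#' Entity-quality (EQ) phenotype definitions
#'
#' An EQ definition formalises a phenotype class as a PATO quality that
#' `inheres_in` some entity (a GO process, a CL cell type, an anatomical
#' structure), optionally `qualifier some abnormal` (PATO_0000460) and
#' optionally directed `towards` a second entity (used with relational
#' qualities such as 'has extra parts of type'). A definition is either an
#' equivalent-class axiom (necessary and sufficient conditions) or a
#' necessary-condition-only axiom; a union definition holds two or more
#' operand definitions and is satisfied by membership in any operand.
#'
#' @param quality quality term id (short form, e.g. `"PATO_0001552"`).
#' @param entity optional `inheres_in` filler id.
#' @param towards optional `towards` filler id; only meaningful alongside a
#'   quality.
#' @param abnormal logical; whether the `qualifier some abnormal` conjunct is
#'   present.
#' @param equivalence logical; `TRUE` for an equivalent-class definition,
#'   `FALSE` for necessary conditions only.
#' @param operands for [eq_union()], a list of `eq_definition` objects
#'   (at least two).
#' @return an object of class `eq_definition`.
#' @examples
#' # 'radiation resistant': decreased sensitivity of a process that
#' # inheres_in some 'response to radiation'
#' eq_definition("PATO_0001552", entity = "GO_0009314")
#' @export
eq_definition <- function(quality, entity = NULL, towards = NULL,
                          abnormal = FALSE, equivalence = TRUE) {
  if (is.null(quality) || !nzchar(quality)) {
    stop_eqonto("eqonto_pattern_error", "an EQ definition requires a quality (genus)")
  }
  if (!is.null(towards) && is.null(quality)) {
    stop_eqonto("eqonto_pattern_error", "'towards' is only valid alongside a quality")
  }
  structure(list(quality = curie_short(quality),
                 entity = if (!is.null(entity)) curie_short(entity),
                 towards = if (!is.null(towards)) curie_short(towards),
                 abnormal = isTRUE(abnormal),
                 operands = NULL,
                 equivalence = isTRUE(equivalence)),
            class = "eq_definition")
}

#' @rdname eq_definition
#' @export
eq_union <- function(operands, equivalence = TRUE) {
  if (!is.list(operands) || length(operands) < 2) {
    stop_eqonto("eqonto_pattern_error", "a union definition requires at least two operands")
  }
  if (!all(vapply(operands, inherits, logical(1), "eq_definition"))) {
    stop_eqonto("eqonto_pattern_error", "union operands must be eq_definition objects")
  }
  structure(list(quality = NULL, entity = NULL, towards = NULL,
                 abnormal = FALSE, operands = operands,
                 equivalence = isTRUE(equivalence)),
            class = "eq_definition")
}

#' @rdname eq_definition
#' @param x object to test or print.
#' @export
is_eq_union <- function(x) inherits(x, "eq_definition") && !is.null(x$operands)

#' @export
print.eq_definition <- function(x, ...) {
  cat(format_eq(x), "\n")
  invisible(x)
}

format_eq <- function(d) {
  if (is_eq_union(d)) {
    inner <- vapply(d$operands, format_eq, character(1))
    return(paste0(if (d$equivalence) "EquivalentTo " else "SubClassOf ",
                  "(", paste(inner, collapse = ") OR ("), ")"))
  }
  parts <- d$quality
  if (!is.null(d$entity)) parts <- c(parts, paste("inheres_in some", d$entity))
  if (d$abnormal) parts <- c(parts, "qualifier some PATO_0000460")
  if (!is.null(d$towards)) parts <- c(parts, paste("towards some", d$towards))
  paste0(if (d$equivalence) "EquivalentTo " else "SubClassOf ",
         paste(parts, collapse = " and "))
}

#' Validate an EQ definition against import graphs
#'
#' Checks that every filler id used by a definition resolves in the supplied
#' import graphs, that unions have at least two operands, and that `towards`
#' only appears alongside a quality. Problems are returned as findings, not
#' raised as errors, so a release run can report all of them at once.
#'
#' @param def an [eq_definition()].
#' @param imports a named list of [term_graph()] objects (one per imported
#'   ontology); lookups are performed across all of them.
#' @return a character vector of findings; empty when the definition is valid.
#' @export
validate_definition <- function(def, imports) {
  stopifnot(inherits(def, "eq_definition"))
  known <- import_node_set(imports)
  findings <- character(0)
  if (is_eq_union(def)) {
    if (length(def$operands) < 2) {
      findings <- c(findings, "union with fewer than two operands")
    }
    for (op in def$operands) {
      findings <- c(findings, validate_definition(op, imports))
    }
    return(findings)
  }
  if (is.null(def$quality)) {
    findings <- c(findings, "definition lacks a quality (genus)")
  } else if (!(def$quality %in% known)) {
    findings <- c(findings, paste0("unresolved quality filler: ", def$quality))
  }
  if (!is.null(def$entity) && !(def$entity %in% known)) {
    findings <- c(findings, paste0("unresolved inheres_in filler: ", def$entity))
  }
  if (!is.null(def$towards)) {
    if (is.null(def$quality)) {
      findings <- c(findings, "towards filler present without a quality")
    }
    if (!(def$towards %in% known)) {
      findings <- c(findings, paste0("unresolved towards filler: ", def$towards))
    }
  }
  findings
}

import_node_set <- function(imports) {
  if (length(imports) == 0) return(character(0))
  unique(unlist(lapply(imports, function(g) g$nodes), use.names = FALSE))
}

# Merge the parent maps of all import graphs into one lookup environment.
import_parent_map <- function(imports) {
  edges <- do.call(rbind, c(lapply(imports, function(g) g$edges),
                            list(empty_edges())))
  parent_map(normalize_edges(edges))
}
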