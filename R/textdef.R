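#' Derive a human-readable textual definition from an entity term
#'
#' Phenotype terms defined with the simple pattern
#' `quality that inheres_in some <GO process> and qualifier some abnormal`
#' get an automatically derived textual definition built from the label and
#' textual definition of the GO process term, keeping phenotype definitions
#' up to date with the GO without manual editing. The generated text is
#' exactly:
#'
#' `A phenotype that is a defect in '<go_label>' (<GO_short_form>). The GO
#' term '<go_label>' is defined as: '<go_definition>'`
#'
#' Quote characters are plain ASCII apostrophes. Definitions whose quality
#' is more specific than bare 'quality' (e.g. 'decreased sensitivity of a
#' process') are refused: deriving readable text for those cases is
#' unreliable, so they keep manually written definitions.
#'
#' @param term_label label of the phenotype term (used only for error
#'   messages).
#' @param go_id id of the defining process term, either rendering.
#' @param go_label label of the process term.
#' @param go_definition textual definition of the process term (must be
#'   non-empty; the template would otherwise emit an empty quote).
#' @param definition optional [eq_definition()] of the phenotype term; when
#'   supplied it is checked against the simple pattern and a mismatch is
#'   refused with an error.
#' @return the generated definition text.
#' @export
derive_textual_definition <- function(term_label, go_id, go_label,
                                      go_definition, definition = NULL) {
  if (is.null(go_definition) || !nzchar(trimws(go_definition))) {
    stop_eqonto("eqonto_textdef_error",
                paste0("cannot derive a textual definition for '", term_label,
                       "': the entity term has no textual definition"))
  }
  if (is.null(go_label) || !nzchar(go_label)) {
    stop_eqonto("eqonto_textdef_error",
                paste0("cannot derive a textual definition for '", term_label,
                       "': the entity term has no label"))
  }
  if (!is.null(definition) && !autotext_eligible(definition)) {
    stop_eqonto("eqonto_textdef_error",
                paste0("term '", term_label, "' does not match the simple ",
                       "quality/inheres_in/abnormal pattern; refusing to ",
                       "derive a textual definition"))
  }
  short <- curie_short(go_id)
  paste0("A phenotype that is a defect in '", go_label, "' (", short,
         "). The GO term '", go_label, "' is defined as: '",
         go_definition, "'")
}

# The simple pattern: bare quality genus, an inheres_in entity, the abnormal
# qualifier, no towards filler, equivalent-class semantics, not a union.
autotext_eligible <- function(def) {
  inherits(def, "eq_definition") &&
    !is_eq_union(def) &&
    identical(def$quality, "PATO_0000001") &&
    !is.null(def$entity) &&
    def$abnormal &&
    is.null(def$towards) &&
    isTRUE(def$equivalence)
}

#' Roll automated textual definitions across a document
#'
#' Applies [derive_textual_definition()] to every term of `doc` that (a)
#' matches the simple pattern, (b) has no manually supplied textual
#' definition, and (c) whose entity filler carries both a label and a
#' definition in `source_doc`. All other terms are left untouched, so terms
#' with curated definitions are never overwritten. Auto-text is regenerated
#' on every release run, so it tracks changes in the source ontology. The
#' operation is deterministic: applying it twice yields identical output.
#'
#' @param doc an [obo_document()] of phenotype terms.
#' @param source_doc an [obo_document()] for the entity ontology (supplies
#'   labels and definitions of the fillers).
#' @return the document with generated definitions filled in; the number of
#'   definitions rolled is available as `attr(, "n_rolled")`.
#' @export
roll_textual_definitions <- function(doc, source_doc) {
  n <- 0L
  for (id in names(doc$terms)) {
    term <- doc$terms[[id]]
    if (!is.null(term$def)) next
    d <- term$eq
    if (is.null(d) || !autotext_eligible(d)) next
    src <- source_doc$terms[[d$entity]]
    if (is.null(src) || is.null(src$name) || is.null(src$def)) next
    term$def <- derive_textual_definition(term$name %||% id, d$entity,
                                          src$name, src$def)
    term$def_xrefs <- character(0)
    doc$terms[[id]] <- term
    n <- n + 1L
  }
  attr(doc, "n_rolled") <- n
  doc
}
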