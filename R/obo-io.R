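#' OBO 1.4 documents, terms and typedefs
#'
#' An `obo_document` is an in-memory model of an OBO 1.4 file: a header
#' (key-value lines kept verbatim), a list of `[Term]` stanzas and a list of
#' `[Typedef]` stanzas. Term stanzas carry the fields this toolkit reasons
#' over -- asserted `is_a` parents, genus-differentia pattern definitions
#' (`intersection_of`), the custom tags for union and necessary-only
#' definitions -- plus any unrecognised tag lines, preserved verbatim so that
#' third-party content survives a round trip.
#'
#' Two custom, header-registered tags extend plain OBO 1.4:
#' \describe{
#'   \item{`equivalent_union_of: <id1> <id2> ...`}{an equivalent-class union
#'     whose operands are auxiliary anonymous pattern stanzas elsewhere in
#'     the same document (`is_anonymous: true`).}
#'   \item{`necessary_intersection_of:`}{same grammar as `intersection_of`,
#'     but asserting necessary conditions only (the term is a subclass of the
#'     pattern, not equivalent to it).}
#' }
#' Both are registered in the header via a `subsetdef` line so conforming
#' parsers skip them safely.
#'
#' @param id term id in either CURIE rendering.
#' @param name term label.
#' @param namespace optional OBO namespace.
#' @param def optional textual definition.
#' @param def_xrefs character vector of definition cross-references.
#' @param is_a character vector of asserted parent ids.
#' @param eq optional [eq_definition()] (non-union); its `equivalence` flag
#'   selects between `intersection_of` and `necessary_intersection_of`.
#' @param union_operands optional character vector of operand stanza ids,
#'   making this term an `equivalent_union_of` definition.
#' @param relationships data frame with columns `rel`, `target` for
#'   non-`is_a` relationship lines (carried through I/O, ignored by the
#'   classifier).
#' @param is_anonymous logical; auxiliary pattern stanzas are anonymous.
#' @param is_obsolete logical; obsolete terms may carry no parents or
#'   pattern definition.
#' @param extra character vector of unrecognised tag lines, verbatim.
#' @return `obo_term()` returns an object of class `obo_term`;
#'   `obo_document()` an object of class `obo_document`.
#' @export
obo_term <- function(id, name = NULL, namespace = NULL, def = NULL,
                     def_xrefs = character(0), is_a = character(0),
                     eq = NULL, union_operands = NULL,
                     relationships = NULL, is_anonymous = FALSE,
                     is_obsolete = FALSE, extra = character(0)) {
  id <- curie_short(id)
  if (!is_curie(id)) {
    stop_eqonto("eqonto_id_error", paste0("malformed term id: ", id))
  }
  if (!is.null(eq) && !is.null(union_operands)) {
    stop_eqonto("eqonto_pattern_error",
                paste0("term ", id, " has more than one definition expression"))
  }
  if (isTRUE(is_obsolete) && (length(is_a) > 0 || !is.null(eq) ||
                              !is.null(union_operands))) {
    stop_eqonto("eqonto_pattern_error",
                paste0("obsolete term ", id,
                       " must not carry parents or a definition expression"))
  }
  if (is.null(relationships)) {
    relationships <- data.frame(rel = character(0), target = character(0),
                                stringsAsFactors = FALSE)
  }
  structure(list(id = id, name = name, namespace = namespace, def = def,
                 def_xrefs = def_xrefs, is_a = curie_short(is_a), eq = eq,
                 union_operands = if (!is.null(union_operands))
                   curie_short(union_operands),
                 relationships = relationships,
                 is_anonymous = isTRUE(is_anonymous),
                 is_obsolete = isTRUE(is_obsolete),
                 extra = extra),
            class = "obo_term")
}

#' @rdname obo_term
#' @param terms list of `obo_term` objects.
#' @param typedefs list of typedef stanzas (lists with `id`, `name`, `extra`).
#' @param header character vector of header lines, kept verbatim.
#' @export
obo_document <- function(terms = list(), typedefs = list(),
                         header = "format-version: 1.4") {
  ids <- vapply(terms, function(t) t$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop_eqonto("eqonto_duplicate_id",
                paste0("duplicate term id(s): ", paste(unique(dup), collapse = ", ")))
  }
  names(terms) <- ids
  structure(list(header = header, terms = terms, typedefs = typedefs),
            class = "obo_document")
}

#' @export
print.obo_document <- function(x, ...) {
  cat(sprintf("<obo_document: %d terms, %d typedefs>\n",
              length(x$terms), length(x$typedefs)))
  invisible(x)
}

REGISTRATION_LINE <- paste0(
  'subsetdef: eq_pattern_tags "Custom stanza tags equivalent_union_of and ',
  'necessary_intersection_of carry pattern definitions; third-party parsers ',
  'may ignore them"')

#' Parse OBO 1.4 text into a document model
#'
#' Every `[Term]` stanza yields one term; `intersection_of` blocks of shape
#' \{genus; `inheres_in` filler; `qualifier` abnormal; `towards` filler\} are
#' assembled into an EQ definition, and the custom union / necessary-only
#' tags likewise (see [obo_term]). Unknown tags are preserved verbatim.
#'
#' @param text a single string or character vector of OBO lines.
#' @return an [obo_document()].
#' @seealso [read_obo()] to parse from a file, [write_obo()] for the inverse.
#' @export
parse_obo <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- sub("\r$", "", text)
  lines <- sub("[ \t]+$", "", lines)

  stanza_starts <- grep("^\\[", lines)
  header_end <- if (length(stanza_starts) == 0) length(lines) else stanza_starts[1] - 1
  header <- lines[seq_len(header_end)]
  header <- header[nzchar(header)]

  terms <- list()
  typedefs <- list()
  seen_ids <- character(0)

  bounds <- c(stanza_starts, length(lines) + 1L)
  if (length(stanza_starts) > 0) {
    for (i in seq_along(stanza_starts)) {
      start <- stanza_starts[i]
      block <- lines[seq(start + 1L, bounds[i + 1L] - 1L)]
      block <- block[nzchar(block)]
      kind <- sub("^\\[(.*)\\]$", "\\1", lines[start])
      if (kind == "Term") {
        term <- parse_term_stanza(block)
        if (term$id %in% seen_ids) {
          stop_eqonto("eqonto_duplicate_id",
                      paste0("duplicate term id(s): ", term$id))
        }
        seen_ids <- c(seen_ids, term$id)
        terms[[term$id]] <- term
      } else if (kind == "Typedef") {
        td <- parse_typedef_stanza(block)
        typedefs[[length(typedefs) + 1L]] <- td
      } else {
        # Unknown stanza kinds are not modeled; keep them as a typedef-like
        # opaque record so nothing is silently dropped.
        typedefs[[length(typedefs) + 1L]] <-
          list(id = NA_character_, name = NULL, kind = kind, extra = block)
      }
    }
  }
  obo_document(terms = terms, typedefs = typedefs, header = header)
}

#' @rdname parse_obo
#' @param path path to an OBO file.
#' @export
read_obo <- function(path) {
  parse_obo(readLines(path, warn = FALSE))
}

strip_obo_comment <- function(value) {
  sub("[ \t]+!.*$", "", value)
}

split_tag <- function(line) {
  m <- regexpr(": ", line, fixed = TRUE)
  if (m < 0) return(NULL)
  list(tag = substr(line, 1, m - 1L),
       value = substr(line, m + 2L, nchar(line)))
}

parse_term_stanza <- function(block) {
  fields <- list(id = NULL, name = NULL, namespace = NULL, def = NULL,
                 def_xrefs = character(0), is_a = character(0),
                 relationships = data.frame(rel = character(0),
                                            target = character(0),
                                            stringsAsFactors = FALSE),
                 is_anonymous = FALSE, is_obsolete = FALSE,
                 extra = character(0))
  ix_lines <- list()   # list of c(tag_kind, raw value)
  union_ids <- NULL

  for (line in block) {
    parts <- split_tag(line)
    if (is.null(parts)) { fields$extra <- c(fields$extra, line); next }
    tag <- parts$tag
    value <- parts$value
    if (tag == "id") {
      fields$id <- curie_short(strip_obo_comment(value))
    } else if (tag == "name") {
      fields$name <- value
    } else if (tag == "namespace") {
      fields$namespace <- value
    } else if (tag == "def") {
      parsed <- parse_def_value(value)
      fields$def <- parsed$text
      fields$def_xrefs <- parsed$xrefs
    } else if (tag == "is_a") {
      fields$is_a <- c(fields$is_a, curie_short(strip_obo_comment(value)))
    } else if (tag %in% c("intersection_of", "necessary_intersection_of")) {
      ix_lines[[length(ix_lines) + 1L]] <-
        c(tag, strip_obo_comment(value))
    } else if (tag == "equivalent_union_of") {
      union_ids <- curie_short(strsplit(strip_obo_comment(value), "[ \t]+")[[1]])
    } else if (tag == "relationship") {
      toks <- strsplit(strip_obo_comment(value), "[ \t]+")[[1]]
      if (length(toks) != 2) {
        stop_eqonto("eqonto_pattern_error",
                    paste0("malformed relationship line: ", line))
      }
      fields$relationships <- rbind(fields$relationships,
                                    data.frame(rel = toks[1],
                                               target = curie_short(toks[2]),
                                               stringsAsFactors = FALSE))
    } else if (tag == "is_obsolete") {
      fields$is_obsolete <- identical(value, "true")
    } else if (tag == "is_anonymous") {
      fields$is_anonymous <- identical(value, "true")
    } else {
      fields$extra <- c(fields$extra, line)
    }
  }
  if (is.null(fields$id)) {
    stop_eqonto("eqonto_id_error", "term stanza without an id")
  }

  eq <- NULL
  if (length(ix_lines) > 0) {
    kinds <- unique(vapply(ix_lines, `[`, character(1), 1))
    if (length(kinds) > 1) {
      stop_eqonto("eqonto_pattern_error",
                  paste0("term ", fields$id,
                         " mixes intersection_of and necessary_intersection_of"))
    }
    if (!is.null(union_ids)) {
      stop_eqonto("eqonto_pattern_error",
                  paste0("term ", fields$id,
                         " has more than one definition expression"))
    }
    eq <- assemble_eq(fields$id,
                      vapply(ix_lines, `[`, character(1), 2),
                      equivalence = kinds == "intersection_of")
  }

  obo_term(id = fields$id, name = fields$name, namespace = fields$namespace,
           def = fields$def, def_xrefs = fields$def_xrefs,
           is_a = fields$is_a, eq = eq, union_operands = union_ids,
           relationships = fields$relationships,
           is_anonymous = fields$is_anonymous,
           is_obsolete = fields$is_obsolete, extra = fields$extra)
}

# Assemble intersection_of lines into an eq_definition. Exactly one genus
# (bare id) line is required; differentia lines are "rel filler" pairs.
assemble_eq <- function(id, values, equivalence) {
  genus <- character(0)
  entity <- NULL
  towards <- NULL
  abnormal <- FALSE
  for (value in values) {
    toks <- strsplit(value, "[ \t]+")[[1]]
    if (length(toks) == 1) {
      genus <- c(genus, curie_short(toks))
    } else if (length(toks) == 2) {
      filler <- curie_short(toks[2])
      if (toks[1] == "inheres_in") {
        entity <- filler
      } else if (toks[1] == "towards") {
        towards <- filler
      } else if (toks[1] == "qualifier") {
        if (filler != "PATO_0000460") {
          stop_eqonto("eqonto_pattern_error",
                      paste0("term ", id, ": unsupported qualifier filler ", filler))
        }
        abnormal <- TRUE
      } else {
        stop_eqonto("eqonto_pattern_error",
                    paste0("term ", id, ": unsupported relation '", toks[1],
                           "' in pattern definition"))
      }
    } else {
      stop_eqonto("eqonto_pattern_error",
                  paste0("term ", id, ": malformed pattern line '", value, "'"))
    }
  }
  if (length(genus) != 1) {
    stop_eqonto("eqonto_pattern_error",
                paste0("term ", id, ": pattern definition requires exactly one ",
                       "genus, found ", length(genus)))
  }
  eq_definition(genus, entity = entity, towards = towards,
                abnormal = abnormal, equivalence = equivalence)
}

parse_def_value <- function(value) {
  m <- regmatches(value,
                  regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:[ \t]*\\[(.*)\\])?[ \t]*$',
                          value))[[1]]
  if (length(m) == 0) {
    stop_eqonto("eqonto_pattern_error", paste0("malformed def line: ", value))
  }
  text <- gsub("\\\\(.)", "\\1", m[2])
  xrefs <- if (is.na(m[3]) || !nzchar(m[3])) character(0) else
    trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  list(text = text, xrefs = xrefs[nzchar(xrefs)])
}

parse_typedef_stanza <- function(block) {
  td <- list(id = NA_character_, name = NULL, extra = character(0))
  for (line in block) {
    parts <- split_tag(line)
    if (is.null(parts)) { td$extra <- c(td$extra, line); next }
    if (parts$tag == "id") {
      td$id <- strip_obo_comment(parts$value)
    } else if (parts$tag == "name") {
      td$name <- parts$value
    } else {
      td$extra <- c(td$extra, line)
    }
  }
  td
}

#' Resolve a term's pattern definition, expanding unions
#'
#' Returns the [eq_definition()] attached to a term, resolving
#' `equivalent_union_of` operand ids into a union over the operand stanzas'
#' own pattern definitions. Terms without any pattern definition yield
#' `NULL`.
#'
#' @param doc an [obo_document()].
#' @param id a term id.
#' @return an `eq_definition` or `NULL`.
#' @export
term_definition <- function(doc, id) {
  id <- curie_short(id)
  term <- doc$terms[[id]]
  if (is.null(term)) {
    stop_eqonto("eqonto_unknown_id", paste0("unknown term: ", id))
  }
  if (!is.null(term$union_operands)) {
    ops <- lapply(term$union_operands, function(op) {
      opterm <- doc$terms[[op]]
      if (is.null(opterm) || is.null(opterm$eq)) {
        stop_eqonto("eqonto_unresolved",
                    paste0("union operand ", op, " of ", id,
                           " does not resolve to a pattern stanza"))
      }
      opterm$eq
    })
    return(eq_union(ops, equivalence = TRUE))
  }
  term$eq
}

#' Serialise a document as OBO 1.4 text
#'
#' Output is deterministic: terms are sorted by id, tags are written in a
#' fixed order, and `is_a` / relationship lines are sorted. The `"full"`
#' flavour reproduces pattern definitions; the `"simple"` flavour emits a
#' pre-reasoned artifact whose only structural tags are `is_a` links taken
#' from a (transitively reduced) inferred hierarchy, with pattern tags and
#' anonymous operand stanzas dropped.
#'
#' @param doc an [obo_document()].
#' @param flavour `"full"` or `"simple"`.
#' @param hierarchy an [inferred_hierarchy] (required for `"simple"`); its
#'   `direct_edges` supply the `is_a` links.
#' @param file optional path; when given the text is also written to disk.
#' @return the OBO text as a single string, invisibly when `file` is given.
#' @export
write_obo <- function(doc, flavour = c("full", "simple"), hierarchy = NULL,
                      file = NULL) {
  flavour <- match.arg(flavour)
  if (flavour == "simple") {
    if (is.null(hierarchy)) {
      stop_eqonto("eqonto_usage_error",
                  "flavour = \"simple\" requires a hierarchy argument")
    }
    ids <- names(doc$terms)
    referenced <- unique(c(hierarchy$direct_edges$child,
                           hierarchy$direct_edges$parent))
    missing <- sort_c(setdiff(referenced, ids))
    if (length(missing) > 0) {
      stop_eqonto("eqonto_unknown_id",
                  paste0("hierarchy references ids absent from the document: ",
                         paste(missing, collapse = ", ")))
    }
  }

  uses_custom <- any(vapply(doc$terms, function(t) {
    !is.null(t$union_operands) || (!is.null(t$eq) && !t$eq$equivalence)
  }, logical(1)))

  header <- doc$header
  header <- header[!grepl("^format-version:", header)]
  header <- header[header != REGISTRATION_LINE]
  out <- c("format-version: 1.4",
           if (flavour == "full" && uses_custom) REGISTRATION_LINE,
           header)

  ids <- sort_c(names(doc$terms))
  for (id in ids) {
    term <- doc$terms[[id]]
    if (flavour == "simple" && term$is_anonymous) next
    out <- c(out, "", format_term_stanza(term, flavour, hierarchy))
  }

  td_ids <- vapply(doc$typedefs, function(td) td$id %||% NA_character_,
                   character(1))
  for (i in order_c(td_ids)) {
    td <- doc$typedefs[[i]]
    out <- c(out, "", "[Typedef]",
             if (!is.na(td$id)) paste0("id: ", td$id),
             if (!is.null(td$name)) paste0("name: ", td$name),
             td$extra)
  }

  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(text, file, sep = "")
    return(invisible(text))
  }
  text
}

format_term_stanza <- function(term, flavour, hierarchy) {
  lines <- c("[Term]", paste0("id: ", curie_obo(term$id)))
  if (term$is_anonymous) lines <- c(lines, "is_anonymous: true")
  if (!is.null(term$name)) lines <- c(lines, paste0("name: ", term$name))
  if (!is.null(term$namespace)) {
    lines <- c(lines, paste0("namespace: ", term$namespace))
  }
  if (!is.null(term$def)) {
    escaped <- gsub('"', '\\"', gsub("\\", "\\\\", term$def, fixed = TRUE),
                    fixed = TRUE)
    lines <- c(lines, paste0('def: "', escaped, '" [',
                             paste(term$def_xrefs, collapse = ", "), "]"))
  }

  if (flavour == "simple") {
    parents <- hierarchy$direct_edges$parent[
      hierarchy$direct_edges$child == term$id]
    for (p in sort_c(parents)) {
      lines <- c(lines, paste0("is_a: ", curie_obo(p)))
    }
  } else {
    for (p in sort_c(term$is_a)) {
      lines <- c(lines, paste0("is_a: ", curie_obo(p)))
    }
    if (!is.null(term$eq)) {
      tag <- if (term$eq$equivalence) "intersection_of"
             else "necessary_intersection_of"
      lines <- c(lines, paste0(tag, ": ", curie_obo(term$eq$quality)))
      if (!is.null(term$eq$entity)) {
        lines <- c(lines, paste0(tag, ": inheres_in ", curie_obo(term$eq$entity)))
      }
      if (term$eq$abnormal) {
        lines <- c(lines, paste0(tag, ": qualifier PATO:0000460"))
      }
      if (!is.null(term$eq$towards)) {
        lines <- c(lines, paste0(tag, ": towards ", curie_obo(term$eq$towards)))
      }
    }
    if (!is.null(term$union_operands)) {
      lines <- c(lines, paste0("equivalent_union_of: ",
                               paste(curie_obo(term$union_operands),
                                     collapse = " ")))
    }
    if (nrow(term$relationships) > 0) {
      rel <- term$relationships[order_c(term$relationships$rel,
                                        term$relationships$target), ,
                                drop = FALSE]
      lines <- c(lines, paste0("relationship: ", rel$rel, " ",
                               curie_obo(rel$target)))
    }
  }
  lines <- c(lines, term$extra)
  if (term$is_obsolete) lines <- c(lines, "is_obsolete: true")
  lines
}

#' Report unresolved references in a document
#'
#' Scans `is_a` targets, relationship targets and pattern-definition fillers
#' for ids that resolve neither within the document nor in the supplied
#' import graphs. Dangling references are reported as findings (warnings by
#' default); imported-module workflows legitimately carry references that
#' are resolved elsewhere, so they only become fatal under a strict release.
#'
#' @param doc an [obo_document()].
#' @param imports named list of [term_graph()] objects.
#' @return a data frame with columns `id`, `kind`, `message`.
#' @export
document_findings <- function(doc, imports = list()) {
  known <- c(names(doc$terms), import_node_set(imports))
  rows <- list()
  add <- function(id, kind, message) {
    rows[[length(rows) + 1L]] <<- data.frame(id = id, kind = kind,
                                             message = message,
                                             stringsAsFactors = FALSE)
  }
  for (term in doc$terms) {
    for (p in term$is_a) {
      if (!(p %in% known)) {
        add(term$id, "dangling_is_a", paste0("is_a target ", p, " unresolved"))
      }
    }
    if (nrow(term$relationships) > 0) {
      for (tgt in term$relationships$target) {
        if (!(tgt %in% known)) {
          add(term$id, "dangling_relationship",
              paste0("relationship target ", tgt, " unresolved"))
        }
      }
    }
    d <- tryCatch(term_definition(doc, term$id), error = function(e) NULL)
    if (!is.null(d)) {
      for (f in validate_definition(d, imports)) {
        add(term$id, "definition", f)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id = character(0), kind = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
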