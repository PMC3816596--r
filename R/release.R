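#' Run a desk-scale release of a pattern-defined phenotype ontology
#'
#' Reproduces the continuous-integration release flow at desk scale:
#' validate the ontology against its imports, roll automated textual
#' definitions, classify, and emit both the full artifact (patterns intact,
#' auto-text rolled) and the pre-reasoned '-simple' artifact (inferred,
#' transitively reduced `is_a` links only), together with machine-readable
#' reports. Running the release twice on identical inputs produces
#' byte-identical artifacts.
#'
#' Written artifacts (under `out_dir`):
#' \describe{
#'   \item{`<name>-full.obo`}{pattern definitions intact, auto-text rolled.}
#'   \item{`<name>-simple.obo`}{inferred, reduced `is_a` links only.}
#'   \item{`stats.tsv`}{term/edge counts and the inferred fraction.}
#'   \item{`edges.tsv`}{direct edges with asserted/inferred provenance.}
#'   \item{`findings.tsv`}{validation findings (dangling references,
#'     unresolved fillers, inferred equivalences).}
#'   \item{`<name>-lethal.obo`, `lethal-edges.tsv`}{with
#'     `generate_lethal = TRUE`, the classified lethal-phase term set.}
#' }
#'
#' @param ontology path to the ontology OBO file.
#' @param imports named character vector of import OBO paths; names are the
#'   prefix bindings (must be unique).
#' @param out_dir output directory, created if missing.
#' @param name basename for the artifacts; defaults to the ontology file
#'   name without extension.
#' @param strict treat validation findings as fatal (status 1).
#' @param generate_lethal also generate and classify the lethal-phase term
#'   set over the stage chain in `stages`.
#' @param stages path to the stage-chain OBO (required with
#'   `generate_lethal`).
#' @param thresholds lethal-phase quantifier cutoffs, see
#'   [generate_lethal_phase_terms()].
#' @param with_short_lived forward to [generate_lethal_phase_terms()].
#' @return a list with `status` (0 success, 1 validation failure under
#'   strict, 2 I/O failure), `paths` of written artifacts, `stats`,
#'   `hierarchy` and `findings`. Suitable for `quit(status = )` in a CLI
#'   wrapper.
#' @export
run_release <- function(ontology, imports = character(0), out_dir,
                        name = NULL, strict = FALSE,
                        generate_lethal = FALSE, stages = NULL,
                        thresholds = c(some = 5, most = 50, all = 98),
                        with_short_lived = FALSE) {
  name <- name %||% sub("\\.obo$", "", basename(ontology))
  if (anyDuplicated(names(imports))) {
    return(release_failure(2, "duplicate import prefix bindings"))
  }
  missing_paths <- c(ontology, imports,
                     if (generate_lethal) stages)[!file.exists(
                       c(ontology, imports, if (generate_lethal) stages))]
  if (length(missing_paths) > 0) {
    return(release_failure(2, paste0("missing input file(s): ",
                                     paste(missing_paths, collapse = ", "))))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  doc <- read_obo(ontology)
  import_docs <- lapply(imports, read_obo)
  import_graphs <- lapply(import_docs, graph_from_document)

  findings <- document_findings(doc, import_graphs)
  if (strict && nrow(findings) > 0) {
    findings_path <- file.path(out_dir, "findings.tsv")
    write_tsv(findings, findings_path)
    message("release failed validation; see ", findings_path)
    return(list(status = 1L, paths = c(findings = findings_path),
                stats = NULL, hierarchy = NULL, findings = findings))
  }

  # non-strict: exclude invalid definitions from classification, keep going
  bad_def_ids <- unique(findings$id[findings$kind == "definition"])
  doc_classify <- doc
  for (id in bad_def_ids) {
    doc_classify$terms[[id]]$eq <- NULL
    doc_classify$terms[[id]]$union_operands <- NULL
  }

  for (src in import_docs) {
    doc <- roll_textual_definitions(doc, src)
    doc_classify <- roll_textual_definitions(doc_classify, src)
  }

  warned_groups <- character(0)
  hierarchy <- withCallingHandlers(
    classify(doc_classify, import_graphs),
    warning = function(w) {
      warned_groups <<- c(warned_groups, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (msg in warned_groups) {
    findings <- rbind(findings,
                      data.frame(id = NA_character_, kind = "equivalence",
                                 message = msg, stringsAsFactors = FALSE))
  }
  stats <- inference_stats(hierarchy)

  paths <- c(full = file.path(out_dir, paste0(name, "-full.obo")),
             simple = file.path(out_dir, paste0(name, "-simple.obo")),
             stats = file.path(out_dir, "stats.tsv"),
             edges = file.path(out_dir, "edges.tsv"),
             findings = file.path(out_dir, "findings.tsv"))
  write_obo(doc, flavour = "full", file = paths[["full"]])
  write_obo(doc, flavour = "simple", hierarchy = hierarchy,
            file = paths[["simple"]])
  write_tsv(data.frame(
    metric = c("n_terms", "n_direct", "n_inferred", "fraction_inferred",
               "percent_inferred"),
    value = c(length(hierarchy$nodes), stats$n_direct, stats$n_inferred,
              format(stats$fraction_inferred, digits = 6),
              stats$percent_inferred),
    stringsAsFactors = FALSE), paths[["stats"]])
  edges_out <- hierarchy$direct_edges
  edges_out$provenance <- hierarchy$provenance
  write_tsv(edges_out, paths[["edges"]])
  write_tsv(findings, paths[["findings"]])

  if (generate_lethal) {
    chain <- stage_chain_from_obo(read_obo(stages))
    lterms <- generate_lethal_phase_terms(chain, thresholds = thresholds,
                                          with_short_lived = with_short_lived)
    lh <- classify_lethal(lterms, chain)
    ldoc <- obo_document(lapply(lterms, function(t) {
      obo_term(t$id, name = t$label)
    }), header = c("format-version: 1.4",
                   paste0("ontology: ", name, "-lethal")))
    lpaths <- c(lethal = file.path(out_dir, paste0(name, "-lethal.obo")),
                lethal_edges = file.path(out_dir, "lethal-edges.tsv"))
    write_obo(ldoc, flavour = "simple", hierarchy = lh,
              file = lpaths[["lethal"]])
    ledges <- lh$direct_edges
    ledges$provenance <- lh$provenance
    write_tsv(ledges, lpaths[["lethal_edges"]])
    paths <- c(paths, lpaths)
  }

  list(status = 0L, paths = paths, stats = stats, hierarchy = hierarchy,
       findings = findings)
}

release_failure <- function(status, msg) {
  message(msg)
  list(status = as.integer(status), paths = character(0), stats = NULL,
       hierarchy = NULL,
       findings = data.frame(id = NA_character_, kind = "io", message = msg,
                             stringsAsFactors = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
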