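#' Bundled miniature ontology fixtures
#'
#' Builds, entirely in memory, the small ontology fragments every other
#' module is exercised against, so nothing needs downloading:
#' \describe{
#'   \item{`mini_pato`}{qualities: 'quality', 'abnormal', 'decreased
#'     sensitivity of a process', 'increased size', 'has extra parts of
#'     type' and their grouping classes.}
#'   \item{`mini_go`}{the stress-response fragment (response to stress and
#'     its dual-parent children such as 'response to cold', which also sits
#'     under 'response to temperature stimulus'), the behavior/perception
#'     fragment, and the programmed-cell-death terms.}
#'   \item{`mini_clfbbt`}{'cell', 'organism' and 'multicellular structure'.}
#'   \item{`fly_stages`}{the four major life stages chained by
#'     `immediately_preceded_by` links.}
#'   \item{`mini_dpo`}{phenotype terms carrying EQ pattern definitions over
#'     the above: the stress-response and behavior families, the cell
#'     phenotypes, the cell-death union, and a necessary-only example.}
#' }
#' These fixtures are the single source of truth for the worked
#' classification examples (e.g. the eight inferred subclasses of 'stress
#' response defective').
#'
#' @return a named list of [obo_document()] objects.
#' @export
make_named_fixtures <- function() {
  list(mini_pato = fixture_mini_pato(),
       mini_go = fixture_mini_go(),
       mini_clfbbt = fixture_mini_clfbbt(),
       fly_stages = fixture_fly_stages(),
       mini_dpo = fixture_mini_dpo())
}

GO_STRESS_DEF <- paste0(
  "Any process that results in a change in state or activity of a cell or ",
  "an organism (in terms of movement, secretion, enzyme production, gene ",
  "expression, etc.) as a result of a disturbance in organismal or ",
  "cellular homeostasis, usually, but not necessarily, exogenous ",
  "(e.g. temperature, humidity, ionizing radiation).")

fixture_mini_pato <- function() {
  t <- function(id, name, is_a = character(0)) {
    obo_term(id, name = name, namespace = "quality", is_a = is_a)
  }
  obo_document(list(
    t("PATO_0000001", "quality"),
    t("PATO_0000460", "abnormal", "PATO_0000001"),
    t("PATO_0001236", "process quality", "PATO_0000001"),
    t("PATO_0001457", "sensitivity of a process", "PATO_0001236"),
    t("PATO_0001552", "decreased sensitivity of a process", "PATO_0001457"),
    t("PATO_0000117", "size", "PATO_0000001"),
    t("PATO_0000586", "increased size", "PATO_0000117"),
    t("PATO_0002002", "has extra parts of type", "PATO_0000001")),
    header = c("format-version: 1.4", "ontology: mini-pato"))
}

fixture_mini_go <- function() {
  t <- function(id, name, is_a = character(0), def = NULL) {
    obo_term(id, name = name, namespace = "biological_process",
             is_a = is_a, def = def,
             def_xrefs = if (!is.null(def)) "GOC:fixture" else character(0))
  }
  obo_document(list(
    t("GO_0008150", "biological_process"),
    t("GO_0050896", "response to stimulus", "GO_0008150"),
    t("GO_0006950", "response to stress", "GO_0050896", def = GO_STRESS_DEF),
    t("GO_0009628", "response to abiotic stimulus", "GO_0050896"),
    t("GO_0009266", "response to temperature stimulus", "GO_0009628"),
    t("GO_0009409", "response to cold", c("GO_0006950", "GO_0009266"),
      def = "Any process that results in a change in state or activity of a cell or an organism as a result of a cold stimulus, a temperature stimulus below the optimal temperature for that organism."),
    t("GO_0009408", "response to heat", c("GO_0006950", "GO_0009266")),
    t("GO_0006979", "response to oxidative stress", "GO_0006950"),
    t("GO_0006974", "cellular response to DNA damage stimulus",
      c("GO_0006950", "GO_0009987")),
    t("GO_0006281", "DNA repair", "GO_0006974",
      def = "The process of restoring DNA after damage."),
    t("GO_0006952", "defense response", "GO_0006950"),
    t("GO_0009611", "response to wounding", "GO_0006950"),
    t("GO_0042060", "wound healing", "GO_0009611"),
    t("GO_0009314", "response to radiation", "GO_0009628"),
    t("GO_0007610", "behavior", "GO_0008150",
      def = "The internally coordinated responses of whole living organisms to internal or external stimuli."),
    t("GO_0007630", "jump response", "GO_0007610"),
    t("GO_0007623", "circadian rhythm", "GO_0008150"),
    t("GO_0048512", "circadian behavior", c("GO_0007610", "GO_0007623")),
    t("GO_0050877", "nervous system process", "GO_0008150"),
    t("GO_0007600", "sensory perception", "GO_0050877"),
    t("GO_0007605", "sensory perception of sound", "GO_0007600"),
    t("GO_0009987", "cellular process", "GO_0008150"),
    t("GO_0012501", "programmed cell death", "GO_0009987"),
    t("GO_0006915", "apoptotic process", "GO_0012501"),
    t("GO_0065007", "biological regulation", "GO_0008150"),
    t("GO_0043067", "regulation of programmed cell death", "GO_0065007")),
    header = c("format-version: 1.4", "ontology: mini-go"))
}

fixture_mini_clfbbt <- function() {
  obo_document(list(
    obo_term("CL_0000000", name = "cell"),
    obo_term("FBbt_00000001", name = "organism"),
    obo_term("FBbt_00100313", name = "multicellular structure")),
    header = c("format-version: 1.4", "ontology: mini-clfbbt"))
}

fixture_fly_stages <- function() {
  ipb <- function(target) {
    data.frame(rel = "immediately_preceded_by", target = target,
               stringsAsFactors = FALSE)
  }
  obo_document(
    terms = list(
      obo_term("FBdv_00005289", name = "embryonic stage"),
      obo_term("FBdv_00005336", name = "larval stage",
               relationships = ipb("FBdv_00005289")),
      obo_term("FBdv_00005342", name = "pupal stage",
               relationships = ipb("FBdv_00005336")),
      obo_term("FBdv_00007026", name = "mature adult stage",
               relationships = ipb("FBdv_00005342"))),
    typedefs = list(list(id = "immediately_preceded_by",
                         name = "immediately_preceded_by",
                         extra = character(0))),
    header = c("format-version: 1.4", "ontology: fly-stages"))
}

fixture_mini_dpo <- function() {
  simple <- function(id, name, go) {
    obo_term(id, name = name,
             eq = eq_definition("PATO_0000001", entity = go, abnormal = TRUE))
  }
  obo_document(list(
    obo_term("FBcv_0000001", name = "phenotype",
             def = paste0("A quality of some anatomical structure, process ",
                          "or behavior that differs from wild-type."),
             def_xrefs = "FBC:fixture",
             eq = eq_definition("PATO_0000001", abnormal = TRUE)),
    simple("FBcv_0000408", "stress response defective", "GO_0006950"),
    simple("FBcv_0000683", "temperature response defective", "GO_0009266"),
    simple("FBcv_0000684", "cold stress response defective", "GO_0009409"),
    simple("FBcv_0000686", "heat stress response defective", "GO_0009408"),
    simple("FBcv_0000687", "oxidative stress response defective", "GO_0006979"),
    simple("FBcv_0000688", "DNA damage response defective", "GO_0006974"),
    simple("FBcv_0000423", "DNA repair defective", "GO_0006281"),
    simple("FBcv_0000689", "defense response defective", "GO_0006952"),
    simple("FBcv_0000690", "wound response defective", "GO_0009611"),
    simple("FBcv_0000691", "wound healing defective", "GO_0042060"),
    obo_term("FBcv_0000439", name = "radiation resistant",
             def = paste0("A phenotype that is a decreased sensitivity ",
                          "to radiation."),
             def_xrefs = "FBC:fixture",
             is_a = "FBcv_0000001",
             eq = eq_definition("PATO_0001552", entity = "GO_0009314")),
    simple("FBcv_0000387", "behavior defective", "GO_0007610"),
    simple("FBcv_0000394", "circadian rhythm defective", "GO_0007623"),
    simple("FBcv_0000679", "circadian behavior defective", "GO_0048512"),
    simple("FBcv_0000692", "sensory perception defective", "GO_0007600"),
    simple("FBcv_0000693", "hearing defective", "GO_0007605"),
    simple("FBcv_0000694", "jump response defective", "GO_0007630"),
    obo_term("FBcv_0000415", name = "jumping defective",
             def = paste0("Flies fail to jump in a standard assay, with no ",
                          "controls discounting physical explanations such ",
                          "as defective legs; neutral about whether the ",
                          "defect is behavioral."),
             def_xrefs = "FBC:fixture",
             eq = eq_definition("PATO_0000001", abnormal = TRUE,
                                equivalence = FALSE)),
    obo_term("FBcv_0000363", name = "increased cell size",
             is_a = "FBcv_0000001",
             eq = eq_definition("PATO_0000586", entity = "CL_0000000")),
    obo_term("FBcv_0000362", name = "increased cell number",
             is_a = "FBcv_0000001",
             eq = eq_definition("PATO_0002002", entity = "FBbt_00100313",
                                towards = "CL_0000000")),
    obo_term("FBcv_0000425", name = "cell death defective",
             union_operands = c("PATTERN_0000001", "PATTERN_0000002")),
    obo_term("PATTERN_0000001", is_anonymous = TRUE,
             eq = eq_definition("PATO_0000001", entity = "GO_0012501",
                                abnormal = TRUE)),
    obo_term("PATTERN_0000002", is_anonymous = TRUE,
             eq = eq_definition("PATO_0000001", entity = "GO_0043067",
                                abnormal = TRUE)),
    simple("FBcv_0000695", "apoptosis defective", "GO_0006915")),
    header = c("format-version: 1.4", "ontology: mini-dpo"))
}

#' Import graphs for the bundled fixtures
#'
#' Convenience wrapper turning the fixture documents into the named list of
#' [term_graph()] objects that [classify()] expects.
#'
#' @param fixtures output of [make_named_fixtures()] (rebuilt when omitted).
#' @return named list of term graphs keyed by ontology prefix family.
#' @export
fixture_imports <- function(fixtures = make_named_fixtures()) {
  list(pato = graph_from_document(fixtures$mini_pato),
       go = graph_from_document(fixtures$mini_go),
       clfbbt = graph_from_document(fixtures$mini_clfbbt))
}

#' Write the bundled fixtures as OBO files
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
fixtures_write_all <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- make_named_fixtures()
  files <- c(mini_pato = "mini-pato.obo", mini_go = "mini-go.obo",
             mini_clfbbt = "mini-clfbbt.obo", fly_stages = "fly-stages.obo",
             mini_dpo = "mini-dpo.obo")
  paths <- character(0)
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    write_obo(fx[[nm]], file = path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Specification for a seeded random instance
#'
#' @param seed integer seed; generation is a pure function of the spec.
#' @param n_terms number of phenotype terms to generate.
#' @param n_import_nodes nodes per imported DAG.
#' @param max_parents maximum direct parents per DAG node.
#' @param prefix namespace prefix for the phenotype terms.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_terms = 8, n_import_nodes = 12,
                         max_parents = 2, prefix = "PH") {
  stopifnot(n_terms >= 1, n_import_nodes >= 2, max_parents >= 1)
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 n_import_nodes = as.integer(n_import_nodes),
                 max_parents = as.integer(max_parents), prefix = prefix),
            class = "fixture_spec")
}

# Random rooted DAG: node i > 1 draws 1..max_parents parents among earlier
# nodes, which guarantees acyclicity by construction.
random_dag <- function(prefix, n, max_parents) {
  ids <- mint_curie(prefix, seq_len(n))
  edges <- empty_edges()
  for (i in seq_len(n)[-1]) {
    k <- sample.int(min(max_parents, i - 1L), 1)
    parents <- ids[sample.int(i - 1L, k)]
    edges <- rbind(edges, edge_df(ids[i], parents))
  }
  term_graph(ids, edges)
}

#' Generate a seeded random ontology and imports
#'
#' Produces a random quality DAG, a random entity DAG, and a document of
#' phenotype terms with random EQ definitions over them (a mix of
#' equivalent-class, necessary-only and union definitions, plus occasional
#' asserted parents). Identical specs produce identical output; every
#' generated definition validates against the generated imports.
#'
#' @param spec a [fixture_spec()].
#' @return a list with elements `doc` (an [obo_document()]) and `imports`
#'   (named list of [term_graph()]).
#' @export
random_instance <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    qualities <- random_dag("QU", spec$n_import_nodes, spec$max_parents)
    entities <- random_dag("EN", spec$n_import_nodes, spec$max_parents)
    random_def <- function() {
      eq_definition(
        quality = sample(qualities$nodes, 1),
        entity = if (stats::runif(1) < 0.8) sample(entities$nodes, 1),
        towards = if (stats::runif(1) < 0.2) sample(entities$nodes, 1),
        abnormal = stats::runif(1) < 0.6,
        equivalence = stats::runif(1) < 0.8)
    }
    ids <- mint_curie(spec$prefix, seq_len(spec$n_terms))
    terms <- list()
    n_anon <- 0L
    for (i in seq_len(spec$n_terms)) {
      parents <- if (i > 1 && stats::runif(1) < 0.3) ids[sample.int(i - 1L, 1)]
                 else character(0)
      if (stats::runif(1) < 0.15) {
        # union definition: two anonymous operand stanzas + the union term
        ops <- mint_curie("PAT", n_anon + 1:2)
        n_anon <- n_anon + 2L
        terms <- c(terms,
                   lapply(ops, function(op) {
                     obo_term(op, is_anonymous = TRUE, eq = random_def())
                   }))
        terms[[length(terms) + 1L]] <-
          obo_term(ids[i], name = paste("term", i), is_a = parents,
                   union_operands = ops)
      } else {
        terms[[length(terms) + 1L]] <-
          obo_term(ids[i], name = paste("term", i), is_a = parents,
                   eq = random_def())
      }
    }
    list(doc = obo_document(terms,
                            header = c("format-version: 1.4",
                                       paste0("ontology: random-",
                                              spec$seed))),
         imports = list(qu = qualities, en = entities))
  })
}
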