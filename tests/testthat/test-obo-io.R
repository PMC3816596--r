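test_that("CURIE renderings round-trip losslessly", {
  ids <- c("GO_0006950", "FBcv_0000439", "PATO_0000001", "FBbt_00100313")
  expect_identical(curie_short(curie_obo(ids)), ids)
  expect_identical(curie_obo("FBcv_0000423"), "FBcv:0000423")
  expect_identical(curie_prefix("FBdv_00005289"), "FBdv")
  expect_identical(curie_local("GO:0006950"), "0006950")
  expect_true(all(is_curie(ids)))
})

test_that("a pattern stanza parses into an EQ definition", {
  txt <- c("format-version: 1.4", "",
           "[Term]",
           "id: FBcv:0000439",
           "name: radiation resistant",
           "intersection_of: PATO:0001552 ! decreased sensitivity of a process",
           "intersection_of: inheres_in GO:0009314 ! response to radiation")
  doc <- parse_obo(txt)
  d <- term_definition(doc, "FBcv_0000439")
  expect_identical(d$quality, "PATO_0001552")
  expect_identical(d$entity, "GO_0009314")
  expect_false(d$abnormal)
  expect_true(d$equivalence)
  expect_null(d$towards)
})

test_that("an empty document with only a header has zero terms", {
  doc <- parse_obo(c("format-version: 1.4", "ontology: empty"))
  expect_length(doc$terms, 0)
  expect_s3_class(doc, "obo_document")
})

test_that("structural parse errors are raised with the offending id", {
  dup <- c("[Term]", "id: X:0000001", "", "[Term]", "id: X:0000001")
  expect_error(parse_obo(dup), "X_0000001", class = "eqonto_duplicate_id")

  two_genus <- c("[Term]", "id: X:0000001",
                 "intersection_of: PATO:0000001",
                 "intersection_of: PATO:0000460")
  expect_error(parse_obo(two_genus), "exactly one",
               class = "eqonto_pattern_error")

  no_genus <- c("[Term]", "id: X:0000001",
                "intersection_of: inheres_in GO:0000001")
  expect_error(parse_obo(no_genus), class = "eqonto_pattern_error")
})

test_that("write-parse-write is a fixed point on every bundled fixture", {
  for (nm in names(fixtures)) {
    first <- write_obo(fixtures[[nm]])
    second <- write_obo(parse_obo(first))
    expect_identical(second, first, label = paste("fixture", nm))
  }
})

test_that("writing the same inputs twice is byte-identical", {
  expect_identical(write_obo(fixtures$mini_dpo), write_obo(fixtures$mini_dpo))
  h <- classify(fixtures$mini_dpo, fixture_graphs)
  expect_identical(write_obo(fixtures$mini_dpo, "simple", h),
                   write_obo(fixtures$mini_dpo, "simple", h))
})

test_that("unknown tags and union operands survive a round trip", {
  txt <- c("format-version: 1.4",
           "",
           "[Term]",
           "id: PX:0000001",
           "name: widget",
           "xref: WIKI:widget",
           "synonym: \"gadget\" EXACT []")
  doc <- parse_obo(txt)
  expect_true(all(c("xref: WIKI:widget", "synonym: \"gadget\" EXACT []") %in%
                    doc$terms[["PX_0000001"]]$extra))
  reparsed <- parse_obo(write_obo(doc))
  expect_identical(reparsed$terms[["PX_0000001"]]$extra,
                   doc$terms[["PX_0000001"]]$extra)

  cdd <- fixtures$mini_dpo$terms[["FBcv_0000425"]]
  expect_identical(cdd$union_operands, c("PATTERN_0000001", "PATTERN_0000002"))
  d <- term_definition(fixtures$mini_dpo, "FBcv_0000425")
  expect_true(is_eq_union(d))
  expect_length(d$operands, 2)
})

test_that("the simple flavour emits only reduced is_a structure", {
  h <- classify(fixtures$mini_dpo, fixture_graphs)
  txt <- write_obo(fixtures$mini_dpo, flavour = "simple", hierarchy = h)
  expect_false(grepl("intersection_of", txt))
  expect_false(grepl("equivalent_union_of", txt))
  expect_false(grepl("relationship:", txt))
  expect_true(grepl("is_a:", txt))
  # anonymous operand stanzas are dropped
  expect_false(grepl("PATTERN:0000001", txt, fixed = TRUE))

  simple <- parse_obo(txt)
  got <- do.call(rbind, lapply(simple$terms, function(t) {
    if (length(t$is_a) == 0) return(NULL)
    data.frame(child = t$id, parent = t$is_a, stringsAsFactors = FALSE)
  }))
  got <- got[order(got$child, got$parent, method = "radix"), ]
  rownames(got) <- NULL
  expect_identical(got, h$direct_edges)
})

test_that("simple flavour validates its hierarchy argument", {
  expect_error(write_obo(fixtures$mini_pato, flavour = "simple"),
               class = "eqonto_usage_error")
  h <- classify(fixtures$mini_dpo, fixture_graphs)
  expect_error(write_obo(fixtures$mini_pato, flavour = "simple",
                         hierarchy = h),
               "FBcv_0000408", class = "eqonto_unknown_id")
})

test_that("simple flavour with the asserted hierarchy reproduces it", {
  g <- graph_from_document(fixtures$mini_go)
  h <- eqonto:::make_inferred_hierarchy(g$edges,
                                        rep("asserted", nrow(g$edges)),
                                        list(), g$edges, g$nodes)
  simple <- parse_obo(write_obo(fixtures$mini_go, "simple", h))
  for (id in names(simple$terms)) {
    expect_setequal(simple$terms[[id]]$is_a, fixtures$mini_go$terms[[id]]$is_a)
  }
})

test_that("obsolete terms may not carry parents or a definition", {
  expect_error(obo_term("X_0000001", is_obsolete = TRUE, is_a = "X_0000002"),
               class = "eqonto_pattern_error")
  expect_silent(obo_term("X_0000001", name = "gone", is_obsolete = TRUE))
})

test_that("bundled extdata files match the in-code generators", {
  files <- c(mini_pato = "mini-pato.obo", mini_go = "mini-go.obo",
             mini_clfbbt = "mini-clfbbt.obo", fly_stages = "fly-stages.obo",
             mini_dpo = "mini-dpo.obo")
  for (nm in names(files)) {
    path <- system.file("extdata", files[[nm]], package = "eqonto")
    expect_true(nzchar(path), label = files[[nm]])
    expect_identical(paste0(paste(readLines(path), collapse = "\n"), "\n"),
                     write_obo(fixtures[[nm]]), label = files[[nm]])
  }
})
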