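dpo_hierarchy <- classify(fixtures$mini_dpo, fixture_graphs)

test_that("stress-response phenotypes classify as in the worked example", {
  sub <- subclasses_of(dpo_hierarchy, "FBcv_0000408")
  expect_length(sub, 8)
  expect_true("FBcv_0000423" %in% sub)   # DNA repair defective
  # cold stress response defective under both groupings
  cold_sup <- superclasses_of(dpo_hierarchy, "FBcv_0000684")
  expect_true(all(c("FBcv_0000408", "FBcv_0000683") %in% cold_sup))
  # both direct and transitive counts are exposed
  direct <- subclasses_of(dpo_hierarchy, "FBcv_0000408", direct = TRUE)
  expect_setequal(direct, c("FBcv_0000684", "FBcv_0000686", "FBcv_0000687",
                            "FBcv_0000688", "FBcv_0000689", "FBcv_0000690"))
  # the nested pairs arrive through their intermediate parents
  expect_true("FBcv_0000423" %in%
                subclasses_of(dpo_hierarchy, "FBcv_0000688", direct = TRUE))
  expect_true("FBcv_0000691" %in%
                subclasses_of(dpo_hierarchy, "FBcv_0000690", direct = TRUE))
})

test_that("perception and general circadian terms leave the behavior tree", {
  behav <- subclasses_of(dpo_hierarchy, "FBcv_0000387")
  expect_false("FBcv_0000692" %in% behav)   # sensory perception defective
  expect_false("FBcv_0000693" %in% behav)   # hearing defective
  expect_false("FBcv_0000394" %in% behav)   # circadian rhythm defective
  expect_true("FBcv_0000679" %in% behav)    # circadian behavior defective
  expect_true("FBcv_0000694" %in% behav)    # jump response defective
  # the neutral broader term gains no definition-driven descendants
  expect_length(subclasses_of(dpo_hierarchy, "FBcv_0000415"), 0)
  expect_true("FBcv_0000001" %in% superclasses_of(dpo_hierarchy,
                                                  "FBcv_0000415"))
})

test_that("union definitions subsume their instantiations", {
  pcd <- eq_definition("PATO_0000001", entity = "GO_0012501", abnormal = TRUE)
  cdd <- term_definition(fixtures$mini_dpo, "FBcv_0000425")
  expect_true(eq_subsumes(pcd, cdd, fixture_graphs))
  expect_false(eq_subsumes(cdd, pcd, fixture_graphs))
  # a union is below the phenotype root iff every operand is
  root <- term_definition(fixtures$mini_dpo, "FBcv_0000001")
  expect_true(eq_subsumes(cdd, root, fixture_graphs))
  # and the classifier materialises both directions of that picture
  expect_true("FBcv_0000695" %in% subclasses_of(dpo_hierarchy, "FBcv_0000425"))
  expect_true("FBcv_0000001" %in% superclasses_of(dpo_hierarchy,
                                                  "FBcv_0000425"))
})

test_that("subsumption is reflexive and errors on unresolved fillers", {
  for (id in c("FBcv_0000408", "FBcv_0000439", "FBcv_0000425",
               "FBcv_0000362")) {
    d <- term_definition(fixtures$mini_dpo, id)
    expect_true(eq_subsumes(d, d, fixture_graphs), label = id)
  }
  bad <- eq_definition("PATO_0000001", entity = "GO_7777777", abnormal = TRUE)
  good <- eq_definition("PATO_0000001", abnormal = TRUE)
  expect_error(eq_subsumes(bad, good, fixture_graphs),
               class = "eqonto_unresolved")
})

test_that("degenerate documents classify without inferred edges", {
  solo <- obo_document(list(obo_term("PH_0000001", name = "only",
                                     eq = eq_definition("PATO_0000001",
                                                        abnormal = TRUE))))
  h <- classify(solo, fixture_graphs)
  expect_identical(nrow(h$direct_edges), 0L)
  expect_identical(sum(h$provenance == "inferred"), 0L)
})

test_that("identical definitions yield one reported equivalence group", {
  twin <- function(id) {
    obo_term(id, name = id,
             eq = eq_definition("PATO_0000001", entity = "GO_0006950",
                                abnormal = TRUE))
  }
  doc <- obo_document(list(twin("PH_0000001"), twin("PH_0000002")))
  expect_warning(h <- classify(doc, fixture_graphs), "equivalence")
  expect_length(h$equivalence_groups, 1)
  expect_setequal(h$equivalence_groups[[1]], c("PH_0000001", "PH_0000002"))
})

test_that("eq_subsumes matches the homomorphism-search oracle", {
  n_pairs <- 0
  for (seed in 1:30) {
    inst <- random_instance(fixture_spec(seed, n_terms = 5))
    anon <- vapply(inst$doc$terms, function(t) t$is_anonymous, logical(1))
    defs <- lapply(names(inst$doc$terms)[!anon],
                   function(id) term_definition(inst$doc, id))
    for (a in defs) for (b in defs) {
      expect_identical(eq_subsumes(a, b, inst$imports),
                       oracle_eq_subsumes(a, b, inst$imports))
      n_pairs <- n_pairs + 1
    }
  }
  expect_gte(n_pairs, 500)
})

test_that("the classify closure equals pairwise subsumption plus assertions", {
  for (seed in 1:100) {
    inst <- random_instance(fixture_spec(seed, n_terms = 6))
    h <- suppressWarnings(classify(inst$doc, inst$imports))
    real <- Filter(function(t) !t$is_anonymous, inst$doc$terms)
    ids <- sort(names(real), method = "radix")
    defs <- lapply(ids, function(id) term_definition(inst$doc, id))
    names(defs) <- ids
    inferred <- data.frame(child = character(0), parent = character(0),
                           stringsAsFactors = FALSE)
    for (x in ids) for (y in ids) {
      if (x == y || is.null(defs[[x]]) || is.null(defs[[y]])) next
      if (!defs[[y]]$equivalence) next
      if (oracle_eq_subsumes(defs[[x]], defs[[y]], inst$imports)) {
        inferred <- rbind(inferred, data.frame(child = x, parent = y,
                                               stringsAsFactors = FALSE))
      }
    }
    asserted <- do.call(rbind, c(list(inferred[0, ]), lapply(real, function(t) {
      if (length(t$is_a) == 0) return(NULL)
      data.frame(child = t$id, parent = t$is_a, stringsAsFactors = FALSE)
    })))
    combined <- unique(rbind(asserted, inferred))
    expected <- unlist(lapply(ids, function(n) {
      anc <- setdiff(oracle_ancestors(combined, n), n)
      if (length(anc) == 0) return(character(0))
      paste(n, anc)
    }))
    got <- paste(h$closure_edges$child, h$closure_edges$parent)
    expect_setequal(got, expected)
  }
})

test_that("re-classifying a pre-reasoned artifact adds nothing", {
  simple <- parse_obo(write_obo(fixtures$mini_dpo, "simple",
                                hierarchy = dpo_hierarchy))
  h2 <- classify(simple, fixture_graphs)
  expect_identical(h2$direct_edges, dpo_hierarchy$direct_edges)
  expect_identical(h2$closure_edges, dpo_hierarchy$closure_edges)
  expect_identical(sum(h2$provenance == "inferred"), 0L)
})

test_that("every abnormal-qualified definition falls under the root", {
  all_abnormal <- function(d) {
    if (is_eq_union(d)) return(all(vapply(d$operands, all_abnormal,
                                          logical(1))))
    d$abnormal
  }
  for (id in setdiff(dpo_hierarchy$nodes, "FBcv_0000001")) {
    d <- term_definition(fixtures$mini_dpo, id)
    if (is.null(d) || !all_abnormal(d)) next
    expect_true("FBcv_0000001" %in% superclasses_of(dpo_hierarchy, id),
                label = id)
  }
})

test_that("inference statistics use half-up percentage rounding", {
  s <- inference_stats(n_direct = 305, n_inferred = 258)
  expect_identical(s$percent_inferred, 85L)
  expect_equal(s$fraction_inferred, 258 / 305)
  expect_identical(inference_stats(n_direct = 200, n_inferred = 1)$percent_inferred,
                   1L)  # 0.5 rounds up
  expect_identical(inference_stats(n_direct = 10, n_inferred = 0)$fraction_inferred,
                   0)
  expect_error(inference_stats(n_direct = 3, n_inferred = 4),
               class = "eqonto_usage_error")
})

test_that("mini-ontology statistics match the frozen golden values", {
  s <- inference_stats(dpo_hierarchy)
  # independent set difference: direct edges absent from the asserted pairs
  asserted <- unlist(lapply(fixtures$mini_dpo$terms, function(t) {
    if (length(t$is_a) == 0) return(character(0))
    paste(t$id, t$is_a)
  }), use.names = FALSE)
  n_inf <- sum(!(paste(dpo_hierarchy$direct_edges$child,
                       dpo_hierarchy$direct_edges$parent) %in% asserted))
  expect_identical(s$n_inferred, as.integer(n_inf))
  # golden values, fixed when the fixture was created
  expect_identical(s$n_direct, 25L)
  expect_identical(s$n_inferred, 22L)
  expect_identical(s$percent_inferred, 88L)
})
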