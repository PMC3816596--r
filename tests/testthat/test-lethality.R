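lterms <- generate_lethal_phase_terms(fly_chain)
by_label <- function(terms, label) {
  hit <- Filter(function(t) t$label == label, terms)
  expect_length(hit, 1)
  hit[[1]]
}

test_that("mortality bound syntax normalises strict bounds losslessly", {
  expect_identical(unclass(parse_mortality_bounds(">=5"))[c("lo", "hi")],
                   list(lo = 5L, hi = 100L))
  expect_identical(unclass(parse_mortality_bounds(">50, <= 98"))[c("lo", "hi")],
                   list(lo = 51L, hi = 98L))
  expect_identical(unclass(parse_mortality_bounds("<= 98"))[c("lo", "hi")],
                   list(lo = 0L, hi = 98L))
  expect_identical(unclass(parse_mortality_bounds(">50"))[c("lo", "hi")],
                   list(lo = 51L, hi = 100L))
  expect_error(mortality_range(50.5, 60), class = "eqonto_range_error")
  expect_error(mortality_range(60, 50), class = "eqonto_range_error")
  expect_error(parse_mortality_bounds("about half"),
               class = "eqonto_range_error")
})

test_that("the generated term set has the stated size and bands", {
  # 3 pre-adult stages x {some,most,all} x {during, before end of} + 3 core
  expect_length(lterms, 21)
  lethal <- lterms[["FBcv_0000351"]]
  expect_identical(c(lethal$range$lo, lethal$range$hi), c(98L, 100L))
  expect_identical(lethal$age$form, "precedes")
  expect_identical(lethal$age$stage, fly_chain$ids[4])
  partial <- lterms[["FBcv_0000352"]]
  expect_identical(c(partial$range$lo, partial$range$hi), c(51L, 98L))
  incmort <- lterms[["FBcv_0002004"]]
  expect_identical(c(incmort$range$lo, incmort$range$hi), c(5L, 100L))
  expect_identical(incmort$age$form, "any")
  all_emb <- by_label(lterms, "lethal - all die during embryonic stage")
  expect_identical(c(all_emb$range$lo, all_emb$range$hi), c(98L, 100L))

  # smallest valid chain: one pre-adult stage
  tiny <- stage_chain(c("S_0000001", "S_0000002"),
                      c("embryonic stage", "mature adult stage"))
  expect_length(generate_lethal_phase_terms(tiny), 9)
  # short-lived variant is opt-in
  expect_length(generate_lethal_phase_terms(fly_chain,
                                            with_short_lived = TRUE), 22)
  # a chain that never reaches adulthood is rejected
  noadult <- stage_chain(c("S_0000001", "S_0000002"),
                         c("embryonic stage", "larval stage"))
  expect_error(generate_lethal_phase_terms(noadult),
               class = "eqonto_usage_error")
  # regeneration is stable
  expect_identical(names(generate_lethal_phase_terms(fly_chain)),
                   names(lterms))
})

test_that("subsumption between lethal-phase terms follows band and window", {
  all_emb <- by_label(lterms, "lethal - all die during embryonic stage")
  lethal <- lterms[["FBcv_0000351"]]
  partial <- lterms[["FBcv_0000352"]]
  expect_true(lethal_subsumes(all_emb, lethal, fly_chain))
  expect_false(lethal_subsumes(lethal, all_emb, fly_chain))
  expect_true(lethal_subsumes(lethal, lethal, fly_chain))
  # overlapping but non-nested bands subsume in neither direction
  expect_false(lethal_subsumes(partial, lethal, fly_chain))
  expect_false(lethal_subsumes(lethal, partial, fly_chain))
  # everything generated sits under 'increased mortality'
  for (t in lterms) {
    expect_true(lethal_subsumes(t, lterms[["FBcv_0002004"]], fly_chain),
                label = t$label)
  }
  other <- stage_chain(c("S_0000001", "S_0000002"), c("a", "adult"))
  tother <- generate_lethal_phase_terms(other)[[1]]
  expect_error(lethal_subsumes(tother, lethal, fly_chain),
               class = "eqonto_usage_error")
})

test_that("the flat set classifies into a nested DAG with one top", {
  h <- classify_lethal(lterms, fly_chain)
  # flat before: the generator emits no parent links at all
  expect_true(all(vapply(lterms, function(t) is.null(t$is_a), logical(1))))
  # nested after: strictly more edges than terms minus one
  expect_gte(nrow(h$direct_edges), length(lterms) - 1)
  # unique top element among the collapsed classes
  tops <- setdiff(unique(c(h$direct_edges$parent, h$direct_edges$child)),
                  h$direct_edges$child)
  expect_identical(tops, "FBcv_0002004")
  # the characteristic chain: all die during S0 < all die before end of S0
  # < all die before end of S1 < ... < lethal, all present in the closure
  key <- function(child, parent) paste(child$id, parent$id)
  closure_keys <- paste(h$closure_edges$child, h$closure_edges$parent)
  chain_terms <- c(list(by_label(lterms,
                                 "lethal - all die during embryonic stage")),
                   lapply(fly_chain$labels[1:3], function(s) {
                     by_label(lterms, paste0("lethal - all die before end of ", s))
                   }),
                   list(lterms[["FBcv_0000351"]]))
  for (i in seq_len(length(chain_terms) - 1)) {
    expect_true(key(chain_terms[[i]], chain_terms[[i + 1]]) %in% closure_keys,
                label = paste(chain_terms[[i]]$label, "under",
                              chain_terms[[i + 1]]$label))
  }
  # 'all die before the end of the last pre-adult stage' IS 'lethal'
  expect_true(any(vapply(h$equivalence_groups, function(g) {
    "FBcv_0000351" %in% g
  }, logical(1))))
  # single term classifies to no edges
  h1 <- classify_lethal(lterms["FBcv_0000351"], fly_chain)
  expect_identical(nrow(h1$direct_edges), 0L)
})

test_that("model checking confirms the band-membership examples", {
  lethal <- lterms[["FBcv_0000351"]]
  partial <- lterms[["FBcv_0000352"]]
  all_emb <- by_label(lterms, "lethal - all die during embryonic stage")
  # a population dying out during the embryonic stage is lethal
  expect_true(model_check_subsumption(all_emb, lethal, fly_chain))
  # 75% mortality before adulthood: partially lethal but never lethal
  seventy_five <- eqonto:::lethal_phase_term(
    "TMP_0000001", "three quarters die",
    mortality_range(75, 75), age_constraint("precedes", fly_chain$ids[4]),
    fly_chain)
  expect_true(model_check_subsumption(seventy_five, partial, fly_chain))
  expect_false(model_check_subsumption(seventy_five, lethal, fly_chain))
  expect_error(model_check_subsumption(lethal, partial, fly_chain,
                                       population_sizes = 5),
               class = "eqonto_usage_error")
})

test_that("annotation returns the most specific applicable classes", {
  obs <- c(FBdv_00005289 = 100, FBdv_00005336 = 0, FBdv_00005342 = 0)
  got <- annotate_mortality(obs, lterms, fly_chain)
  expect_identical(unname(vapply(lterms[got], function(t) t$label,
                                 character(1))),
                   "lethal - all die during embryonic stage")

  expect_identical(annotate_mortality(
    c(FBdv_00005289 = 0, FBdv_00005336 = 0, FBdv_00005342 = 0),
    lterms, fly_chain), character(0))

  got <- annotate_mortality(
    c(FBdv_00005289 = 30, FBdv_00005336 = 40, FBdv_00005342 = 0),
    lterms, fly_chain)
  expect_true("FBcv_0000352" %in% got)   # partially lethal - majority die

  expect_error(annotate_mortality(c(FBdv_00005289 = 120, FBdv_00005336 = 0,
                                    FBdv_00005342 = 0),
                                  lterms, fly_chain),
               class = "eqonto_range_error")
  expect_error(annotate_mortality(c(FBdv_00005289 = 10.5, FBdv_00005336 = 0,
                                    FBdv_00005342 = 0),
                                  lterms, fly_chain),
               class = "eqonto_range_error")
  expect_error(annotate_mortality(c(FBdv_00005289 = 10), lterms, fly_chain),
               class = "eqonto_usage_error")
})

test_that("annotation output is always an antichain", {
  set.seed(45)
  for (rep in 1:40) {
    obs <- setNames(sample(0:100, 3, replace = TRUE), fly_chain$ids[1:3])
    got <- annotate_mortality(obs, lterms, fly_chain)
    for (a in got) for (b in got) {
      if (a == b) next
      expect_false(lethal_subsumes(lterms[[a]], lterms[[b]], fly_chain) &&
                     !lethal_subsumes(lterms[[b]], lterms[[a]], fly_chain),
                   label = paste(a, b, paste(obs, collapse = ",")))
    }
  }
})

test_that("the mortality TSV reader feeds annotation", {
  path <- system.file("extdata", "mortality-example.tsv", package = "eqonto")
  expect_true(nzchar(path))
  obs <- read_mortality_tsv(path)
  got <- annotate_mortality(obs, lterms, fly_chain)
  expect_true(length(got) >= 1)
})
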