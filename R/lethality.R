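#' Mortality-rate ranges
#'
#' An increased-mortality rate is the percentage of a population dying in
#' excess of the wild-type rate for the same stage, recorded as a whole
#' number between 0 and 100 (fractional values are excluded so the ranges
#' stay within what datatype reasoning handles). A range is a closed integer
#' interval; printed strict bounds normalise losslessly to closed ones
#' (`>50` becomes `>=51`).
#'
#' @param lo,hi whole-number percentages with `0 <= lo <= hi <= 100`.
#' @return an object of class `mortality_range`.
#' @examples
#' parse_mortality_bounds(">50, <= 98")  # the 'partially lethal' band [51, 98]
#' @export
mortality_range <- function(lo, hi) {
  if (lo != round(lo) || hi != round(hi)) {
    stop_eqonto("eqonto_range_error",
                "mortality bounds must be whole-number percentages")
  }
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo < 0 || hi > 100 || lo > hi) {
    stop_eqonto("eqonto_range_error",
                sprintf("invalid mortality range [%d, %d]", lo, hi))
  }
  structure(list(lo = lo, hi = hi), class = "mortality_range")
}

#' @export
print.mortality_range <- function(x, ...) {
  cat(sprintf("[%d, %d]%%\n", x$lo, x$hi))
  invisible(x)
}

#' @rdname mortality_range
#' @param text printed bound syntax, e.g. `">=5"`, `"<= 98"`,
#'   `">50, <= 98"`; comma-separated comparisons against whole numbers.
#' @export
parse_mortality_bounds <- function(text) {
  text <- gsub("^\\[|\\]$", "", trimws(text))
  lo <- 0L; hi <- 100L
  for (tok in trimws(strsplit(text, ",", fixed = TRUE)[[1]])) {
    m <- regmatches(tok, regexec("^(>=|<=|>|<)?[ \t]*([0-9]+)$", tok))[[1]]
    if (length(m) == 0) {
      stop_eqonto("eqonto_range_error", paste0("malformed bound: ", tok))
    }
    v <- as.integer(m[3])
    switch(m[2],
           ">=" = { lo <- max(lo, v) },
           ">"  = { lo <- max(lo, v + 1L) },
           "<=" = { hi <- min(hi, v) },
           "<"  = { hi <- min(hi, v - 1L) },
           { lo <- max(lo, v); hi <- min(hi, v) })   # bare number: exact
  }
  mortality_range(lo, hi)
}

range_subsumed <- function(r1, r2) r1$lo >= r2$lo && r1$hi <= r2$hi

lethal_phase_term <- function(id, label, range, age, chain) {
  structure(list(id = curie_short(id), label = label, range = range,
                 age = age, chain_ids = chain$ids),
            class = "lethal_phase_term")
}

#' @export
print.lethal_phase_term <- function(x, ...) {
  cat(sprintf("%s '%s' [%d, %d]%% %s%s\n", x$id, x$label,
              x$range$lo, x$range$hi, x$age$form,
              if (is.null(x$age$stage)) "" else paste0(" ", x$age$stage)))
  invisible(x)
}

# Deterministic id minting: polynomial hash of the (quantifier, mode, stage)
# key so regeneration is stable across runs and platforms.
mint_lethal_local <- function(key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 9999991
  sprintf("%07d", h)
}

#' Generate the flat lethal-phase term set for a stage chain
#'
#' For each pre-adult stage the generator emits six terms: the cross-product
#' of the quantifier bands some (>= 5%), most (>= 50%) and 'all' (>= 98%)
#' with the two timing modes die-during-the-stage and
#' die-before-the-end-of-the-stage. Three core terms complete the set:
#' 'increased mortality' (>= 5% at any stage of life), 'lethal' (>= 98%
#' before the mature adult stage -- the cutoff absorbs rare escaper
#' survivors) and 'partially lethal - majority die' (>50% and <= 98%,
#' normalised to the closed band \[51, 98\]). The emitted list is completely
#' flat -- no parent links -- and only [classify_lethal()] nests it.
#'
#' @param chain a [stage_chain()] whose final stage is the mature adult
#'   stage (an error otherwise).
#' @param thresholds named integer vector with entries `some`, `most`,
#'   `all`; `0 < some <= most <= all <= 100`.
#' @param with_short_lived also emit a 'short lived' term (increased
#'   mortality during the adult stage). This encoding is this toolkit's
#'   reading: the class is described as covering stages where wild-type
#'   death rates run high, but carries no published axiom, so it is
#'   generated only behind this flag.
#' @return a list of `lethal_phase_term` objects; for a chain with `k`
#'   pre-adult stages, `6 * k + 3` terms (plus one with
#'   `with_short_lived = TRUE`).
#' @export
generate_lethal_phase_terms <- function(chain,
                                        thresholds = c(some = 5, most = 50,
                                                       all = 98),
                                        with_short_lived = FALSE) {
  stopifnot(inherits(chain, "stage_chain"))
  th <- thresholds
  if (!all(c("some", "most", "all") %in% names(th)) ||
      !(0 < th[["some"]] && th[["some"]] <= th[["most"]] &&
        th[["most"]] <= th[["all"]] && th[["all"]] <= 100)) {
    stop_eqonto("eqonto_usage_error",
                "thresholds must satisfy 0 < some <= most <= all <= 100")
  }
  n <- length(chain$ids)
  adult <- chain$ids[n]
  if (!grepl("adult", chain$labels[n], ignore.case = TRUE)) {
    stop_eqonto("eqonto_usage_error",
                "the stage chain lacks a final adult stage")
  }

  terms <- list(
    lethal_phase_term("FBcv_0002004", "increased mortality",
                      mortality_range(th[["some"]], 100),
                      age_constraint("any"), chain),
    lethal_phase_term("FBcv_0000351", "lethal",
                      mortality_range(th[["all"]], 100),
                      age_constraint("precedes", adult), chain),
    lethal_phase_term("FBcv_0000352", "partially lethal - majority die",
                      mortality_range(th[["most"]] + 1L, th[["all"]]),
                      age_constraint("precedes", adult), chain))
  if (with_short_lived) {
    terms <- c(terms, list(
      lethal_phase_term("FBcv_0000385", "short lived",
                        mortality_range(th[["some"]], 100),
                        age_constraint("during", adult), chain)))
  }

  quant_label <- c(some = "some die", most = "majority die",
                   all = "lethal - all die")
  for (i in seq_len(n - 1L)) {
    sid <- chain$ids[i]
    slabel <- chain$labels[i]
    for (q in c("some", "most", "all")) {
      for (mode in c("during", "before_end_of")) {
        label <- paste0(quant_label[[q]], " ",
                        if (mode == "during") "during " else "before end of ",
                        slabel)
        id <- paste0("LP_", mint_lethal_local(paste(q, mode, sid)))
        terms <- c(terms, list(
          lethal_phase_term(id, label, mortality_range(th[[q]], 100),
                            age_constraint(mode, sid), chain)))
      }
    }
  }

  ids <- vapply(terms, function(t) t$id, character(1))
  if (anyDuplicated(ids)) {
    stop_eqonto("eqonto_id_error",
                paste0("minted id collision: ", ids[duplicated(ids)][1]))
  }
  names(terms) <- ids
  terms
}

#' Subsumption between lethal-phase terms
#'
#' `t1` is subsumed by `t2` iff its mortality band is contained in `t2`'s as
#' an integer interval and its age window is contained in `t2`'s
#' ([age_subsumes()]). This is the structural counterpart of the OWL
#' entailment over the population axioms, and [model_check_subsumption()]
#' provides the independent finite-model oracle for it.
#'
#' @param t1,t2 `lethal_phase_term` objects generated over `chain`.
#' @param chain the [stage_chain()] both terms were generated over; terms
#'   from a different chain raise an error.
#' @return `TRUE` or `FALSE`.
#' @export
lethal_subsumes <- function(t1, t2, chain) {
  stopifnot(inherits(t1, "lethal_phase_term"),
            inherits(t2, "lethal_phase_term"))
  if (!identical(t1$chain_ids, chain$ids) ||
      !identical(t2$chain_ids, chain$ids)) {
    stop_eqonto("eqonto_usage_error",
                "terms were generated over a different stage chain")
  }
  range_subsumed(t1$range, t2$range) &&
    age_subsumes(chain, t1$age, t2$age)
}

#' Classify a flat lethal-phase term set
#'
#' Computes the pairwise subsumption closure of the terms, reports mutually
#' subsuming pairs as equivalence groups (e.g. 'lethal' and 'all die before
#' the end of the last pre-adult stage' denote the same band and window),
#' and transitively reduces the remainder into a direct-subclass DAG. For
#' the default thresholds the result is a connected DAG whose unique top
#' element is 'increased mortality'.
#'
#' @param terms list of `lethal_phase_term` objects (distinct ids).
#' @param chain the [stage_chain()] the terms were generated over.
#' @return an `inferred_hierarchy`; every edge has provenance `"inferred"`.
#' @export
classify_lethal <- function(terms, chain) {
  ids <- vapply(terms, function(t) t$id, character(1))
  if (anyDuplicated(ids)) {
    stop_eqonto("eqonto_duplicate_id", "lethal-phase terms must be distinct")
  }
  names(terms) <- ids
  ids <- sort_c(ids)

  sub <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (x in ids) for (y in ids) {
    if (x != y) sub[x, y] <- lethal_subsumes(terms[[x]], terms[[y]], chain)
  }

  closure <- which(sub, arr.ind = TRUE)
  closure <- edge_df(ids[closure[, 1]], ids[closure[, 2]])
  closure <- normalize_edges(closure)

  mutual_keys <- intersect(edge_keys(closure),
                           paste(closure$parent, closure$child, sep = "\r"))
  groups <- equivalence_groups_from(edge_keys(closure)[
    edge_keys(closure) %in% mutual_keys])

  rep_of <- stats::setNames(as.list(ids), ids)
  for (g in groups) {
    r <- sort_c(g)[1]
    for (m in g) rep_of[[m]] <- r
  }
  collapsed <- edge_df(unlist(rep_of[closure$child], use.names = FALSE),
                       unlist(rep_of[closure$parent], use.names = FALSE))
  collapsed <- normalize_edges(collapsed)
  collapsed <- collapsed[collapsed$child != collapsed$parent, , drop = FALSE]
  direct <- transitive_reduction(collapsed)
  make_inferred_hierarchy(direct,
                          rep("inferred", nrow(direct)),
                          groups, closure, ids)
}

# expand.grid of member death stages, cached per (n_stages, n_members)
assignments_cache <- new.env(parent = emptyenv())
member_assignments <- function(n_stages, n_members) {
  key <- paste(n_stages, n_members)
  if (!exists(key, envir = assignments_cache, inherits = FALSE)) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(n_stages)), n_members)))
    assign(key, grid, envir = assignments_cache)
  }
  get(key, envir = assignments_cache)
}

#' Finite-population model checking of lethal-phase subsumption
#'
#' Independent semantic oracle for [lethal_subsumes()]. A population model
#' assigns each of `n` members a death-stage index (the final, adult stage
#' doubles as "survives to adulthood") together with an increased-mortality
#' rate drawn from a coarse grid covering every band boundary. A model
#' satisfies a term when its rate lies in the term's band and every member's
#' death stage lies in the term's age window. `t1` is subsumed by `t2` iff
#' every satisfying model of `t1` satisfies `t2`.
#'
#' @param t1,t2 `lethal_phase_term` objects.
#' @param chain their [stage_chain()].
#' @param population_sizes member counts to enumerate (kept small; the
#'   distinctions the bands make need no more than a handful of members).
#' @param rate_grid mortality percentages to enumerate; the default hits
#'   both sides of the 5/50/98 cutoffs.
#' @return `TRUE` or `FALSE`.
#' @export
model_check_subsumption <- function(t1, t2, chain, population_sizes = 1:3,
                                    rate_grid = c(0, 5, 50, 51, 97, 98, 100)) {
  if (any(population_sizes > 4)) {
    stop_eqonto("eqonto_usage_error",
                "population sizes above 4 are not supported (intractable)")
  }
  # refine the grid with the two terms' own band endpoints so that every
  # band boundary involved in this comparison is represented by a model
  rate_grid <- sort(unique(c(rate_grid, t1$range$lo, t1$range$hi,
                             t2$range$lo, t2$range$hi)))
  n_stages <- length(chain$ids)
  w1 <- index_set(chain, t1$age) + 1L
  w2 <- index_set(chain, t2$age) + 1L
  rate_ok1 <- rate_grid >= t1$range$lo & rate_grid <= t1$range$hi
  rate_ok2 <- rate_grid >= t2$range$lo & rate_grid <= t2$range$hi
  # a rate satisfying t1 but not t2 refutes subsumption outright (provided
  # some member assignment satisfies t1's window, which w1 nonempty gives)
  if (length(w1) == 0) return(TRUE)   # unsatisfiable age window
  if (any(rate_ok1 & !rate_ok2)) return(FALSE)
  if (!any(rate_ok1)) return(TRUE)
  for (n in population_sizes) {
    grid <- member_assignments(n_stages, n)
    in_w1 <- matrix(grid %in% w1, nrow(grid), n)
    sat1 <- rowSums(in_w1) == n
    if (!any(sat1)) next
    in_w2 <- matrix(grid %in% w2, nrow(grid), n)
    sat2 <- rowSums(in_w2) == n
    if (any(sat1 & !sat2)) return(FALSE)
  }
  TRUE
}

#' Annotate a mortality observation with lethal-phase terms
#'
#' Given per-stage increased-mortality percentages (wild-type baseline
#' already excluded), finds every generated term whose band contains the
#' mortality accumulated over its age window, then returns the most
#' specific of them: the antichain of applicable terms under
#' [lethal_subsumes()].
#'
#' @param obs named integer vector of increased-mortality percentages; one
#'   entry per pre-adult stage, named by stage id (or label). Values must
#'   be whole numbers in \[0, 100\].
#' @param terms the generated lethal-phase term list.
#' @param chain the [stage_chain()].
#' @return sorted character vector of term ids (possibly empty: observations
#'   entirely below the 5% floor match nothing).
#' @export
annotate_mortality <- function(obs, terms, chain) {
  n <- length(chain$ids)
  pre_adult <- chain$ids[-n]
  idx <- vapply(names(obs), function(nm) stage_index(chain, nm), integer(1))
  if (any(is.na(idx))) {
    stop_eqonto("eqonto_unknown_id", "observation names unknown stages")
  }
  if (!setequal(chain$ids[idx], pre_adult)) {
    stop_eqonto("eqonto_usage_error",
                "observations must cover every pre-adult stage exactly once")
  }
  if (any(obs < 0 | obs > 100)) {
    stop_eqonto("eqonto_range_error",
                "mortality observations must lie in [0, 100]")
  }
  if (any(obs != round(obs))) {
    stop_eqonto("eqonto_range_error",
                "mortality observations must be whole numbers")
  }
  by_index0 <- stats::setNames(as.numeric(obs), idx - 1L)  # 0-based

  applies <- vapply(terms, function(t) {
    w <- index_set(chain, t$age)
    w <- w[w <= n - 2L]    # adult stage carries no observation
    total <- sum(by_index0[as.character(w)], na.rm = TRUE)
    total >= t$range$lo && total <= t$range$hi
  }, logical(1))
  applicable <- terms[applies]
  if (length(applicable) == 0) return(character(0))

  keep <- vapply(seq_along(applicable), function(i) {
    t <- applicable[[i]]
    !any(vapply(seq_along(applicable), function(j) {
      if (i == j) return(FALSE)
      o <- applicable[[j]]
      lethal_subsumes(o, t, chain) && !lethal_subsumes(t, o, chain)
    }, logical(1)))
  }, logical(1))
  minimal <- applicable[keep]
  # mutually subsuming terms denote the same class; report its
  # lexicographically least id, matching the collapse in classify_lethal()
  reps <- vapply(seq_along(minimal), function(i) {
    t <- minimal[[i]]
    equiv <- vapply(minimal, function(o) {
      lethal_subsumes(o, t, chain) && lethal_subsumes(t, o, chain)
    }, logical(1))
    sort_c(vapply(minimal[equiv], function(o) o$id, character(1)))[1]
  }, character(1))
  sort_c(unique(reps))
}

#' @rdname annotate_mortality
#' @param path two-column TSV (stage id, percent); `#` comments allowed, no
#'   header.
#' @export
read_mortality_tsv <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 2) {
    stop_eqonto("eqonto_usage_error",
                "mortality table must have two columns: stage id, percent")
  }
  stats::setNames(as.numeric(tab[[2]]), curie_short(as.character(tab[[1]])))
}
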