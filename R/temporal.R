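#' The Allen interval relation subset used for life-stage reasoning
#'
#' Relative timing over developmental stages uses a subset of the Allen
#' interval algebra: precedes (p), preceded_by (P), meets (m), met_by (M),
#' during (d), starts (s), finishes (f), plus explicit equality. `p` is the
#' inverse of `P` and `m` of `M`; `equals` is self-inverse. Composition of
#' two subset relations can produce base relations outside the subset
#' (overlaps, contains, ...); these are reported collectively as the marker
#' `"other"`.
#'
#' Composition is computed analytically from endpoint order relations: each
#' of the thirteen base relations is encoded as the four order relations
#' between the two intervals' endpoints, compositions are taken in the
#' point algebra on \{<, =, >\}, and the resulting constraints are decoded
#' back into base relations. (The common claim that 'meets' is transitive
#' is false in the standard algebra -- `m ; m = p` -- and the standard table
#' is what is implemented here; the grid-enumeration tests exercise this.)
#'
#' @return `allen_relations()` returns a data frame of the subset relations
#'   with their one-letter abbreviations and inverses.
#' @export
allen_relations <- function() {
  data.frame(
    name = c("precedes", "preceded_by", "meets", "met_by", "during",
             "starts", "finishes", "equals"),
    letter = c("p", "P", "m", "M", "d", "s", "f", "="),
    inverse = c("preceded_by", "precedes", "met_by", "meets", "contains",
                "started_by", "finished_by", "equals"),
    stringsAsFactors = FALSE)
}

ALLEN_SUBSET <- c("precedes", "preceded_by", "meets", "met_by", "during",
                  "starts", "finishes", "equals")

# Endpoint matrices: relations (a1 vs c1, a1 vs c2, a2 vs c1, a2 vs c2)
# for "a <rel> c", with interval validity a1 < a2, c1 < c2.
ALLEN_BASE13 <- list(
  precedes      = c("<", "<", "<", "<"),
  meets         = c("<", "<", "=", "<"),
  overlaps      = c("<", "<", ">", "<"),
  finished_by   = c("<", "<", ">", "="),
  contains      = c("<", "<", ">", ">"),
  starts        = c("=", "<", ">", "<"),
  equals        = c("=", "<", ">", "="),
  started_by    = c("=", "<", ">", ">"),
  during        = c(">", "<", ">", "<"),
  finishes      = c(">", "<", ">", "="),
  overlapped_by = c(">", "<", ">", ">"),
  met_by        = c(">", "=", ">", ">"),
  preceded_by   = c(">", ">", ">", ">"))

#' @rdname allen_relations
#' @param r a subset relation name.
#' @export
allen_inverse <- function(r) {
  tab <- c(precedes = "preceded_by", preceded_by = "precedes",
           meets = "met_by", met_by = "meets", during = "contains",
           starts = "started_by", finishes = "finished_by",
           equals = "equals")
  out <- unname(tab[r])
  if (any(is.na(out))) {
    stop_eqonto("eqonto_usage_error",
                paste0("unknown relation: ", paste(r[is.na(out)], collapse = ", ")))
  }
  out
}

# Point algebra composition on {<,=,>}: x holds between u,v and y between
# v,w; returns the possible relations between u,w.
pa_compose <- function(x, y) {
  if (x == "=") return(y)
  if (y == "=") return(x)
  if (x == y) return(x)          # <;< = < and >;> = >
  c("<", "=", ">")               # <;> and >;< are unconstrained
}

#' Compose two Allen relations from the subset
#'
#' @param r1,r2 subset relation names (see [allen_relations()]).
#' @return sorted character vector of subset relation names, possibly
#'   including the marker `"other"` when the standard composition contains
#'   base relations outside the subset.
#' @examples
#' allen_compose("during", "precedes")   # "precedes"
#' allen_compose("meets", "meets")       # "precedes": meets is not transitive
#' @export
allen_compose <- function(r1, r2) {
  for (r in c(r1, r2)) {
    if (!(r %in% ALLEN_SUBSET)) {
      stop_eqonto("eqonto_usage_error", paste0("unknown subset relation: ", r))
    }
  }
  m1 <- ALLEN_BASE13[[r1]]
  m2 <- ALLEN_BASE13[[r2]]
  # cell index helper for (a_i vs b_k) layout: (1,1)=1 (1,2)=2 (2,1)=3 (2,2)=4
  cell <- function(m, i, k) m[(i - 1L) * 2L + k]
  possible <- vector("list", 4)
  for (i in 1:2) for (j in 1:2) {
    via1 <- pa_compose(cell(m1, i, 1), cell(m2, 1, j))
    via2 <- pa_compose(cell(m1, i, 2), cell(m2, 2, j))
    possible[[(i - 1L) * 2L + j]] <- intersect(via1, via2)
  }
  hits <- names(Filter(function(m) {
    all(vapply(1:4, function(k) m[k] %in% possible[[k]], logical(1)))
  }, ALLEN_BASE13))
  out <- ifelse(hits %in% ALLEN_SUBSET, hits, "other")
  sort_c(unique(out))
}

#' A linearly ordered chain of life stages
#'
#' Life stages (embryonic, larval, pupal, adult, ...) form a chain in which
#' each stage is `immediately_preceded_by` the previous one -- the Allen
#' relation 'meets' read in reverse. Death timing is modeled at stage
#' granularity: each organism has a single death-stage index.
#'
#' @param ids character vector of stage term ids, in chronological order.
#' @param labels character vector of stage labels, same length.
#' @return an object of class `stage_chain`.
#' @export
stage_chain <- function(ids, labels = ids) {
  ids <- curie_short(ids)
  if (length(ids) < 2) {
    stop_eqonto("eqonto_usage_error", "a stage chain needs at least two stages")
  }
  if (anyDuplicated(ids)) {
    stop_eqonto("eqonto_usage_error", "duplicate stages in chain")
  }
  stopifnot(length(labels) == length(ids))
  structure(list(ids = ids, labels = as.character(labels)),
            class = "stage_chain")
}

#' @export
print.stage_chain <- function(x, ...) {
  cat("<stage_chain: ", paste(x$labels, collapse = " -> "), ">\n", sep = "")
  invisible(x)
}

#' @rdname stage_chain
#' @param doc an [obo_document()] whose stage terms are linked by
#'   `relationship: immediately_preceded_by` lines.
#' @param relation the relationship tag carrying the chain links.
#' @export
stage_chain_from_obo <- function(doc, relation = "immediately_preceded_by") {
  terms <- Filter(function(t) !t$is_obsolete && !t$is_anonymous, doc$terms)
  pred_of <- list()   # stage -> its immediate predecessor
  for (t in terms) {
    rel <- t$relationships
    hit <- rel$target[rel$rel == relation]
    if (length(hit) > 1) {
      stop_eqonto("eqonto_usage_error",
                  paste0("stage ", t$id, " has multiple predecessors"))
    }
    if (length(hit) == 1) pred_of[[t$id]] <- hit
  }
  ids <- vapply(terms, function(t) t$id, character(1))
  first <- setdiff(ids, names(pred_of))
  if (length(first) != 1) {
    stop_eqonto("eqonto_usage_error",
                paste0("stage chain must have exactly one initial stage, found: ",
                       paste(sort_c(first), collapse = ", ")))
  }
  succ_of <- stats::setNames(names(pred_of), unlist(pred_of))
  chain <- first
  while (chain[length(chain)] %in% names(succ_of)) {
    nxt <- succ_of[[chain[length(chain)]]]
    if (nxt %in% chain) {
      stop_eqonto("eqonto_cycle", "cycle in stage chain")
    }
    chain <- c(chain, nxt)
  }
  if (length(chain) != length(ids)) {
    stop_eqonto("eqonto_usage_error",
                "stage terms do not form a single linear chain")
  }
  labels <- vapply(chain, function(id) doc$terms[[id]]$name %||% id,
                   character(1))
  stage_chain(chain, unname(labels))
}

stage_index <- function(chain, stage) {
  stage <- curie_short(stage)
  i <- match(stage, chain$ids)
  if (is.na(i)) {
    i <- match(stage, chain$labels)
  }
  if (is.na(i)) {
    stop_eqonto("eqonto_unknown_id", paste0("unknown stage: ", stage))
  }
  i
}

#' Allen relation between two stages of a chain
#'
#' Stages of a chain are consecutive, non-overlapping intervals: the same
#' stage is `equals`, adjacent stages are `meets` / `met_by`, and
#' non-adjacent stages are `precedes` / `preceded_by`.
#'
#' @param chain a [stage_chain()].
#' @param a,b stage ids (or labels).
#' @return a single relation name.
#' @export
stage_relation <- function(chain, a, b) {
  ia <- stage_index(chain, a)
  ib <- stage_index(chain, b)
  if (ia == ib) return("equals")
  if (ib == ia + 1L) return("meets")
  if (ia == ib + 1L) return("met_by")
  if (ib > ia) "precedes" else "preceded_by"
}

#' Age constraints over a stage chain
#'
#' An age constraint restricts the death stage of every member of a
#' population: `precedes(S)` (death strictly before stage S), `during(S)`
#' (death during S), `before_end_of(S)` (death during or before S, i.e.
#' `during` union `precedes`), or `any` (no restriction). Its canonical
#' semantics is the set of death-stage indices it denotes, given by
#' [index_set()] (0-based, so `precedes(S_k)` is \{0, ..., k-1\}).
#'
#' @param form one of `"precedes"`, `"during"`, `"before_end_of"`, `"any"`.
#' @param stage a stage id, required unless `form = "any"`.
#' @return an object of class `age_constraint`.
#' @export
age_constraint <- function(form = c("precedes", "during", "before_end_of",
                                    "any"), stage = NULL) {
  form <- match.arg(form)
  if (form != "any" && is.null(stage)) {
    stop_eqonto("eqonto_usage_error",
                paste0("age constraint '", form, "' requires a stage"))
  }
  structure(list(form = form,
                 stage = if (!is.null(stage)) curie_short(stage)),
            class = "age_constraint")
}

#' @export
print.age_constraint <- function(x, ...) {
  if (x$form == "any") cat("<age: any>\n")
  else cat("<age: ", x$form, " ", x$stage, ">\n", sep = "")
  invisible(x)
}

#' @rdname age_constraint
#' @param chain a [stage_chain()].
#' @param constraint an `age_constraint`.
#' @return `index_set()` returns the 0-based stage indices the constraint
#'   permits as death stages.
#' @export
index_set <- function(chain, constraint) {
  stopifnot(inherits(constraint, "age_constraint"))
  n <- length(chain$ids)
  if (constraint$form == "any") return(seq_len(n) - 1L)
  k <- stage_index(chain, constraint$stage) - 1L   # 0-based
  switch(constraint$form,
         precedes = if (k == 0L) integer(0) else seq_len(k) - 1L,
         during = k,
         before_end_of = seq_len(k + 1L) - 1L)
}

#' @rdname age_constraint
#' @param c1,c2 `age_constraint` objects.
#' @return `age_subsumes()` returns `TRUE` iff every death stage permitted
#'   by `c1` is permitted by `c2` (index-set inclusion).
#' @export
age_subsumes <- function(chain, c1, c2) {
  all(index_set(chain, c1) %in% index_set(chain, c2))
}
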