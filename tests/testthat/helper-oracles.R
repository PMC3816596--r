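# Independent oracle implementations used by the property tests. These are
# deliberately written with different algorithms from the package code
# (plain recursion, grid enumeration, conjunct mapping) so that agreement
# between the two routes is meaningful.

# --- naive recursive ancestor closure over an edge data frame -------------

oracle_ancestors <- function(edges, node, seen = character(0)) {
  parents <- setdiff(edges$parent[edges$child == node], seen)
  out <- parents
  for (p in parents) {
    out <- union(out, oracle_ancestors(edges, p, union(seen, out)))
  }
  out
}

# --- Allen base relation of two integer-endpoint intervals ----------------

rel13 <- function(a1, a2, c1, c2) {
  if (a2 < c1) return("precedes")
  if (a2 == c1) return("meets")
  if (a1 > c2) return("preceded_by")
  if (a1 == c2) return("met_by")
  if (a1 == c1 && a2 == c2) return("equals")
  if (a1 == c1) return(if (a2 < c2) "starts" else "started_by")
  if (a2 == c2) return(if (a1 > c1) "finishes" else "finished_by")
  if (a1 > c1 && a2 < c2) return("during")
  if (a1 < c1 && a2 > c2) return("contains")
  if (a1 < c1) "overlaps" else "overlapped_by"
}

ALLEN_SUBSET_NAMES <- c("precedes", "preceded_by", "meets", "met_by",
                        "during", "starts", "finishes", "equals")

# Composition by brute-force enumeration of interval triples on the
# integer grid [0, hi].
grid_compose <- function(r1, r2, hi = 8) {
  iv <- do.call(rbind, lapply(0:(hi - 1), function(i) {
    cbind(i, (i + 1):hi)
  }))
  n <- nrow(iv)
  relm <- matrix(NA_character_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    relm[i, j] <- rel13(iv[i, 1], iv[i, 2], iv[j, 1], iv[j, 2])
  }
  ab <- which(relm == r1, arr.ind = TRUE)
  bc <- which(relm == r2, arr.ind = TRUE)
  bc_by_b <- split(bc[, 2], bc[, 1])
  out <- character(0)
  for (k in seq_len(nrow(ab))) {
    cs <- bc_by_b[[as.character(ab[k, 2])]]
    if (!is.null(cs)) out <- union(out, relm[ab[k, 1], cs])
  }
  sort(unique(ifelse(out %in% ALLEN_SUBSET_NAMES, out, "other")),
       method = "radix")
}

# --- homomorphism-search oracle for EQ subsumption ------------------------
# Expands unions to disjunct lists and maps each conjunct of the subsumer
# onto a conjunct of the subsumee with the same role, checking reflexive
# ancestor containment of the fillers with oracle_ancestors().

oracle_eq_subsumes <- function(d1, d2, imports) {
  edges <- do.call(rbind, lapply(imports, function(g) g$edges))
  filler_ok <- function(a, b) {
    a == b || b %in% oracle_ancestors(edges, a)
  }
  conjuncts <- function(d) {
    out <- list(list(role = "genus", filler = d$quality))
    if (!is.null(d$entity)) {
      out <- c(out, list(list(role = "inheres_in", filler = d$entity)))
    }
    if (!is.null(d$towards)) {
      out <- c(out, list(list(role = "towards", filler = d$towards)))
    }
    if (d$abnormal) {
      out <- c(out, list(list(role = "qualifier", filler = "abnormal")))
    }
    out
  }
  conj_sub <- function(a, b) {
    # every conjunct of b must map onto some conjunct of a
    all(vapply(conjuncts(b), function(cb) {
      any(vapply(conjuncts(a), function(ca) {
        ca$role == cb$role &&
          (cb$role == "qualifier" || filler_ok(ca$filler, cb$filler))
      }, logical(1)))
    }, logical(1)))
  }
  disjuncts <- function(d) if (is_eq_union(d)) d$operands else list(d)
  all(vapply(disjuncts(d1), function(a) {
    any(vapply(disjuncts(d2), function(b) conj_sub(a, b), logical(1)))
  }, logical(1)))
}

# --- shared fixture handles ----------------------------------------------

fixtures <- make_named_fixtures()
fixture_graphs <- fixture_imports(fixtures)
fly_chain <- stage_chain_from_obo(fixtures$fly_stages)

# A small random DAG as a plain edge data frame (independent of the
# package's fixture generator): each node links to 1-2 earlier nodes.
random_edge_df <- function(n, p_extra = 0.3) {
  edges <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  ids <- sprintf("N_%07d", seq_len(n))
  for (i in seq_len(n)[-1]) {
    k <- 1 + (runif(1) < p_extra && i > 2)
    parents <- ids[sample.int(i - 1, min(k, i - 1))]
    edges <- rbind(edges, data.frame(child = ids[i], parent = parents,
                                     stringsAsFactors = FALSE))
  }
  list(ids = ids, edges = edges)
}
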