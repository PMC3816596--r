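# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent (C collation) sort, so written artifacts are
# byte-identical across machines.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

empty_edges <- function() {
  data.frame(child = character(0), parent = character(0),
             stringsAsFactors = FALSE)
}

edge_df <- function(child, parent) {
  data.frame(child = as.character(child), parent = as.character(parent),
             stringsAsFactors = FALSE)
}

# Deterministic ordering and de-duplication of an edge table.
normalize_edges <- function(edges) {
  if (nrow(edges) == 0) return(empty_edges())
  edges <- unique(edges[, c("child", "parent")])
  edges <- edges[order_c(edges$child, edges$parent), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

edge_keys <- function(edges) paste(edges$child, edges$parent, sep = "\r")

stop_eqonto <- function(class, message) {
  stop(structured_condition(class, message))
}

structured_condition <- function(class, message) {
  structure(class = c(class, "eqonto_error", "error", "condition"),
            list(message = message, call = sys.call(-1)))
}
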