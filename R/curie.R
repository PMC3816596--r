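#' Compact prefixed identifiers (CURIEs)
#'
#' Ontology terms are identified by a namespace prefix and a zero-padded
#' numeric local part. Two renderings are used in the wild: the OWL "short
#' form" with an underscore (`GO_0006950`) and the OBO form with a colon
#' (`GO:0006950`). The two round-trip losslessly; this package uses the
#' short form as its internal canonical spelling.
#'
#' @param x character vector of identifiers in either rendering.
#' @return `curie_short()` and `curie_obo()` return the identifiers
#'   re-rendered; `curie_prefix()` / `curie_local()` return the components;
#'   `is_curie()` returns a logical vector.
#' @examples
#' curie_obo("GO_0006950")    # "GO:0006950"
#' curie_short("FBcv:0000439") # "FBcv_0000439"
#' @name curie
NULL

#' @rdname curie
#' @export
is_curie <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9]*[_:][0-9]+$", x)
}

#' @rdname curie
#' @export
curie_short <- function(x) sub(":", "_", x, fixed = TRUE)

#' @rdname curie
#' @export
curie_obo <- function(x) sub("_", ":", x, fixed = TRUE)

#' @rdname curie
#' @export
curie_prefix <- function(x) sub("[_:].*$", "", x)

#' @rdname curie
#' @export
curie_local <- function(x) sub("^[A-Za-z][A-Za-z0-9]*[_:]", "", x)

# Mint a short-form id from a prefix and an integer local part.
mint_curie <- function(prefix, n, width = 7) {
  sprintf("%s_%0*d", prefix, width, n)
}
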