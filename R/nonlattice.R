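# Non-lattice pair detection and subgraph extraction. In a lattice any two
# nodes have a unique maximal common descendant and a unique minimal common
# ancestor; pairs violating that signal structural defects such as missing
# concepts. A subgraph is built from a pair's maximal common descendants,
# the minimal common ancestors thereof, and everything on is-a paths
# between them; its size is its concept count.

#' Maximal common descendants of a concept pair
#'
#' The maximal elements of the set of shared lower bounds of `a` and `b` in
#' the is-a order (descendants-or-self, as in the lattice-theoretic
#' definition: a node is a lower bound of itself). Maximal means having no
#' ancestor that is also a shared lower bound. For an is-a-related pair
#' this is the lower concept itself, so only incomparable pairs can have
#' more than one.
#'
#' @param o An [ontology].
#' @param a,b Distinct concept ids.
#' @return Character vector of ids (possibly empty), sorted.
#' @export
maximal_common_descendants <- function(o, a, b) {
  assert_concept(o, a); assert_concept(o, b)
  if (a == b) stop("maximal_common_descendants requires two distinct concepts")
  dm <- descendant_map(o)
  common <- intersect(c(a, dm[[a]]), c(b, dm[[b]]))
  if (!length(common)) return(character(0L))
  am <- ancestor_map(o)
  keep <- vapply(common, function(x) !any(am[[x]] %in% common), logical(1L))
  sort(common[keep], method = "radix")
}

#' Minimal common ancestors of a concept set
#'
#' The minimal elements of the set of shared upper bounds (ancestors-or-
#' self) of the input concepts: shared upper bounds having no descendant
#' that is also a shared upper bound.
#'
#' @param o An [ontology].
#' @param concepts Non-empty character vector of concept ids.
#' @return Character vector of ids (possibly empty), sorted.
#' @export
minimal_common_ancestors <- function(o, concepts) {
  if (!length(concepts)) stop("minimal_common_ancestors requires a non-empty set")
  for (id in concepts) assert_concept(o, id)
  am <- ancestor_map(o)
  common <- c(concepts[[1L]], am[[concepts[[1L]]]])
  for (id in concepts[-1L]) common <- intersect(common, c(id, am[[id]]))
  if (!length(common)) return(character(0L))
  dm <- descendant_map(o)
  keep <- vapply(common, function(x) !any(dm[[x]] %in% common), logical(1L))
  sort(common[keep], method = "radix")
}

#' Non-lattice pair test
#'
#' A pair is non-lattice when it shares more than one maximal common
#' descendant or more than one minimal common ancestor.
#'
#' @param o An [ontology].
#' @param a,b Distinct concept ids.
#' @return Logical.
#' @examples
#' o <- make_nonlattice_fixture()
#' is_nonlattice_pair(o, concept_by_fsn(o, "Neoplasm of vulva (disorder)"),
#'                       concept_by_fsn(o, "Disorder of Bartholin's gland (disorder)"))
#' @export
is_nonlattice_pair <- function(o, a, b) {
  length(maximal_common_descendants(o, a, b)) > 1L ||
    length(minimal_common_ancestors(o, c(a, b))) > 1L
}

#' Build the non-lattice subgraph seeded by a pair
#'
#' From the pair's maximal common descendants (MCDs) the minimal common
#' ancestors (MCAs) are computed reversely, and every concept on an is-a
#' path from an MCA down to an MCD is aggregated, together with the is-a
#' edges among the aggregated concepts. For pairs that are non-lattice only
#' through their shared ancestors (no or one common descendant), the dual
#' construction is used: the MCAs of the pair itself above the pair.
#'
#' @param o An [ontology].
#' @param a,b The seed pair; must satisfy [is_nonlattice_pair()].
#' @return An object of class `nonlattice_subgraph` with fields `seed_pair`,
#'   `mcds`, `mcas`, `concepts`, `edges` and `size`.
#' @export
build_subgraph <- function(o, a, b) {
  if (!is_nonlattice_pair(o, a, b))
    stop("(", a, ", ", b, ") is not a non-lattice pair")
  mcds <- maximal_common_descendants(o, a, b)
  if (length(mcds) > 1L) {
    mcas <- minimal_common_ancestors(o, mcds)
  } else {
    mcas <- minimal_common_ancestors(o, c(a, b))
    mcds <- sort(c(a, b), method = "radix")
  }
  am <- ancestor_map(o); dm <- descendant_map(o)
  below_mca <- unique(unlist(dm[mcas]))
  above_mcd <- unique(unlist(am[mcds]))
  between <- intersect(below_mca, above_mcd)
  nodes <- sort(unique(c(mcas, mcds, between)), method = "radix")
  e <- o$isa_edges[o$isa_edges$child %in% nodes & o$isa_edges$parent %in% nodes, ,
                   drop = FALSE]
  e <- e[order(e$child, e$parent, method = "radix"), ]
  rownames(e) <- NULL
  structure(list(
    seed_pair = sort(c(a, b), method = "radix"), mcds = mcds, mcas = mcas,
    concepts = nodes, edges = e, size = length(nodes)
  ), class = "nonlattice_subgraph")
}

#' @export
print.nonlattice_subgraph <- function(x, ...) {
  cat(sprintf("<non-lattice subgraph of size %d>\n", x$size))
  cat("  seed pair:", paste(x$seed_pair, collapse = ", "), "\n")
  cat("  MCAs:", paste(x$mcas, collapse = ", "), "\n")
  cat("  MCDs:", paste(x$mcds, collapse = ", "), "\n")
  invisible(x)
}

subgraph_identity <- function(sg) paste(sg$concepts, collapse = .KSEP)

#' Enumerate non-lattice subgraphs
#'
#' Tests every unordered concept pair, builds subgraphs for the non-lattice
#' ones, deduplicates them by concept set, and keeps those within the size
#' threshold. Pairs sharing at least one common descendant are found from
#' inverted descendant lists; remaining pairs are screened for the
#' multiple-minimal-common-ancestor criterion.
#'
#' @param o An [ontology].
#' @param max_size Size threshold (concept count), at least 2.
#' @param inclusive Keep subgraphs with size `<= max_size` (default); set
#'   `FALSE` for a strict `<` threshold.
#' @return A list of `nonlattice_subgraph` objects, deterministically ordered
#'   by concept-set identity.
#' @export
enumerate_subgraphs <- function(o, max_size = 10L, inclusive = TRUE) {
  stopifnot(max_size >= 2L)
  ids <- sort(o$concepts$id, method = "radix")
  n <- length(ids)
  if (n < 2L) return(list())
  seen <- character(0L)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- ids[[i]]; b <- ids[[j]]
      if (!is_nonlattice_pair(o, a, b)) next
      sg <- build_subgraph(o, a, b)
      ok <- if (inclusive) sg$size <= max_size else sg$size < max_size
      if (!ok) next
      key <- subgraph_identity(sg)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- sg
    }
  }
  out[order(vapply(out, subgraph_identity, character(1L)), method = "radix")]
}

#' Export a non-lattice subgraph
#'
#' `subgraph_to_json` writes the concepts, edges, MCDs and MCAs as JSON;
#' `subgraph_to_dot` renders a Graphviz DOT digraph (child -> parent) for
#' visual review.
#'
#' @param sg A `nonlattice_subgraph`.
#' @param o Optional [ontology] for FSN labels in DOT output.
#' @return A JSON string / a DOT string.
#' @export
subgraph_to_json <- function(sg) {
  jsonlite::toJSON(list(
    seed_pair = sg$seed_pair, mcds = sg$mcds, mcas = sg$mcas,
    concepts = sg$concepts, size = sg$size,
    edges = unname(apply(sg$edges, 1L, function(r) list(child = r[["child"]],
                                                        parent = r[["parent"]])))
  ), auto_unbox = FALSE, pretty = TRUE)
}

#' @rdname subgraph_to_json
#' @export
subgraph_to_dot <- function(sg, o = NULL) {
  lab <- function(id) {
    if (!is.null(o) && has_concept(o, id)) concept_fsn(o, id) else id
  }
  lines <- c("digraph nonlattice {", "  rankdir=BT;")
  for (cid in sg$concepts)
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"];", cid, lab(cid)))
  for (k in seq_len(nrow(sg$edges)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", sg$edges$child[[k]],
                              sg$edges$parent[[k]]))
  paste(c(lines, "}"), collapse = "\n")
}
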