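# Candidate concept pairs: pairs inside a non-lattice subgraph that are
# hierarchically unrelated, both fully defined, and both deep enough in the
# hierarchy not to be overly general. The same pair may qualify in several
# subgraphs; candidates are deduplicated with provenance.

#' Candidate-pair test within one subgraph
#'
#' `a` and `b` form a candidate pair in `sg` when: both belong to the
#' subgraph; neither is a direct or indirect is-a ancestor of the other;
#' both are fully defined; and both have level at least `min_level`
#' (longest-path hops from the root; default 10, excluding very general
#' concepts).
#'
#' @param o An [ontology].
#' @param sg A `nonlattice_subgraph` from [build_subgraph()].
#' @param a,b Distinct concept ids.
#' @param min_level Minimum concept level (default 10).
#' @return Logical.
#' @export
is_candidate <- function(o, sg, a, b, min_level = 10L) {
  assert_concept(o, a); assert_concept(o, b)
  if (a == b) stop("a candidate pair needs two distinct concepts")
  if (!(a %in% sg$concepts) || !(b %in% sg$concepts)) return(FALSE)
  if (is_subtype(o, a, b) || is_subtype(o, b, a)) return(FALSE)
  if (!is_fully_defined(o, a) || !is_fully_defined(o, b)) return(FALSE)
  lv <- concept_levels(o)
  if (is.na(lv[[a]]) || is.na(lv[[b]])) return(FALSE)
  lv[[a]] >= min_level && lv[[b]] >= min_level
}

#' Generate deduplicated candidate pairs from subgraphs
#'
#' All qualifying unordered pairs across every subgraph; pairs occurring in
#' several subgraphs are merged into one candidate carrying the identities
#' of all contributing subgraphs. Output ordering is canonical (sorted ids),
#' hence independent of subgraph iteration order.
#'
#' @param o An [ontology].
#' @param subgraphs List of `nonlattice_subgraph` objects (e.g. from
#'   [enumerate_subgraphs()]).
#' @param min_level Minimum concept level (default 10).
#' @return A list of `candidate_pair` objects (fields `a`, `b`,
#'   `source_subgraphs`).
#' @export
generate_candidates <- function(o, subgraphs, min_level = 10L) {
  acc <- list()  # pair key -> list(a, b, sources)
  for (sg in subgraphs) {
    sgid <- subgraph_identity(sg)
    nodes <- sort(sg$concepts, method = "radix")
    n <- length(nodes)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      a <- nodes[[i]]; b <- nodes[[j]]
      if (!is_candidate(o, sg, a, b, min_level)) next
      k <- paste(a, b, sep = .KSEP)
      if (is.null(acc[[k]])) {
        acc[[k]] <- list(a = a, b = b, sources = sgid)
      } else if (!sgid %in% acc[[k]]$sources) {
        acc[[k]]$sources <- sort(c(acc[[k]]$sources, sgid), method = "radix")
      }
    }
  }
  keys <- if (length(acc)) sort(names(acc), method = "radix") else character(0L)
  lapply(keys, function(k) {
    structure(list(a = acc[[k]]$a, b = acc[[k]]$b,
                   source_subgraphs = acc[[k]]$sources),
              class = "candidate_pair")
  })
}

#' @export
print.candidate_pair <- function(x, ...) {
  cat(sprintf("<candidate pair (%s, %s); %d source subgraph(s)>\n", x$a, x$b,
              length(x$source_subgraphs)))
  invisible(x)
}

#' Export candidate pairs as a TSV table
#'
#' @param o An [ontology].
#' @param candidates List of `candidate_pair` objects.
#' @param path Output file; when `NULL` the data frame is returned only.
#' @return A `data.frame` (a_id, a_fsn, b_id, b_fsn, n_subgraphs), invisibly
#'   when written.
#' @export
candidates_to_tsv <- function(o, candidates, path = NULL) {
  df <- data.frame(
    a_id = vapply(candidates, function(x) x$a, character(1L)),
    a_fsn = vapply(candidates, function(x) concept_fsn(o, x$a), character(1L)),
    b_id = vapply(candidates, function(x) x$b, character(1L)),
    b_fsn = vapply(candidates, function(x) concept_fsn(o, x$b), character(1L)),
    n_subgraphs = vapply(candidates, function(x) length(x$source_subgraphs),
                         integer(1L)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    return(invisible(df))
  }
  df
}
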