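# End-to-end proposal pipeline: intersect each candidate pair's derived
# definitions, reduce, drop empty intersections, suppress definitions that
# already define an existing concept, and merge proposals whose definitions
# coincide.

#' Order-insensitive definition equality
#'
#' Two logical definitions are equal when they contain the same groups and
#' each group the same pairs, regardless of order. When `reduce = TRUE`
#' (default) both sides are reduced first, so distinct raw forms of the same
#' definition compare equal.
#'
#' @param o An [ontology].
#' @param d1,d2 [logical_definition()] objects.
#' @param reduce Reduce both definitions before comparing.
#' @return Logical.
#' @export
definition_equals <- function(o, d1, d2, reduce = TRUE) {
  stopifnot(inherits(d1, "logical_definition"), inherits(d2, "logical_definition"))
  if (!length(d1$groups) || !length(d2$groups))
    return(length(d1$groups) == length(d2$groups))
  if (reduce) {
    d1 <- reduce_definition(o, d1)
    d2 <- reduce_definition(o, d2)
  }
  definition_key(d1) == definition_key(d2)
}

# reduced definitions of every concept with a non-empty definition,
# keyed for suppression lookups; memoized per ontology
existing_definition_keys <- function(o) {
  if (!is.null(o$cache$existing_defs)) return(o$cache$existing_defs)
  ids <- sort(o$concepts$id, method = "radix")
  keys <- vapply(ids, function(cid) {
    d <- own_groups(o, cid)
    if (!length(d$groups)) return(NA_character_)
    definition_key(reduce_definition(o, d))
  }, character(1L))
  out <- keys[!is.na(keys)]
  o$cache$existing_defs <- out
  out
}

#' Propose potential missing concepts from candidate pairs
#'
#' For each candidate pair the derived logical definitions are intersected
#' ([intersect_derived()], already reduced). Empty intersections are dropped
#' (counted in the `n_empty` attribute); definitions equal to the reduced
#' definition of any existing concept — fully defined or primitive — are
#' suppressed (`n_suppressed`); candidates yielding the same definition are
#' merged into one proposal with concatenated provenance. The result is
#' ordered by definition key and therefore independent of candidate order.
#'
#' @param o An [ontology].
#' @param candidates List of `candidate_pair` objects from
#'   [generate_candidates()].
#' @param chain_depth,ceiling_level Passed to [intersect_derived()].
#' @return A list of `potential_missing_concept` objects (fields
#'   `definition`, `provenance`, `predicted_fsn`, `validation`), with
#'   attributes `n_empty` and `n_suppressed`.
#' @export
propose <- function(o, candidates, chain_depth = 3L, ceiling_level = 2L) {
  existing <- existing_definition_keys(o)
  acc <- list()
  n_empty <- 0L
  n_suppressed <- 0L
  for (cp in candidates) {
    d <- intersect_derived(o, cp$a, cp$b, chain_depth = chain_depth,
                           ceiling_level = ceiling_level)
    if (!length(d$groups)) { n_empty <- n_empty + 1L; next }
    k <- definition_key(d)
    if (k %in% existing) { n_suppressed <- n_suppressed + 1L; next }
    if (is.null(acc[[k]])) {
      acc[[k]] <- list(definition = d, provenance = list(cp))
    } else {
      acc[[k]]$provenance <- c(acc[[k]]$provenance, list(cp))
    }
  }
  keys <- if (length(acc)) sort(names(acc), method = "radix") else character(0L)
  out <- lapply(keys, function(k) {
    structure(list(definition = acc[[k]]$definition,
                   provenance = acc[[k]]$provenance,
                   predicted_fsn = NULL, validation = NULL),
              class = "potential_missing_concept")
  })
  attr(out, "n_empty") <- n_empty
  attr(out, "n_suppressed") <- n_suppressed
  out
}

#' @export
print.potential_missing_concept <- function(x, ...) {
  cat("<potential missing concept>\n")
  if (!is.null(x$predicted_fsn)) cat("  predicted FSN:", x$predicted_fsn, "\n")
  cat("  definition:\n")
  for (line in format_definition(x$definition)) cat("   ", line, "\n")
  cat(sprintf("  provenance: %d candidate pair(s)\n", length(x$provenance)))
  invisible(x)
}

#' Export proposals as JSON lines
#'
#' One JSON object per proposal: the definition as a list of groups (each a
#' list of `{attribute, value}` records), the provenance pairs, and the
#' predicted FSN when present.
#'
#' @param proposals List of `potential_missing_concept` objects.
#' @param path Output file; when `NULL` the JSON lines are returned as a
#'   character vector.
#' @return Character vector of JSON lines (invisibly when written).
#' @export
proposals_to_jsonl <- function(proposals, path = NULL) {
  lines <- vapply(proposals, function(p) {
    def <- lapply(p$definition$groups, function(g)
      lapply(g$pairs, function(pr) list(attribute = pr$attribute, value = pr$value)))
    prov <- lapply(p$provenance, function(cp) list(a = cp$a, b = cp$b))
    obj <- list(definition = def, provenance = prov)
    if (!is.null(p$predicted_fsn)) obj$predicted_fsn <- p$predicted_fsn
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
  }, character(1L))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Render proposals as a human-readable report
#'
#' Groups are rendered one per row in the style of a grouped relationship
#' listing, with ids resolved to names.
#'
#' @param o An [ontology].
#' @param proposals List of `potential_missing_concept` objects.
#' @return A character vector of report lines.
#' @export
proposals_report <- function(o, proposals) {
  out <- character(0L)
  for (i in seq_along(proposals)) {
    p <- proposals[[i]]
    out <- c(out, sprintf("Proposal %d%s", i,
                          if (is.null(p$predicted_fsn)) "" else
                            paste0(": ", p$predicted_fsn)))
    gl <- format_definition(p$definition, o)
    out <- c(out, sprintf("  Group %d  %s", seq_along(gl) - 1L, gl))
    prov <- vapply(p$provenance, function(cp)
      sprintf("(%s, %s)", concept_fsn(o, cp$a), concept_fsn(o, cp$b)), character(1L))
    out <- c(out, paste0("  from candidate pair(s): ", paste(prov, collapse = "; ")), "")
  }
  out
}
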