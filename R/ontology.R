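# In-memory model of an EL-style terminology: a concept table, an acyclic
# is-a graph, grouped defining attribute relationships, property-chain
# axioms and a synonym table. Attribute concepts (relation types) live in
# the same concept set and the same is-a DAG as ordinary concepts, so
# attribute subsumption and value subsumption are one query.

ISA_DEFAULT <- "is_a"

#' Construct an ontology
#'
#' Assembles and validates the in-memory terminology used by every other
#' function in the package. Validation enforces: unique non-empty ids, an
#' acyclic is-a graph, at least one is-a parent for every non-root concept,
#' and resolvable ids in attribute groups and property chains. The is-a
#' relation itself is modeled as an ordinary attribute concept (added as a
#' child of the root when absent), so subsumption between attributes uses
#' the same hierarchy as subsumption between values.
#'
#' @param concepts `data.frame` with columns `id`, `fsn`, `preferred_term`,
#'   `fully_defined` (logical), `active` (logical). Inactive rows are dropped.
#' @param isa_edges `data.frame` with columns `child`, `parent`.
#' @param groups Either `NULL`, or a `data.frame` with columns `concept`,
#'   `group_index`, `attribute`, `value` describing the defining non-is-a
#'   attribute groups, or a named list mapping concept id to a list of
#'   [att_group()] objects.
#' @param chains `data.frame` with columns `first`, `second`, `implied`
#'   declaring property-chain axioms first o second -> implied, or `NULL`.
#' @param synonyms `data.frame` with columns `concept`, `term`, or `NULL`.
#' @param root Root concept id; defaults to the unique parentless concept.
#' @param isa_id Id used for the is-a attribute (default `"is_a"`).
#' @return An object of class `ontology`.
#' @export
ontology <- function(concepts, isa_edges, groups = NULL, chains = NULL,
                     synonyms = NULL, root = NULL, isa_id = ISA_DEFAULT) {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  need <- c("id", "fsn", "preferred_term", "fully_defined", "active")
  missing_cols <- setdiff(need, names(concepts))
  if (length(missing_cols))
    stop("concept table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(concepts) == 0L) stop("concept table is empty")
  concepts$id <- as.character(concepts$id)
  concepts$fsn <- as.character(concepts$fsn)
  concepts$preferred_term <- as.character(concepts$preferred_term)
  concepts$fully_defined <- as.logical(concepts$fully_defined)
  concepts$active <- as.logical(concepts$active)
  concepts <- concepts[concepts$active, , drop = FALSE]
  if (nrow(concepts) == 0L) stop("no active concepts")
  if (anyDuplicated(concepts$id))
    stop("duplicate concept id(s): ",
         paste(unique(concepts$id[duplicated(concepts$id)]), collapse = ", "))
  if (any(!nzchar(concepts$fsn))) stop("empty fsn for concept(s): ",
    paste(concepts$id[!nzchar(concepts$fsn)], collapse = ", "))
  blank <- !nzchar(concepts$preferred_term) | is.na(concepts$preferred_term)
  concepts$preferred_term[blank] <- strip_semantic_tag(concepts$fsn[blank])

  isa_edges <- as.data.frame(isa_edges, stringsAsFactors = FALSE)
  if (nrow(isa_edges)) {
    isa_edges$child <- as.character(isa_edges$child)
    isa_edges$parent <- as.character(isa_edges$parent)
    isa_edges <- unique(isa_edges[, c("child", "parent")])
  } else {
    isa_edges <- data.frame(child = character(), parent = character(),
                            stringsAsFactors = FALSE)
  }

  # identify root before injecting the is-a attribute concept
  ids <- concepts$id
  bad <- setdiff(unique(c(isa_edges$child, isa_edges$parent)), ids)
  if (length(bad))
    stop("is-a edges reference unknown concept(s): ", paste(bad, collapse = ", "))
  parentless <- setdiff(ids, isa_edges$child)
  if (is.null(root)) {
    if (length(parentless) != 1L)
      stop("root is ambiguous; parentless concepts: ",
           paste(parentless, collapse = ", "))
    root <- parentless
  } else if (!root %in% ids) stop("declared root ", root, " not in concept table")
  orphans <- setdiff(parentless, root)
  if (length(orphans))
    stop("non-root concept(s) without an is-a parent: ",
         paste(orphans, collapse = ", "))

  if (!isa_id %in% ids) {
    concepts <- rbind(concepts, data.frame(
      id = isa_id, fsn = "Is a (attribute)", preferred_term = "Is a",
      fully_defined = FALSE, active = TRUE, stringsAsFactors = FALSE))
    isa_edges <- rbind(isa_edges, data.frame(child = isa_id, parent = root,
                                             stringsAsFactors = FALSE))
    ids <- concepts$id
  }

  check_acyclic(isa_edges, ids)

  parents <- split(isa_edges$parent, factor(isa_edges$child, levels = ids))
  children <- split(isa_edges$child, factor(isa_edges$parent, levels = ids))
  parents <- lapply(parents, as.character)
  children <- lapply(children, as.character)

  attribute_rels <- normalize_groups_input(groups, ids)

  if (is.null(chains))
    chains <- data.frame(first = character(), second = character(),
                         implied = character(), stringsAsFactors = FALSE)
  chains <- as.data.frame(chains, stringsAsFactors = FALSE)
  if (nrow(chains)) {
    for (cc in c("first", "second", "implied")) chains[[cc]] <- as.character(chains[[cc]])
    badc <- setdiff(unique(unlist(chains[, c("first", "second", "implied")])), ids)
    if (length(badc))
      stop("property chains reference unknown attribute(s): ",
           paste(badc, collapse = ", "))
  }

  if (is.null(synonyms))
    synonyms <- data.frame(concept = character(), term = character(),
                           stringsAsFactors = FALSE)
  synonyms <- as.data.frame(synonyms, stringsAsFactors = FALSE)
  if (nrow(synonyms)) {
    synonyms$concept <- as.character(synonyms$concept)
    synonyms$term <- as.character(synonyms$term)
    bads <- setdiff(unique(synonyms$concept), ids)
    if (length(bads))
      stop("synonym rows reference unknown concept(s): ", paste(bads, collapse = ", "))
  }

  structure(list(
    concepts = concepts, isa_edges = isa_edges, parents = parents,
    children = children, attribute_rels = attribute_rels, chains = chains,
    synonyms = synonyms, root = root, isa = isa_id, cache = new.env(parent = emptyenv())
  ), class = "ontology")
}

# groups input: data.frame (concept, group_index, attribute, value) or named
# list of lists of att_group
normalize_groups_input <- function(groups, ids) {
  if (is.null(groups)) return(list())
  if (is.data.frame(groups)) {
    if (nrow(groups) == 0L) return(list())
    need <- c("concept", "group_index", "attribute", "value")
    miss <- setdiff(need, names(groups))
    if (length(miss)) stop("group table lacks column(s): ", paste(miss, collapse = ", "))
    groups$concept <- as.character(groups$concept)
    groups$attribute <- as.character(groups$attribute)
    groups$value <- as.character(groups$value)
    bad <- setdiff(unique(c(groups$concept, groups$attribute, groups$value)), ids)
    if (length(bad))
      stop("attribute groups reference unknown concept(s): ",
           paste(bad, collapse = ", "))
    out <- lapply(split(groups, groups$concept), function(df) {
      lapply(split(df, df$group_index), function(gd) {
        att_group(Map(avp, gd$attribute, gd$value))
      })
    })
    return(lapply(out, unname))
  }
  stopifnot(is.list(groups))
  bad <- setdiff(names(groups), ids)
  if (length(bad))
    stop("attribute groups reference unknown concept(s): ", paste(bad, collapse = ", "))
  lapply(groups, function(gl) {
    if (inherits(gl, "att_group")) gl <- list(gl)
    stopifnot(all(vapply(gl, inherits, logical(1L), "att_group")))
    unname(gl)
  })
}

check_acyclic <- function(isa_edges, ids) {
  # Kahn's algorithm on child -> parent edges; leftovers form cycles.
  indeg <- table(factor(isa_edges$child, levels = ids))
  by_parent <- split(isa_edges$child, factor(isa_edges$parent, levels = ids))
  queue <- ids[indeg == 0L]
  indeg <- as.integer(indeg); names(indeg) <- ids
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in by_parent[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    inside <- names(indeg)[indeg > 0L]
    cyc <- find_cycle(isa_edges[isa_edges$child %in% inside &
                                  isa_edges$parent %in% inside, ], inside)
    stop("is-a graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  invisible(TRUE)
}

find_cycle <- function(edges, nodes) {
  adj <- split(edges$parent, factor(edges$child, levels = nodes))
  v <- nodes[[1L]]; path <- character()
  repeat {
    if (v %in% path) {
      i <- match(v, path)
      return(c(path[i:length(path)], v))
    }
    path <- c(path, v)
    nxt <- adj[[v]]
    if (!length(nxt)) return(path)  # should not happen when called on a cycle set
    v <- nxt[[1L]]
  }
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d concepts, %d is-a edges, %d concepts with attribute groups, %d property chains>\n",
              nrow(x$concepts), nrow(x$isa_edges), length(x$attribute_rels),
              nrow(x$chains)))
  cat(sprintf("  root: %s (%s)\n", x$root, concept_fsn(x, x$root)))
  invisible(x)
}

has_concept <- function(o, id) id %in% o$concepts$id

assert_concept <- function(o, id) {
  if (length(id) != 1L || !has_concept(o, id))
    stop("unknown concept id: ", paste(id, collapse = ", "))
  invisible(id)
}

#' Look up concept fields
#'
#' @param o An [ontology].
#' @param id Concept id(s).
#' @return `concept_fsn` the FSN string(s); `is_fully_defined` logical(s).
#' @export
concept_fsn <- function(o, id) {
  o$concepts$fsn[match(id, o$concepts$id)]
}

#' @rdname concept_fsn
#' @export
is_fully_defined <- function(o, id) {
  o$concepts$fully_defined[match(id, o$concepts$id)]
}

#' Find a concept id by its FSN
#'
#' Convenience lookup used heavily with the bundled fixtures.
#'
#' @param o An [ontology].
#' @param fsn Full FSN string (including the semantic tag, if any).
#' @return The concept id, or an error when absent.
#' @export
concept_by_fsn <- function(o, fsn) {
  i <- match(fsn, o$concepts$fsn)
  if (is.na(i)) stop("no concept with fsn: ", fsn)
  o$concepts$id[[i]]
}

# Full transitive closures, computed once per ontology and memoized in the
# ontology's cache environment (reference semantics survive list copies).
ancestor_map <- function(o) {
  if (!is.null(o$cache$anc)) return(o$cache$anc)
  ids <- o$concepts$id
  order <- topo_order(o)  # parents before children
  anc <- new.env(parent = emptyenv())
  for (v in order) {
    ps <- o$parents[[v]]
    if (is.null(ps) || !length(ps)) { assign(v, character(), envir = anc); next }
    acc <- ps
    for (p in ps) acc <- c(acc, get(p, envir = anc))
    assign(v, unique(acc), envir = anc)
  }
  out <- mget(ids, envir = anc)
  o$cache$anc <- out
  out
}

descendant_map <- function(o) {
  if (!is.null(o$cache$desc)) return(o$cache$desc)
  ids <- o$concepts$id
  order <- rev(topo_order(o))  # children before parents
  des <- new.env(parent = emptyenv())
  for (v in order) {
    cs <- o$children[[v]]
    if (is.null(cs) || !length(cs)) { assign(v, character(), envir = des); next }
    acc <- cs
    for (ch in cs) acc <- c(acc, get(ch, envir = des))
    assign(v, unique(acc), envir = des)
  }
  out <- mget(ids, envir = des)
  o$cache$desc <- out
  out
}

topo_order <- function(o) {
  if (!is.null(o$cache$topo)) return(o$cache$topo)
  ids <- o$concepts$id
  indeg <- vapply(ids, function(v) length(o$parents[[v]]), integer(1L))
  names(indeg) <- ids
  queue <- ids[indeg == 0L]
  out <- character(0L)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in o$children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  o$cache$topo <- out
  out
}

#' Hierarchy queries
#'
#' `ancestors` and `descendants` return the transitive, non-reflexive is-a
#' closure of a concept. `is_subtype(o, a, b)` tests whether `b` is a strict
#' ancestor of `a` (irreflexive: a concept is not a subtype of itself; call
#' sites that need "same as or more general" test equality explicitly).
#'
#' @param o An [ontology].
#' @param id,a,b Concept ids.
#' @return Character vector of ids (`ancestors`/`descendants`) or a logical.
#' @examples
#' o <- make_nonlattice_fixture()
#' benign <- concept_by_fsn(o, "Benign neoplasm of Bartholin's gland (disorder)")
#' concept_fsn(o, ancestors(o, benign))
#' @export
ancestors <- function(o, id) {
  assert_concept(o, id)
  ancestor_map(o)[[id]]
}

#' @rdname ancestors
#' @export
descendants <- function(o, id) {
  assert_concept(o, id)
  descendant_map(o)[[id]]
}

#' @rdname ancestors
#' @export
is_subtype <- function(o, a, b) {
  assert_concept(o, a); assert_concept(o, b)
  b %in% ancestor_map(o)[[a]]
}

#' Concept level (longest path from the root)
#'
#' The level of a concept is the number of hops in the longest is-a path
#' from the root down to it; the root has level 0. Candidate-pair filtering
#' uses levels to exclude overly general concepts.
#'
#' @param o An [ontology].
#' @param id Concept id (must be reachable from the root).
#' @return `concept_level`: a non-negative integer. `concept_levels`: a named
#'   integer vector over all concepts.
#' @export
concept_level <- function(o, id) {
  assert_concept(o, id)
  lv <- concept_levels(o)
  if (is.na(lv[[id]])) stop("concept not reachable from root: ", id)
  lv[[id]]
}

#' @rdname concept_level
#' @export
concept_levels <- function(o) {
  if (!is.null(o$cache$levels)) return(o$cache$levels)
  ids <- o$concepts$id
  lv <- rep(NA_integer_, length(ids)); names(lv) <- ids
  lv[[o$root]] <- 0L
  for (v in topo_order(o)) {
    if (v == o$root) next
    ps <- o$parents[[v]]
    pls <- lv[ps]
    if (all(is.na(pls))) next  # unreachable from root
    lv[[v]] <- max(pls, na.rm = TRUE) + 1L
  }
  o$cache$levels <- lv
  lv
}

#' A concept's own logical definition under the grouping convention
#'
#' Each is-a parent is placed in its own singleton attribute group (the is-a
#' relation acting as an ordinary attribute), followed by the concept's
#' defining non-is-a attribute groups. The group count therefore always
#' equals (number of is-a parents) + (number of defining attribute groups).
#'
#' @param o An [ontology].
#' @param id Concept id.
#' @return A [logical_definition()]; for the root with no attribute groups
#'   this is empty-flagged via an attribute `empty = TRUE` on a definition
#'   with zero groups.
#' @examples
#' o <- make_thyroid_fixture()
#' id <- concept_by_fsn(o, "Malignant epithelial neoplasm of thyroid (disorder)")
#' length(own_groups(o, id))  # 3
#' @export
own_groups <- function(o, id) {
  assert_concept(o, id)
  isa_groups <- lapply(o$parents[[id]], function(p) att_group(avp(o$isa, p)))
  attr_groups <- o$attribute_rels[[id]]
  if (is.null(attr_groups)) attr_groups <- list()
  groups <- c(isa_groups, attr_groups)
  if (!length(groups)) {
    d <- structure(list(groups = list()), class = "logical_definition")
    attr(d, "empty") <- TRUE
    return(d)
  }
  logical_definition(groups)
}

strip_semantic_tag <- function(x) {
  sub("\\s*\\([^()]*\\)\\s*$", "", x)
}

semantic_tag <- function(x) {
  m <- regexpr("\\(([^()]*)\\)\\s*$", x)
  out <- rep(NA_character_, length(x))
  hit <- !is.na(x) & m > 0L
  out[hit] <- gsub("^\\(|\\)\\s*$", "", regmatches(x, m))
  out
}
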