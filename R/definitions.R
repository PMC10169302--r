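# Logical-definition building blocks: attribute-value pairs, attribute
# groups (sets of pairs), and logical definitions (sets of groups).
# Equality is order-insensitive at every level; canonical string keys make
# that cheap. The key separator is the ASCII unit separator, which cannot
# occur in ids read from the tab/pipe-separated input dialects.

.KSEP <- "\x1f"
.GSEP <- "\x1e"

#' Attribute-value pair
#'
#' One element of an attribute group: a relation type (the attribute, which
#' may be the is-a relation itself) and a target concept (the value).
#'
#' @param attribute Concept id of the relation type.
#' @param value Concept id of the target.
#' @return An object of class `avp`.
#' @examples
#' avp("finding_site", "thyroid_structure")
#' @export
avp <- function(attribute, value) {
  stopifnot(is.character(attribute), length(attribute) == 1L, nzchar(attribute),
            is.character(value), length(value) == 1L, nzchar(value))
  structure(list(attribute = attribute, value = value), class = "avp")
}

#' @export
print.avp <- function(x, ...) {
  cat(sprintf("(%s, %s)\n", x$attribute, x$value))
  invisible(x)
}

pair_key <- function(p) paste(p$attribute, p$value, sep = .KSEP)

pair_from_key <- function(k) {
  parts <- strsplit(k, .KSEP, fixed = TRUE)[[1L]]
  avp(parts[[1L]], parts[[2L]])
}

#' Attribute group
#'
#' A non-empty set of attribute-value pairs that jointly qualify a concept's
#' definition. Duplicate pairs are unified and order is canonicalized, so two
#' groups with the same pairs compare equal regardless of construction order.
#'
#' @param pairs A list of [avp()] objects (or a single `avp`).
#' @return An object of class `att_group`.
#' @export
att_group <- function(pairs) {
  if (inherits(pairs, "avp")) pairs <- list(pairs)
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  if (!all(vapply(pairs, inherits, logical(1L), "avp")))
    stop("all elements of an attribute group must be avp objects")
  keys <- vapply(pairs, pair_key, character(1L))
  pairs <- pairs[!duplicated(keys)]
  pairs <- pairs[order(vapply(pairs, pair_key, character(1L)), method = "radix")]
  structure(list(pairs = pairs), class = "att_group")
}

group_key <- function(g) {
  paste(vapply(g$pairs, pair_key, character(1L)), collapse = .GSEP)
}

group_from_key <- function(k) {
  att_group(lapply(strsplit(k, .GSEP, fixed = TRUE)[[1L]], pair_from_key))
}

#' @export
print.att_group <- function(x, ...) {
  cat("{", paste(vapply(x$pairs, function(p)
    sprintf("(%s, %s)", p$attribute, p$value), character(1L)), collapse = ", "),
    "}\n")
  invisible(x)
}

#' @export
length.att_group <- function(x) length(x$pairs)

#' Logical definition
#'
#' A non-empty set of attribute groups. By the grouping convention used
#' throughout this package, each is-a parent contributes a singleton group
#' in addition to the concept's defining (non-is-a) attribute groups.
#'
#' @param groups A list of [att_group()] objects (or a single group).
#' @return An object of class `logical_definition`.
#' @export
logical_definition <- function(groups) {
  if (inherits(groups, "att_group")) groups <- list(groups)
  stopifnot(is.list(groups))
  if (!all(vapply(groups, inherits, logical(1L), "att_group")))
    stop("all elements of a logical definition must be att_group objects")
  keys <- vapply(groups, group_key, character(1L))
  groups <- groups[!duplicated(keys)]
  groups <- groups[order(vapply(groups, group_key, character(1L)), method = "radix")]
  structure(list(groups = groups), class = "logical_definition")
}

definition_key <- function(d) {
  paste(vapply(d$groups, group_key, character(1L)), collapse = "\x1d")
}

#' @export
length.logical_definition <- function(x) length(x$groups)

#' @export
print.logical_definition <- function(x, ...) {
  cat(sprintf("<logical definition: %d group(s)>\n", length(x$groups)))
  for (g in x$groups) print(g)
  invisible(x)
}

#' Render a logical definition as a group-per-row table
#'
#' Human-readable rendering in the style of a grouped relationship listing:
#' one row per attribute group, pairs shown with resolved names when an
#' ontology is supplied.
#'
#' @param o Optional [ontology] used to resolve ids to names.
#' @param d A [logical_definition()].
#' @return A character vector, one element per group.
#' @export
format_definition <- function(d, o = NULL) {
  vapply(d$groups, function(g) {
    paste0("{", paste(vapply(g$pairs, function(p) {
      a <- p$attribute; v <- p$value
      if (!is.null(o)) {
        if (a %in% o$concepts$id) a <- concept_fsn(o, a)
        if (v %in% o$concepts$id) v <- concept_fsn(o, v)
      }
      sprintf("(%s, \"%s\")", a, v)
    }, character(1L)), collapse = ", "), "}")
  }, character(1L))
}
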