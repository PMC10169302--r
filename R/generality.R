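# The "more general than" relation on attribute-value pairs and attribute
# groups, and definition reduction. A pair (r2, v2) is strictly more general
# than (r1, v1) when one of four conditions holds:
#   (i)   r1 = r2 and v1 is-a v2;
#   (ii)  r1 is-a r2 and v1 = v2;
#   (iii) r1 is-a r2 and v1 is-a v2;
#   (iv)  v1's own logical definition contains a pair (r_b, v2) and a
#         property chain r_a o r_b [= r2 exists with r1 = r_a or r1 is-a r_a.
# The is-a relation is itself an attribute id, so condition (i) covers
# subsumption between is-a parents uniformly.

#' Strict pair generality
#'
#' Tests whether `general` is strictly more general than `specific` under the
#' four conditions above. Irreflexive: a pair is never more general than
#' itself; use [pair_ge()] for "same as or more general".
#'
#' @param o An [ontology].
#' @param general,specific [avp()] objects whose ids resolve in `o`.
#' @return Logical.
#' @examples
#' o <- make_edetate_fixture()
#' pair_more_general(o,
#'   avp(o$isa, concept_by_fsn(o, "Chelating agent adverse reaction (disorder)")),
#'   avp(o$isa, concept_by_fsn(o, "Edetate adverse reaction (disorder)")))
#' @export
pair_more_general <- function(o, general, specific) {
  stopifnot(inherits(general, "avp"), inherits(specific, "avp"))
  for (id in c(general$attribute, general$value, specific$attribute, specific$value))
    assert_concept(o, id)
  r2 <- general$attribute; v2 <- general$value
  r1 <- specific$attribute; v1 <- specific$value
  if (r1 == r2 && v1 == v2) return(FALSE)
  # (i) same attribute, more general value
  if (r1 == r2 && is_subtype(o, v1, v2)) return(TRUE)
  # (ii) more general attribute, same value
  if (is_subtype(o, r1, r2) && v1 == v2) return(TRUE)
  # (iii) both more general
  if (is_subtype(o, r1, r2) && is_subtype(o, v1, v2)) return(TRUE)
  # (iv) property chain through the specific value's own definition
  chain_more_general(o, r2, v2, r1, v1)
}

chain_more_general <- function(o, r2, v2, r1, v1) {
  ch <- o$chains
  if (!nrow(ch)) return(FALSE)
  # chains whose implied property is r2 or a supertype route to r2
  ok_implied <- ch$implied == r2 |
    vapply(ch$implied, function(x) is_subtype(o, x, r2), logical(1L))
  ch <- ch[ok_implied, , drop = FALSE]
  if (!nrow(ch)) return(FALSE)
  ok_ra <- r1 == ch$first |
    vapply(ch$first, function(ra) is_subtype(o, r1, ra), logical(1L))
  ch <- ch[ok_ra, , drop = FALSE]
  if (!nrow(ch)) return(FALSE)
  def <- own_groups(o, v1)
  for (g in def$groups) {
    for (p in g$pairs) {
      if (p$value == v2 && p$attribute %in% ch$second) return(TRUE)
    }
  }
  FALSE
}

#' @rdname pair_more_general
#' @export
pair_ge <- function(o, general, specific) {
  (general$attribute == specific$attribute && general$value == specific$value) ||
    pair_more_general(o, general, specific)
}

#' Strict group generality
#'
#' `g2` is strictly more general than `g1` when the two groups differ and
#' every pair of `g2` is the same as or more general than some pair of `g1`.
#' Note the asymmetry: `g2` may have fewer pairs than `g1` (dropping a
#' qualifying pair makes a group more general).
#'
#' @param o An [ontology].
#' @param g2,g1 Non-empty [att_group()] objects.
#' @return Logical.
#' @export
group_more_general <- function(o, g2, g1) {
  stopifnot(inherits(g2, "att_group"), inherits(g1, "att_group"))
  if (!length(g2$pairs) || !length(g1$pairs))
    stop("attribute groups must be non-empty")
  if (group_key(g2) == group_key(g1)) return(FALSE)
  for (p2 in g2$pairs) {
    matched <- FALSE
    for (p1 in g1$pairs) {
      if (pair_ge(o, p2, p1)) { matched <- TRUE; break }
    }
    if (!matched) return(FALSE)
  }
  TRUE
}

#' Normalize an attribute group
#'
#' Drops every pair that is strictly more general than another pair of the
#' same group (such pairs are logically redundant: the group with them and
#' the group without them are mutually more general). The result is the
#' canonical representative used by [reduce_definition()] and by derived-
#' definition intersection.
#'
#' @param o An [ontology].
#' @param g An [att_group()].
#' @return An [att_group()] containing only the minimal (most specific) pairs.
#' @export
normalize_group <- function(o, g) {
  ps <- g$pairs
  if (length(ps) <= 1L) return(g)
  keep <- rep(TRUE, length(ps))
  for (i in seq_along(ps)) {
    for (j in seq_along(ps)) {
      if (i == j) next
      if (pair_more_general(o, ps[[i]], ps[[j]])) {
        # drop i unless j is also strictly more general than i (mutual strict
        # pair generality would need an is-a cycle, but guard anyway)
        if (!pair_more_general(o, ps[[j]], ps[[i]])) keep[[i]] <- FALSE
        break
      }
    }
  }
  if (all(keep)) g else att_group(ps[keep])
}

#' Reduce a logical definition
#'
#' Removes every attribute group that is strictly more general than another
#' group of the same definition, after normalizing each group with
#' [normalize_group()] and unifying duplicates. The relation is computed on
#' the full group set first, so the result is independent of processing
#' order; should normalization ever leave a mutually-more-general class, its
#' lexicographically smallest member is kept so the result is never empty.
#' Idempotent.
#'
#' @param o An [ontology].
#' @param d A non-empty [logical_definition()].
#' @return A reduced [logical_definition()].
#' @examples
#' # a group naming "Structure of eye proper" as finding site is removed in
#' # favour of the more specific group naming "Choroidal structure"
#' o <- make_eye_fixture()
#' d <- logical_definition(list(toxoplasma_group(o, "choroidal_structure"),
#'                              toxoplasma_group(o, "eye_proper")))
#' length(reduce_definition(o, d))  # 1
#' @export
reduce_definition <- function(o, d) {
  stopifnot(inherits(d, "logical_definition"))
  if (!length(d$groups)) stop("cannot reduce an empty logical definition")
  gs <- lapply(d$groups, normalize_group, o = o)
  keys <- vapply(gs, group_key, character(1L))
  gs <- gs[!duplicated(keys)]
  n <- length(gs)
  if (n == 1L) return(logical_definition(gs))
  mg <- matrix(FALSE, n, n)  # mg[i, j]: gs[[i]] strictly more general than gs[[j]]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) mg[i, j] <- group_more_general(o, gs[[i]], gs[[j]])
  }
  mutual <- mg & t(mg)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !mg[i, j]) next
      if (mutual[i, j]) next  # resolved below by representative choice
      drop[[i]] <- TRUE
      break
    }
  }
  # mutual classes: keep only the smallest key of each class
  if (any(mutual)) {
    keys <- vapply(gs, group_key, character(1L))
    for (i in seq_len(n)) {
      cls <- c(i, which(mutual[i, ]))
      if (length(cls) > 1L && keys[[i]] != min(keys[cls])) drop[[i]] <- TRUE
    }
  }
  if (all(drop)) drop <- !seq_len(n) %in% which.min(vapply(gs, group_key, character(1L)))
  logical_definition(gs[!drop])
}
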