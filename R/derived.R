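# Derived logical definitions. A concept's derived definition is its own
# attribute groups plus every group more general than one of them. Because a
# group with fewer (or generalized) pairs is more general, the derived
# groups of an own group G are exactly the non-empty subsets of U(G), the
# upward closure of G's pairs under the four generality conditions.
# derived_groups materializes that closure for small inputs (and serves as
# the oracle in tests); intersect_derived computes minimal common
# generalizations directly and scales to real candidate sets.

#' One-step pair generalization
#'
#' All pairs strictly more general than `p` reachable by a single rewrite:
#' the value replaced by any of its ancestors, the attribute by any of its
#' ancestors, both at once, or one property-chain rewrite (condition (iv):
#' when `p`'s value carries a pair `(r_b, v2)` in its own definition and a
#' chain `r_a o r_b` implies some property, the pair `(implied-or-ancestor,
#' v2)` is more general). Closure under repetition is the caller's job.
#'
#' @param o An [ontology].
#' @param p An [avp()].
#' @return A list of [avp()] objects (possibly empty).
#' @export
generalize_pair <- function(o, p) {
  stopifnot(inherits(p, "avp"))
  assert_concept(o, p$attribute); assert_concept(o, p$value)
  out <- c(gen_plain(o, p), gen_chain(o, p))
  keys <- vapply(out, pair_key, character(1L))
  out[!duplicated(keys) & keys != pair_key(p)]
}

# Upward closure of a pair under repeated generalization. Conditions
# (i)-(iii) are exhausted by one application (ancestors of ancestors are
# ancestors); only chain rewrites (iv) can cascade, and those are capped at
# chain_depth applications per element.
up_closure <- function(o, p, chain_depth = 3L) {
  seen <- new.env(parent = emptyenv())
  assign(pair_key(p), 0L, envir = seen)
  queue <- list(list(p = p, d = 0L))
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    plain <- gen_plain(o, cur$p)
    for (q in plain) {
      k <- pair_key(q)
      if (is.null(seen[[k]])) {
        assign(k, cur$d, envir = seen)
        queue[[length(queue) + 1L]] <- list(p = q, d = cur$d)
      }
    }
    if (cur$d < chain_depth) {
      chained <- gen_chain(o, cur$p)
      for (q in chained) {
        k <- pair_key(q)
        if (is.null(seen[[k]])) {
          assign(k, cur$d + 1L, envir = seen)
          queue[[length(queue) + 1L]] <- list(p = q, d = cur$d + 1L)
        }
      }
    }
  }
  lapply(sort(ls(seen), method = "radix"), pair_from_key)
}

gen_plain <- function(o, p) {
  anc <- ancestor_map(o)
  rs <- c(p$attribute, anc[[p$attribute]])
  vs <- c(p$value, anc[[p$value]])
  out <- vector("list", length(rs) * length(vs))
  i <- 0L
  for (r in rs) for (v in vs) {
    if (r == p$attribute && v == p$value) next
    i <- i + 1L; out[[i]] <- avp(r, v)
  }
  out[seq_len(i)]
}

gen_chain <- function(o, p) {
  ch <- o$chains
  if (!nrow(ch)) return(list())
  anc <- ancestor_map(o)
  def <- own_groups(o, p$value)
  val_pairs <- unlist(lapply(def$groups, function(g) g$pairs), recursive = FALSE)
  out <- list()
  for (k in seq_len(nrow(ch))) {
    ra <- ch$first[[k]]; rb <- ch$second[[k]]; imp <- ch$implied[[k]]
    if (!(p$attribute == ra || is_subtype(o, p$attribute, ra))) next
    for (vp in val_pairs) {
      if (vp$attribute != rb) next
      for (r2 in c(imp, anc[[imp]]))
        out[[length(out) + 1L]] <- avp(r2, vp$value)
    }
  }
  keys <- vapply(out, pair_key, character(1L))
  out[!duplicated(keys) & keys != pair_key(p)]
}

# keys of the upward closure of every pair of group g, as one character set
group_up_keys <- function(o, g, chain_depth) {
  keys <- unlist(lapply(g$pairs, function(p)
    vapply(up_closure(o, p, chain_depth), pair_key, character(1L))))
  sort(unique(keys), method = "radix")
}

#' Materialize a derived logical definition (bounded oracle)
#'
#' Enumerates, for each own group G of a concept, every non-empty subset of
#' the upward closure of G's pairs — i.e. every attribute group that is the
#' same as or more general than G. Exponential in the closure size by
#' design; intended for small fixtures and as the reference against which
#' [intersect_derived()] is checked.
#'
#' @param o An [ontology].
#' @param id A defined concept id.
#' @param bound Cap on chained (condition-(iv)) rewrites per pair.
#' @param max_closure Hard limit on the per-group closure size; above it the
#'   enumeration would be intractable and an error advises
#'   [intersect_derived()] instead.
#' @return An object of class `derived_definition` with fields `concept` and
#'   `groups` (list of [att_group()], own groups included).
#' @export
derived_groups <- function(o, id, bound = 3L, max_closure = 14L) {
  assert_concept(o, id)
  own <- own_groups(o, id)
  if (!length(own$groups)) stop("concept has an empty definition: ", id)
  all_keys <- character(0L)
  groups <- list()
  for (g in own$groups) {
    u <- group_up_keys(o, g, bound)
    if (length(u) > max_closure)
      stop("generalization closure of a group of ", id, " has ", length(u),
           " pairs; materializing 2^", length(u),
           " subsets is intractable - use intersect_derived() instead")
    m <- length(u)
    bits <- 2L^(seq_len(m) - 1L)
    for (mask in seq_len(2L^m - 1L)) {
      sel <- u[bitwAnd(mask, bits) > 0L]
      k <- paste(sel, collapse = .GSEP)
      if (!k %in% all_keys) {
        all_keys <- c(all_keys, k)
        groups[[length(groups) + 1L]] <- group_from_key(k)
      }
    }
  }
  structure(list(concept = id, groups = groups), class = "derived_definition")
}

#' @export
print.derived_definition <- function(x, ...) {
  cat(sprintf("<derived definition of %s: %d group(s)>\n", x$concept,
              length(x$groups)))
  invisible(x)
}

# TRUE when every value mentioned by the group sits within `ceiling` levels
# of the root - such groups carry no usable content (e.g. {(is-a, root)})
group_too_general <- function(o, g, ceiling) {
  lv <- concept_levels(o)
  vals <- vapply(g$pairs, function(p) p$value, character(1L))
  all(lv[vals] <= ceiling, na.rm = FALSE)
}

#' Intersect two derived logical definitions
#'
#' Computes the reduced set of minimal common generalizations of the derived
#' definitions of `a` and `b` — the logical definition the method proposes
#' for a potential missing concept. For every own-group pair (Ga, Gb) the
#' upward closures of their pairs are intersected and only the minimal
#' (most specific) pairs kept; groups whose every value lies within
#' `ceiling_level` levels of the root are discarded as vacuous; the
#' surviving groups are reduced with [reduce_definition()]. Equals
#' closure-intersection-then-reduce over [derived_groups()] on instances
#' small enough to materialize, and is symmetric in `a` and `b`.
#'
#' @param o An [ontology].
#' @param a,b Ids of defined concepts.
#' @param chain_depth Cap on chained condition-(iv) rewrites per pair.
#' @param ceiling_level Generality ceiling: groups whose values all have
#'   level at most this are dropped (default 2).
#' @return A [logical_definition()]; zero groups (flagged via the `empty`
#'   attribute) when the pair shares no usable structure.
#' @export
intersect_derived <- function(o, a, b, chain_depth = 3L, ceiling_level = 2L) {
  assert_concept(o, a); assert_concept(o, b)
  own_a <- own_groups(o, a); own_b <- own_groups(o, b)
  if (!length(own_a$groups) || !length(own_b$groups))
    stop("both concepts must have non-empty definitions")
  ua <- lapply(own_a$groups, group_up_keys, o = o, chain_depth = chain_depth)
  ub <- lapply(own_b$groups, group_up_keys, o = o, chain_depth = chain_depth)
  found <- character(0L)
  groups <- list()
  for (ka in ua) for (kb in ub) {
    common <- intersect(ka, kb)
    if (!length(common)) next
    g <- normalize_group(o, att_group(lapply(common, pair_from_key)))
    if (group_too_general(o, g, ceiling_level)) next
    k <- group_key(g)
    if (k %in% found) next
    found <- c(found, k)
    groups[[length(groups) + 1L]] <- g
  }
  if (!length(groups)) {
    d <- structure(list(groups = list()), class = "logical_definition")
    attr(d, "empty") <- TRUE
    return(d)
  }
  reduce_definition(o, logical_definition(groups))
}
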