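# Independent oracles and fixture builders shared across the test files.
# Reachability oracles go through igraph; generality oracles re-derive the
# four conditions from scratch on top of igraph reachability, so they share
# no code path with the package implementation.

isa_graph <- function(o) {
  igraph::graph_from_data_frame(o$isa_edges[, c("child", "parent")],
                                directed = TRUE, vertices = o$concepts$id)
}

# ancestors (mode = "out": child -> parent edges) or descendants ("in"),
# excluding the concept itself
oracle_reach <- function(o, id, mode = c("out", "in")) {
  mode <- match.arg(mode)
  g <- isa_graph(o)
  setdiff(names(igraph::subcomponent(g, id, mode = mode)), id)
}

oracle_reach_all <- function(o, mode = c("out", "in")) {
  mode <- match.arg(mode)
  g <- isa_graph(o)
  ids <- o$concepts$id
  out <- lapply(ids, function(v)
    setdiff(names(igraph::subcomponent(g, v, mode = mode)), v))
  names(out) <- ids
  out
}

# brute-force non-lattice verdict straight from the lattice definition,
# over reflexive bounds computed with igraph
oracle_nonlattice <- function(o, a, b, anc = NULL, des = NULL) {
  if (is.null(anc)) anc <- oracle_reach_all(o, "out")
  if (is.null(des)) des <- oracle_reach_all(o, "in")
  lower <- intersect(c(a, des[[a]]), c(b, des[[b]]))
  mcd <- lower[vapply(lower, function(x) !any(anc[[x]] %in% lower), logical(1L))]
  upper <- intersect(c(a, anc[[a]]), c(b, anc[[b]]))
  mca <- upper[vapply(upper, function(x) !any(des[[x]] %in% upper), logical(1L))]
  length(mcd) > 1L || length(mca) > 1L
}

# strict pair generality re-derived from the four conditions on igraph
# reachability (independent of pair_more_general)
oracle_pair_mg <- function(o, gen, spec, anc = NULL) {
  if (is.null(anc)) anc <- oracle_reach_all(o, "out")
  isa <- function(x, y) y %in% anc[[x]]
  r2 <- gen$attribute; v2 <- gen$value
  r1 <- spec$attribute; v1 <- spec$value
  if (r1 == r2 && v1 == v2) return(FALSE)
  if (r1 == r2 && isa(v1, v2)) return(TRUE)
  if (isa(r1, r2) && v1 == v2) return(TRUE)
  if (isa(r1, r2) && isa(v1, v2)) return(TRUE)
  ch <- o$chains
  if (nrow(ch)) {
    # v1's own definition: is-a parents as pairs plus its attribute groups
    v1_pairs <- lapply(o$parents[[v1]], function(p) list(attribute = o$isa, value = p))
    for (g in o$attribute_rels[[v1]]) v1_pairs <- c(v1_pairs, g$pairs)
    for (k in seq_len(nrow(ch))) {
      ok_imp <- ch$implied[[k]] == r2 || isa(ch$implied[[k]], r2)
      ok_ra <- r1 == ch$first[[k]] || isa(r1, ch$first[[k]])
      if (!ok_imp || !ok_ra) next
      for (p in v1_pairs)
        if (p$attribute == ch$second[[k]] && p$value == v2) return(TRUE)
    }
  }
  FALSE
}

oracle_pair_ge <- function(o, gen, spec, anc = NULL) {
  (gen$attribute == spec$attribute && gen$value == spec$value) ||
    oracle_pair_mg(o, gen, spec, anc)
}

# brute-force group generality: enumerate every assignment of g2's pairs to
# g1's pairs and ask whether some assignment is ge throughout
oracle_group_mg <- function(o, g2, g1, anc = NULL) {
  if (is.null(anc)) anc <- oracle_reach_all(o, "out")
  k2 <- ontoaudit:::group_key(g2); k1 <- ontoaudit:::group_key(g1)
  if (k2 == k1) return(FALSE)
  n2 <- length(g2$pairs); n1 <- length(g1$pairs)
  assignments <- expand.grid(rep(list(seq_len(n1)), n2))
  for (r in seq_len(nrow(assignments))) {
    ok <- TRUE
    for (i in seq_len(n2)) {
      if (!oracle_pair_ge(o, g2$pairs[[i]], g1$pairs[[assignments[r, i]]], anc)) {
        ok <- FALSE; break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# closure-intersection-then-reduce oracle for intersect_derived, via the
# materialized derived_groups families
oracle_intersect <- function(o, a, b, bound = 3L, ceiling = 2L) {
  da <- derived_groups(o, a, bound)
  db <- derived_groups(o, b, bound)
  ka <- vapply(da$groups, ontoaudit:::group_key, character(1L))
  kb <- vapply(db$groups, ontoaudit:::group_key, character(1L))
  common <- intersect(ka, kb)
  if (!length(common)) return(character(0L))
  gs <- lapply(common, ontoaudit:::group_from_key)
  gs <- Filter(function(g) !ontoaudit:::group_too_general(o, g, ceiling), gs)
  if (!length(gs)) return(character(0L))
  ontoaudit:::definition_key(reduce_definition(o, logical_definition(gs)))
}

def_key <- function(d) {
  if (!length(d$groups)) character(0L) else ontoaudit:::definition_key(d)
}

# LCS length by exhaustive subsequence enumeration (tiny inputs only)
oracle_lcs <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  is_subseq <- function(s, t) {
    j <- 1L
    for (x in t) {
      if (j <= length(s) && s[[j]] == x) j <- j + 1L
    }
    j > length(s)
  }
  best <- 0L
  for (mask in 0:(2L^length(a) - 1L)) {
    s <- a[bitwAnd(mask, 2L^(seq_along(a) - 1L)) > 0L]
    if (length(s) > best && is_subseq(s, b)) best <- length(s)
  }
  best
}

# ontology with a synonym table mapping "dyspepsia" to the preferred term
# "Indigestion" (the normalization worked example)
make_synonym_fixture <- function() {
  cons <- rbind(
    ontoaudit:::concept_row("root", "SNOMED CT concept (SNOMED RT+CTV3)"),
    ontoaudit:::concept_row("clinical_finding", "Clinical finding (finding)"),
    ontoaudit:::concept_row("indigestion", "Indigestion (finding)",
                            preferred = "Indigestion"),
    ontoaudit:::concept_row("stomach_structure", "Stomach structure (body structure)"))
  isa <- rbind(ontoaudit:::edge("clinical_finding", "root"),
               ontoaudit:::edge("indigestion", "clinical_finding"),
               ontoaudit:::edge("stomach_structure", "root"))
  syn <- data.frame(concept = "indigestion", term = "dyspepsia",
                    stringsAsFactors = FALSE)
  ontology(cons, isa, synonyms = syn, root = "root")
}

# append a proposal's definition to an ontology as a new defined concept
augment_with_definition <- function(o, def, id) {
  cons <- ontoaudit:::concept_row(id, paste0("Inserted concept ", id, " (test)"), TRUE)
  edges <- NULL
  groups <- list()
  for (g in def$groups) {
    isa_pairs <- Filter(function(p) p$attribute == o$isa, g$pairs)
    rest <- Filter(function(p) p$attribute != o$isa, g$pairs)
    for (p in isa_pairs) edges <- rbind(edges, ontoaudit:::edge(id, p$value))
    if (length(rest)) groups[[id]] <- c(groups[[id]], list(att_group(rest)))
  }
  if (is.null(edges)) edges <- ontoaudit:::edge(id, o$root)
  ontoaudit:::ontology_with(o, cons, edges, groups)
}

# shared pipeline shorthand
propose_all <- function(o, min_level = 10L, max_size = 10L, ...) {
  sgs <- enumerate_subgraphs(o, max_size)
  cands <- generate_candidates(o, sgs, min_level)
  propose(o, cands, ...)
}

proposal_keys <- function(props)
  vapply(props, function(p) ontoaudit:::definition_key(p$definition), character(1L))

truth_keys <- function(truth)
  vapply(truth, function(t) ontoaudit:::definition_key(t$definition), character(1L))

# RF2 snapshot writer used by the loader tests
write_rf2_snapshot <- function(dir, concepts, descriptions, relationships,
                               owl = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  wt(concepts, "sct2_Concept_Snapshot_TEST.txt")
  wt(descriptions, "sct2_Description_Snapshot_TEST.txt")
  wt(relationships, "sct2_Relationship_Snapshot_TEST.txt")
  if (!is.null(owl)) wt(owl, "sct2_sRefset_OWLExpressionSnapshot_TEST.txt")
  dir
}

rf2_concept_rows <- function(ids, fully_defined = FALSE, active = "1") {
  data.frame(id = ids, effectiveTime = "20210301", active = active,
             moduleId = "m",
             definitionStatusId = ifelse(fully_defined, "900000000000073002",
                                         "900000000000074008"),
             stringsAsFactors = FALSE)
}

rf2_fsn_rows <- function(ids, terms) {
  data.frame(id = paste0("d", seq_along(ids)), effectiveTime = "20210301",
             active = "1", moduleId = "m", conceptId = ids,
             languageCode = "en", typeId = "900000000000003001", term = terms,
             caseSignificanceId = "cs", stringsAsFactors = FALSE)
}

rf2_rel_rows <- function(source, dest, type, group = "0",
                         characteristic = "900000000000011006") {
  data.frame(id = paste0("r", seq_along(source)), effectiveTime = "20210301",
             active = "1", moduleId = "m", sourceId = source,
             destinationId = dest, relationshipGroup = group, typeId = type,
             characteristicTypeId = characteristic, modifierId = "mod",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
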