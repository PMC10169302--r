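test_that("one-step pair generalization covers the rewrite rules", {
  o <- make_eye_fixture()
  g <- generalize_pair(o, avp("finding_site", "choroidal_structure"))
  keys <- vapply(g, ontoaudit:::pair_key, character(1L))
  expect_true(ontoaudit:::pair_key(avp("finding_site", "eye_proper")) %in% keys)
  expect_true(ontoaudit:::pair_key(avp("finding_site", "body_structure")) %in% keys)
  # a pair whose attribute and value are both the hierarchy root rewrites to nothing
  expect_length(generalize_pair(o, avp("root", "root")), 0L)
})

test_that("one-step generalization equals the brute-force more-general filter", {
  for (o in list(make_eye_fixture(), make_edetate_fixture())) {
    ids <- o$concepts$id
    universe <- list()
    for (r in ids) for (v in ids) universe[[length(universe) + 1L]] <- avp(r, v)
    anc <- oracle_reach_all(o, "out")
    probes <- list(avp("finding_site", "choroidal_structure"),
                   avp(o$isa, "choroidal_structure"),
                   avp("causative_agent", "sodium_calcium_edetate"))
    for (p in probes) {
      if (!p$attribute %in% ids || !p$value %in% ids) next
      got <- sort(vapply(generalize_pair(o, p), ontoaudit:::pair_key, character(1L)))
      want <- Filter(function(q) oracle_pair_mg(o, q, p, anc), universe)
      want <- sort(vapply(want, ontoaudit:::pair_key, character(1L)))
      expect_identical(got, want)
    }
  }
})

test_that("derived definitions contain own groups and their is-a generalizations", {
  o <- make_edetate_fixture()
  dd <- derived_groups(o, "edetate_adverse_reaction")
  own <- own_groups(o, "edetate_adverse_reaction")
  keys <- vapply(dd$groups, ontoaudit:::group_key, character(1L))
  for (g in own$groups)
    expect_true(ontoaudit:::group_key(g) %in% keys)
  # singleton is-a groups for the parent and grandparent are in the closure
  expect_true(ontoaudit:::group_key(att_group(avp(o$isa, "chelating_agent_adverse_reaction"))) %in% keys)
  expect_true(ontoaudit:::group_key(att_group(avp(o$isa, "adverse_reaction"))) %in% keys)
  # every non-own group is same-as-or-more-general than some own group
  own_keys <- vapply(own$groups, ontoaudit:::group_key, character(1L))
  for (g in dd$groups) {
    k <- ontoaudit:::group_key(g)
    if (k %in% own_keys) next
    expect_true(any(vapply(own$groups, function(og)
      group_more_general(o, g, og), logical(1L))))
  }
})

test_that("derived definitions equal exhaustive enumeration over the pair universe", {
  o <- make_edetate_fixture()
  id <- "edetate_adverse_reaction"
  dd <- derived_groups(o, id)
  dkeys <- sort(vapply(dd$groups, ontoaudit:::group_key, character(1L)))
  universe <- sort(unique(unlist(lapply(dd$groups, function(g)
    vapply(g$pairs, ontoaudit:::pair_key, character(1L))))))
  own <- own_groups(o, id)
  # every group of <= 3 pairs over the closure's pair universe that is
  # ge some own group must be in the derived set, and vice versa
  exhaustive <- character(0L)
  for (sz in 1:3) {
    combos <- utils::combn(seq_along(universe), sz)
    for (cix in seq_len(ncol(combos))) {
      g <- att_group(lapply(universe[combos[, cix]], ontoaudit:::pair_from_key))
      ok <- any(vapply(own$groups, function(og)
        ontoaudit:::group_key(g) == ontoaudit:::group_key(og) ||
          group_more_general(o, g, og), logical(1L)))
      if (ok) exhaustive <- c(exhaustive, ontoaudit:::group_key(g))
    }
  }
  small <- dkeys[vapply(strsplit(dkeys, "\x1e", fixed = TRUE), length,
                        integer(1L)) <= 3L]
  expect_identical(small, sort(unique(exhaustive)))
  # resource guard: deep fixtures refuse to materialize
  f <- make_nonlattice_fixture()
  expect_error(derived_groups(f, "neoplasm_vulva", max_closure = 4L),
               "intersect_derived")
})

test_that("intersection of a concept with itself reduces to its own definition", {
  o <- make_nonlattice_fixture()
  for (id in c("neoplasm_vulva", "disorder_bartholin")) {
    d <- intersect_derived(o, id, id)
    expect_identical(ontoaudit:::definition_key(d),
                     ontoaudit:::definition_key(reduce_definition(o, own_groups(o, id))))
  }
})

test_that("intersection is symmetric and dominated by both concepts' own groups", {
  o <- make_nonlattice_fixture()
  a <- "neoplasm_vulva"; b <- "disorder_bartholin"
  d1 <- intersect_derived(o, a, b)
  d2 <- intersect_derived(o, b, a)
  expect_identical(ontoaudit:::definition_key(d1), ontoaudit:::definition_key(d2))
  for (g in d1$groups) {
    for (id in c(a, b)) {
      own <- own_groups(o, id)
      expect_true(any(vapply(own$groups, function(og)
        ontoaudit:::group_key(g) == ontoaudit:::group_key(og) ||
          group_more_general(o, g, og), logical(1L))))
    }
  }
})

test_that("the non-lattice pair's intersection names the shared site and parent", {
  o <- make_nonlattice_fixture()
  d <- intersect_derived(o, "neoplasm_vulva", "disorder_bartholin")
  expect_length(d, 2L)
  expect_identical(
    ontoaudit:::definition_key(d),
    ontoaudit:::definition_key(logical_definition(list(
      att_group(avp("finding_site", "vulval_structure")),
      att_group(avp(o$isa, "disorder_vulva"))))))
})

test_that("direct intersection equals closure-intersection-then-reduce", {
  checked <- 0L
  for (seed in 1:20) {
    o <- random_ontology(20L + (seed %% 4L) * 10L, seed,
                         params = list(p_group = 0.8, max_pairs = 1L,
                                       n_chains = 0L, max_level = 3))
    ids <- grep("^c", o$concepts$id, value = TRUE)
    set.seed(seed + 300)
    pairs <- t(replicate(4L, sample(ids, 2L)))
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]; b <- pairs[r, 2L]
      orc <- tryCatch(oracle_intersect(o, a, b, ceiling = 1L),
                      error = function(e) NULL)  # closure too large to materialize
      if (is.null(orc)) next
      imp <- intersect_derived(o, a, b, ceiling_level = 1L)
      expect_identical(def_key(imp), orc)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 20L)
})

test_that("empty intersections are reported as empty definitions", {
  # two branches sharing only the root: nothing below the generality ceiling
  cons <- rbind(ontoaudit:::concept_row("root", "Root (root)"),
                ontoaudit:::concept_row("x", "X (t)", TRUE),
                ontoaudit:::concept_row("y", "Y (t)", TRUE),
                ontoaudit:::concept_row("z", "Z (t)"),
                ontoaudit:::concept_row("w", "W (t)"))
  isa <- rbind(ontoaudit:::edge("z", "root"), ontoaudit:::edge("w", "root"),
               ontoaudit:::edge("x", "z"), ontoaudit:::edge("y", "w"))
  o <- ontology(cons, isa)
  d <- intersect_derived(o, "x", "y")
  expect_length(d$groups, 0L)
  expect_true(isTRUE(attr(d, "empty")))
})
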