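test_that("pair generality condition (i): same attribute, value subsumption", {
  o <- make_edetate_fixture()
  caar <- avp(o$isa, "chelating_agent_adverse_reaction")
  ear <- avp(o$isa, "edetate_adverse_reaction")
  expect_true(pair_more_general(o, caar, ear))
  expect_false(pair_more_general(o, ear, caar))
  expect_false(pair_more_general(o, ear, ear))  # strict
  expect_true(pair_ge(o, ear, ear))
  expect_true(pair_ge(o, caar, ear))
  expect_false(pair_ge(o, avp("causative_agent", "edetate"),
                       avp(o$isa, "edetate_adverse_reaction")))
})

test_that("pair generality conditions (ii) and (iii): attribute subsumption", {
  cons <- rbind(ontoaudit:::concept_row("root", "Root (root)"),
                ontoaudit:::concept_row("r_gen", "General attribute (attribute)"),
                ontoaudit:::concept_row("r_spec", "Specific attribute (attribute)"),
                ontoaudit:::concept_row("v_gen", "General value (t)"),
                ontoaudit:::concept_row("v_spec", "Specific value (t)"))
  isa <- rbind(ontoaudit:::edge("r_gen", "root"),
               ontoaudit:::edge("r_spec", "r_gen"),
               ontoaudit:::edge("v_gen", "root"),
               ontoaudit:::edge("v_spec", "v_gen"))
  o <- ontology(cons, isa)
  expect_true(pair_more_general(o, avp("r_gen", "v_gen"), avp("r_spec", "v_gen")))
  expect_true(pair_more_general(o, avp("r_gen", "v_gen"), avp("r_spec", "v_spec")))
  expect_false(pair_more_general(o, avp("r_spec", "v_gen"), avp("r_gen", "v_gen")))
  expect_false(pair_more_general(o, avp("r_gen", "v_spec"), avp("r_spec", "v_gen")))
})

test_that("pair generality condition (iv): property chain through the value's definition", {
  o <- make_edetate_fixture()
  gen <- avp("causative_agent", "edetate")
  spec <- avp("causative_agent", "sodium_calcium_edetate")
  # the substances are intentionally not is-a related: only the chain applies
  expect_false(is_subtype(o, "sodium_calcium_edetate", "edetate"))
  expect_true(pair_more_general(o, gen, spec))
  expect_false(pair_more_general(o, spec, gen))
  # removing the chain removes the verdict
  o2 <- ontology(o$concepts, o$isa_edges, groups = o$attribute_rels,
                 chains = NULL, root = o$root, isa_id = o$isa)
  expect_false(pair_more_general(o2, gen, spec))
  expect_error(pair_more_general(o, gen, avp("causative_agent", "nope")),
               "unknown concept")
})

test_that("pair generality matches the condition oracle and is transitive without chains", {
  for (seed in 1:20) {
    o <- random_ontology(25, seed, params = list(p_group = 0.6))
    anc <- oracle_reach_all(o, "out")
    atts <- grep("^a", o$concepts$id, value = TRUE)
    vals <- grep("^c", o$concepts$id, value = TRUE)
    set.seed(seed)
    ps <- lapply(1:5, function(i) avp(sample(c(atts, o$isa), 1L), sample(vals, 1L)))
    for (p in ps) for (q in ps) {
      expect_identical(pair_more_general(o, p, q), oracle_pair_mg(o, p, q, anc))
      expect_false(pair_more_general(o, p, p))
    }
    for (p in ps) for (q in ps) for (r in ps) {
      if (pair_more_general(o, p, q) && pair_more_general(o, q, r))
        expect_true(pair_more_general(o, p, r))
      if (pair_ge(o, p, q) && pair_ge(o, q, r))
        expect_true(pair_ge(o, p, r))  # preorder under (i)-(iii)
    }
  }
})

test_that("group generality: the eye-structure group dominates the choroid group", {
  o <- make_eye_fixture()
  g1 <- toxoplasma_group(o, "choroidal_structure")
  g2 <- toxoplasma_group(o, "eye_proper")
  expect_true(group_more_general(o, g2, g1))
  expect_false(group_more_general(o, g1, g2))
  expect_false(group_more_general(o, g1, g1))
  # an extra pair unmatched in g1 destroys generality
  g3 <- att_group(c(g2$pairs, list(avp("finding_site", "organism"))))
  expect_false(group_more_general(o, g3, g1))
  expect_error(group_more_general(o, structure(list(pairs = list()),
                                               class = "att_group"), g1),
               "non-empty")
})

test_that("group generality agrees with the brute-force assignment matcher", {
  for (seed in 1:20) {
    o <- random_ontology(20, seed, params = list(n_chains = 1))
    anc <- oracle_reach_all(o, "out")
    atts <- c(grep("^a", o$concepts$id, value = TRUE), o$isa)
    vals <- grep("^c", o$concepts$id, value = TRUE)
    set.seed(seed + 100)
    rand_group <- function() {
      n <- sample.int(5L, 1L)
      att_group(lapply(seq_len(n), function(i)
        avp(sample(atts, 1L), sample(vals, 1L))))
    }
    gs <- lapply(1:4, function(i) rand_group())
    for (g2 in gs) for (g1 in gs) {
      expect_identical(group_more_general(o, g2, g1),
                       oracle_group_mg(o, g2, g1, anc))
    }
  }
})

test_that("definition reduction removes dominated groups and is idempotent", {
  o <- make_eye_fixture()
  g1 <- toxoplasma_group(o, "choroidal_structure")
  g2 <- toxoplasma_group(o, "eye_proper")
  red <- reduce_definition(o, logical_definition(list(g2, g1)))
  expect_length(red, 1L)
  expect_identical(ontoaudit:::group_key(red$groups[[1L]]),
                   ontoaudit:::group_key(g1))
  expect_identical(ontoaudit:::definition_key(reduce_definition(o, red)),
                   ontoaudit:::definition_key(red))

  # chain g3 > g2 > g1 along a value hierarchy collapses to the most specific
  f <- make_nonlattice_fixture()
  gs <- lapply(c("bartholin_structure", "vulval_structure", "body_structure"),
               function(v) att_group(avp("finding_site", v)))
  red2 <- reduce_definition(f, logical_definition(gs))
  expect_length(red2, 1L)
  expect_identical(red2$groups[[1L]]$pairs[[1L]]$value, "bartholin_structure")

  # mutually-general pair {p} vs {p, p'} (p' dominated) unifies to one group
  p <- avp("finding_site", "bartholin_structure")
  pp <- avp("finding_site", "vulval_structure")
  red3 <- reduce_definition(f, logical_definition(list(att_group(p),
                                                       att_group(list(p, pp)))))
  expect_length(red3, 1L)
  expect_identical(ontoaudit:::group_key(red3$groups[[1L]]),
                   ontoaudit:::pair_key(p))
})

test_that("definition reduction is order-insensitive and non-empty on random inputs", {
  for (seed in 1:20) {
    o <- random_ontology(20, seed)
    atts <- c(grep("^a", o$concepts$id, value = TRUE), o$isa)
    vals <- grep("^c", o$concepts$id, value = TRUE)
    set.seed(seed + 200)
    gs <- lapply(1:5, function(i) {
      att_group(lapply(seq_len(sample.int(3L, 1L)), function(j)
        avp(sample(atts, 1L), sample(vals, 1L))))
    })
    d1 <- reduce_definition(o, logical_definition(gs))
    d2 <- reduce_definition(o, logical_definition(rev(gs)))
    expect_gt(length(d1$groups), 0L)
    expect_identical(ontoaudit:::definition_key(d1), ontoaudit:::definition_key(d2))
    expect_identical(ontoaudit:::definition_key(reduce_definition(o, d1)),
                     ontoaudit:::definition_key(d1))
    # no surviving group is strictly more general than another survivor
    for (ga in d1$groups) for (gb in d1$groups) {
      if (ontoaudit:::group_key(ga) != ontoaudit:::group_key(gb))
        expect_false(group_more_general(o, ga, gb) && !group_more_general(o, gb, ga))
    }
  }
})
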