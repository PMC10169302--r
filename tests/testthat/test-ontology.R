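test_that("construction validates ids, parents and acyclicity", {
  cons <- rbind(ontoaudit:::concept_row("root", "Root (root)"),
                ontoaudit:::concept_row("a", "A (test)"),
                ontoaudit:::concept_row("b", "B (test)"))
  isa <- rbind(ontoaudit:::edge("a", "root"), ontoaudit:::edge("b", "a"))
  o <- ontology(cons, isa)
  expect_s3_class(o, "ontology")
  expect_identical(o$root, "root")

  expect_error(ontology(rbind(cons, cons[2, ]), isa), "duplicate concept id")
  expect_error(ontology(cons[1:2, ], isa), "unknown concept")
  expect_error(ontology(cons, isa[1, , drop = FALSE], root = "root"),
               "without an is-a parent")
  expect_error(ontology(cons, isa[1, , drop = FALSE]), "ambiguous")
  cyc <- rbind(isa, ontoaudit:::edge("a", "b"))
  expect_error(ontology(cons, cyc), "cycle")
  expect_error(ontology(cons[0, ], isa), "empty")
})

test_that("inactive concepts are dropped and empty fsn rejected", {
  cons <- rbind(ontoaudit:::concept_row("root", "Root (root)"),
                ontoaudit:::concept_row("a", "A (test)"),
                ontoaudit:::concept_row("gone", "Gone (test)"))
  cons$active[cons$id == "gone"] <- FALSE
  isa <- rbind(ontoaudit:::edge("a", "root"))
  o <- ontology(cons, isa)
  expect_false(has_concept <- "gone" %in% o$concepts$id)
  bad <- cons; bad$fsn[2] <- ""
  expect_error(ontology(bad, isa), "empty fsn")
})

test_that("fixture dialect round-trips an ontology", {
  for (o in list(make_nonlattice_fixture(), make_edetate_fixture(),
                 random_ontology(25, 7, params = list(n_chains = 1)))) {
    d <- withr::local_tempdir()
    write_fixture(o, d)
    o2 <- load_fixture(d)
    expect_true(ontology_equal(o, o2))
  }
})

test_that("fixture loader enforces mandatory files and reports cycles", {
  d <- withr::local_tempdir()
  expect_error(load_fixture(file.path(d, "nope")), "not found")
  write_fixture(make_nonlattice_fixture(), d)
  unlink(file.path(d, "isa.tsv"))
  expect_error(load_fixture(d), "isa.tsv")

  d2 <- withr::local_tempdir()
  write_fixture(make_nonlattice_fixture(), d2)
  isa <- utils::read.delim(file.path(d2, "isa.tsv"), colClasses = "character")
  isa <- rbind(isa, data.frame(child = "disorder_vulva",
                               parent = "benign_neoplasm_bartholin"))
  utils::write.table(isa, file.path(d2, "isa.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_fixture(d2), "cycle")

  d3 <- withr::local_tempdir()
  dir.create(d3, showWarnings = FALSE)
  writeLines("id\tfsn\tpreferred_term\tfully_defined\tactive",
             file.path(d3, "concepts.tsv"))
  writeLines("child\tparent", file.path(d3, "isa.tsv"))
  expect_error(load_fixture(d3), "empty")
})

test_that("the shipped minimal non-lattice fixture loads with all 7 named concepts", {
  dir <- system.file("extdata", "nonlattice_minimal", package = "ontoaudit")
  o <- load_fixture(dir)
  named <- c("root", "neoplasm_vulva", "disorder_bartholin",
             "benign_neoplasm_vulva", "malignant_tumor_vulva",
             "benign_neoplasm_bartholin", "malignant_neoplasm_bartholin")
  expect_true(all(named %in% o$concepts$id))
  # 7 named concepts plus the is-a attribute bookkeeping concept
  expect_identical(nrow(o$concepts), 8L)
})

test_that("ancestors/descendants agree with a reachability oracle on random DAGs", {
  for (seed in 1:20) {
    n <- 20L + (seed %% 5L) * 20L  # 20..100 nodes
    o <- random_ontology(n, seed)
    anc <- oracle_reach_all(o, "out")
    des <- oracle_reach_all(o, "in")
    for (id in o$concepts$id) {
      expect_setequal(ancestors(o, id), anc[[id]])
      expect_setequal(descendants(o, id), des[[id]])
    }
  }
})

test_that("subtype test is irreflexive and matches reachability", {
  o <- make_edetate_fixture()
  expect_true(is_subtype(o, "edetate_adverse_reaction",
                         "chelating_agent_adverse_reaction"))
  expect_false(is_subtype(o, "chelating_agent_adverse_reaction",
                          "edetate_adverse_reaction"))
  for (id in o$concepts$id) expect_false(is_subtype(o, id, id))
  expect_error(is_subtype(o, "edetate", "nope"), "unknown concept")
  o2 <- random_ontology(40, 3)
  anc <- oracle_reach_all(o2, "out")
  ids <- o2$concepts$id
  for (a in ids[1:10]) for (b in ids[1:10]) {
    if (a == b) next
    expect_identical(is_subtype(o2, a, b), b %in% anc[[a]])
  }
})

test_that("levels follow the longest path from the root", {
  cons <- rbind(ontoaudit:::concept_row("root", "Root (root)"),
                ontoaudit:::concept_row("a", "A (t)"),
                ontoaudit:::concept_row("b", "B (t)"),
                ontoaudit:::concept_row("c", "C (t)"),
                ontoaudit:::concept_row("d", "D (t)"))
  # chain root -> a -> b -> c and diamond: d under both a (short) and c (long)
  isa <- rbind(ontoaudit:::edge("a", "root"), ontoaudit:::edge("b", "a"),
               ontoaudit:::edge("c", "b"), ontoaudit:::edge("d", "a"),
               ontoaudit:::edge("d", "c"))
  o <- ontology(cons, isa)
  expect_identical(concept_level(o, "root"), 0L)
  expect_identical(concept_level(o, "c"), 3L)
  expect_identical(concept_level(o, "d"), 4L)  # longest side of the diamond
  for (seed in 1:5) {
    ro <- random_ontology(30, seed)
    lv <- concept_levels(ro)
    for (k in seq_len(nrow(ro$isa_edges))) {
      e <- ro$isa_edges[k, ]
      if (!is.na(lv[[e$child]]) && !is.na(lv[[e$parent]]))
        expect_gt(lv[[e$child]], lv[[e$parent]])
    }
  }
})

test_that("own groups pair one singleton group per is-a parent with the attribute groups", {
  o <- make_thyroid_fixture()
  id <- concept_by_fsn(o, "Malignant epithelial neoplasm of thyroid (disorder)")
  d <- own_groups(o, id)
  expect_length(d, 3L)
  sizes <- sort(vapply(d$groups, function(g) length(g$pairs), integer(1L)))
  expect_identical(sizes, c(1L, 1L, 2L))

  # 1 parent, 0 attribute groups -> 1 group; 2 parents, 2 groups -> 4
  f <- make_nonlattice_fixture()
  expect_length(own_groups(f, "disease"), 1L)
  for (seed in 1:5) {
    ro <- random_ontology(30, seed)
    for (id in ro$concepts$id) {
      expected <- length(ro$parents[[id]]) +
        length(ro$attribute_rels[[id]] %||% list())
      if (expected == 0L) expect_length(own_groups(ro, id)$groups, 0L)
      else expect_length(own_groups(ro, id), expected)
    }
  }
})

test_that("fsn helpers resolve and fail loudly", {
  o <- make_nonlattice_fixture()
  expect_identical(concept_fsn(o, "neoplasm_vulva"), "Neoplasm of vulva (disorder)")
  expect_identical(concept_by_fsn(o, "Neoplasm of vulva (disorder)"), "neoplasm_vulva")
  expect_error(concept_by_fsn(o, "No such (disorder)"), "no concept")
  expect_error(ancestors(o, "nope"), "unknown concept")
})
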