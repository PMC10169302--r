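# Fixture and random-ontology generation. The named fixtures encode the
# worked examples used throughout the documentation and tests (a vulva/
# Bartholin non-lattice subgraph, the thyroid grouping example, the
# toxoplasma chorioretinitis group-generality example, the edetate
# property-chain example, a digoxin product for serialization). The random
# generator plants missing concepts by construction so recovery is
# guaranteed identifiable without any licensed release.

concept_row <- function(id, fsn, fully_defined = FALSE, preferred = NA) {
  data.frame(id = id, fsn = fsn,
             preferred_term = if (is.na(preferred)) strip_semantic_tag(fsn) else preferred,
             fully_defined = fully_defined, active = TRUE, stringsAsFactors = FALSE)
}

edge <- function(child, parent) {
  data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
}

#' Non-lattice subgraph fixture (vulva / Bartholin's gland)
#'
#' A small terminology around the classic non-lattice example: the pair
#' ("Neoplasm of vulva", "Disorder of Bartholin's gland") shares two maximal
#' common descendants (the benign and malignant Bartholin-gland neoplasms),
#' with the benign and malignant vulval neoplasms in between — a size-6
#' subgraph. A padding chain gives the pair level 10 and both members are
#' fully defined with finding-site/morphology groups, so the pair qualifies
#' as a candidate under the default thresholds and its intersection proposes
#' a concept.
#'
#' @return An [ontology].
#' @export
make_nonlattice_fixture <- function() {
  cons <- rbind(
    concept_row("root", "SNOMED CT concept (SNOMED RT+CTV3)"),
    # padding chain, levels 1..9
    concept_row("clinical_finding", "Clinical finding (finding)"),
    concept_row("disease", "Disease (disorder)"),
    concept_row("disorder_body_region", "Disorder of body region structure (disorder)"),
    concept_row("disorder_trunk", "Disorder of trunk (disorder)"),
    concept_row("disorder_pelvis", "Disorder of pelvic region (disorder)"),
    concept_row("disorder_genitalia", "Disorder of genital structure (disorder)"),
    concept_row("disorder_female_genitalia", "Disorder of female genital structure (disorder)"),
    concept_row("disorder_ext_female_genitalia", "Disorder of external female genital organ (disorder)"),
    concept_row("disorder_vulva", "Disorder of vulva (disorder)"),
    # the subgraph, levels 10..12
    concept_row("neoplasm_vulva", "Neoplasm of vulva (disorder)", TRUE),
    concept_row("disorder_bartholin", "Disorder of Bartholin's gland (disorder)", TRUE),
    concept_row("benign_neoplasm_vulva", "Benign neoplasm of vulva (disorder)"),
    concept_row("malignant_tumor_vulva", "Malignant tumor of vulva (disorder)"),
    concept_row("benign_neoplasm_bartholin", "Benign neoplasm of Bartholin's gland (disorder)"),
    concept_row("malignant_neoplasm_bartholin", "Malignant neoplasm of greater vestibular (Bartholin's) gland (disorder)"),
    # attributes
    concept_row("finding_site", "Finding site (attribute)"),
    concept_row("assoc_morph", "Associated morphology (attribute)"),
    # body structures
    concept_row("body_structure", "Body structure (body structure)"),
    concept_row("structure_pelvis", "Structure of pelvis (body structure)"),
    concept_row("structure_female_genitalia", "Structure of female genital organ (body structure)"),
    concept_row("vulval_structure", "Vulval structure (body structure)"),
    concept_row("bartholin_structure", "Structure of Bartholin's gland (body structure)"),
    # morphologies
    concept_row("morph_abnorm", "Morphologically abnormal structure (morphologic abnormality)"),
    concept_row("neoplasm_morph", "Neoplasm (morphologic abnormality)"),
    concept_row("benign_neoplasm_morph", "Neoplasm, benign (morphologic abnormality)"),
    concept_row("malignant_neoplasm_morph", "Neoplasm, malignant (morphologic abnormality)"))
  isa <- rbind(
    edge("clinical_finding", "root"),
    edge("disease", "clinical_finding"),
    edge("disorder_body_region", "disease"),
    edge("disorder_trunk", "disorder_body_region"),
    edge("disorder_pelvis", "disorder_trunk"),
    edge("disorder_genitalia", "disorder_pelvis"),
    edge("disorder_female_genitalia", "disorder_genitalia"),
    edge("disorder_ext_female_genitalia", "disorder_female_genitalia"),
    edge("disorder_vulva", "disorder_ext_female_genitalia"),
    edge("neoplasm_vulva", "disorder_vulva"),
    edge("disorder_bartholin", "disorder_vulva"),
    edge("benign_neoplasm_vulva", "neoplasm_vulva"),
    edge("malignant_tumor_vulva", "neoplasm_vulva"),
    edge("benign_neoplasm_bartholin", "benign_neoplasm_vulva"),
    edge("benign_neoplasm_bartholin", "disorder_bartholin"),
    edge("malignant_neoplasm_bartholin", "malignant_tumor_vulva"),
    edge("malignant_neoplasm_bartholin", "disorder_bartholin"),
    edge("finding_site", "root"),
    edge("assoc_morph", "root"),
    edge("body_structure", "root"),
    edge("structure_pelvis", "body_structure"),
    edge("structure_female_genitalia", "structure_pelvis"),
    edge("vulval_structure", "structure_female_genitalia"),
    edge("bartholin_structure", "vulval_structure"),
    edge("morph_abnorm", "root"),
    edge("neoplasm_morph", "morph_abnorm"),
    edge("benign_neoplasm_morph", "neoplasm_morph"),
    edge("malignant_neoplasm_morph", "neoplasm_morph"))
  groups <- list(
    disorder_vulva = list(att_group(avp("finding_site", "vulval_structure"))),
    neoplasm_vulva = list(att_group(list(
      avp("finding_site", "vulval_structure"),
      avp("assoc_morph", "neoplasm_morph")))),
    disorder_bartholin = list(att_group(avp("finding_site", "bartholin_structure"))),
    benign_neoplasm_vulva = list(att_group(list(
      avp("finding_site", "vulval_structure"),
      avp("assoc_morph", "benign_neoplasm_morph")))),
    malignant_tumor_vulva = list(att_group(list(
      avp("finding_site", "vulval_structure"),
      avp("assoc_morph", "malignant_neoplasm_morph")))),
    benign_neoplasm_bartholin = list(att_group(list(
      avp("finding_site", "bartholin_structure"),
      avp("assoc_morph", "benign_neoplasm_morph")))),
    malignant_neoplasm_bartholin = list(att_group(list(
      avp("finding_site", "bartholin_structure"),
      avp("assoc_morph", "malignant_neoplasm_morph")))))
  ontology(cons, isa, groups = groups, root = "root")
}

#' Grouping-convention fixture (thyroid neoplasm)
#'
#' Encodes "Malignant epithelial neoplasm of thyroid (disorder)" with its
#' two is-a parents and one two-pair attribute group, so its own logical
#' definition has exactly three attribute groups under the convention that
#' every is-a parent occupies a singleton group.
#'
#' @return An [ontology].
#' @export
make_thyroid_fixture <- function() {
  cons <- rbind(
    concept_row("root", "SNOMED CT concept (SNOMED RT+CTV3)"),
    concept_row("clinical_finding", "Clinical finding (finding)"),
    concept_row("disease", "Disease (disorder)"),
    concept_row("neoplastic_disease", "Neoplastic disease (disorder)"),
    concept_row("malignant_neoplastic_disease", "Malignant neoplastic disease (disorder)"),
    concept_row("malignant_tumor_thyroid", "Malignant tumor of thyroid gland (disorder)"),
    concept_row("malignant_epithelial_neoplasm", "Malignant epithelial neoplasm (disorder)"),
    concept_row("malignant_epithelial_neoplasm_thyroid",
                "Malignant epithelial neoplasm of thyroid (disorder)", TRUE),
    concept_row("assoc_morph", "Associated morphology (attribute)"),
    concept_row("finding_site", "Finding site (attribute)"),
    concept_row("morph_abnorm", "Morphologically abnormal structure (morphologic abnormality)"),
    concept_row("men_category", "Malignant epithelial neoplasm - category (morphologic abnormality)"),
    concept_row("body_structure", "Body structure (body structure)"),
    concept_row("thyroid_structure", "Thyroid structure (body structure)"))
  isa <- rbind(
    edge("clinical_finding", "root"),
    edge("disease", "clinical_finding"),
    edge("neoplastic_disease", "disease"),
    edge("malignant_neoplastic_disease", "neoplastic_disease"),
    edge("malignant_tumor_thyroid", "malignant_neoplastic_disease"),
    edge("malignant_epithelial_neoplasm", "malignant_neoplastic_disease"),
    edge("malignant_epithelial_neoplasm_thyroid", "malignant_tumor_thyroid"),
    edge("malignant_epithelial_neoplasm_thyroid", "malignant_epithelial_neoplasm"),
    edge("assoc_morph", "root"),
    edge("finding_site", "root"),
    edge("morph_abnorm", "root"),
    edge("men_category", "morph_abnorm"),
    edge("body_structure", "root"),
    edge("thyroid_structure", "body_structure"))
  groups <- list(
    malignant_epithelial_neoplasm_thyroid = list(att_group(list(
      avp("assoc_morph", "men_category"),
      avp("finding_site", "thyroid_structure")))))
  ontology(cons, isa, groups = groups, root = "root")
}

#' Group-generality fixture (toxoplasma chorioretinitis)
#'
#' Two attribute groups sharing pathological-process and causative-agent
#' pairs but differing in finding site: "Choroidal structure" versus its
#' ancestor "Structure of eye proper". The group naming the ancestor is
#' strictly more general. [toxoplasma_group()] builds either group.
#'
#' @return An [ontology].
#' @export
make_eye_fixture <- function() {
  cons <- rbind(
    concept_row("root", "SNOMED CT concept (SNOMED RT+CTV3)"),
    concept_row("pathological_process", "Pathological process (attribute)"),
    concept_row("causative_agent", "Causative agent (attribute)"),
    concept_row("finding_site", "Finding site (attribute)"),
    concept_row("qualifier_value", "Qualifier value (qualifier value)"),
    concept_row("parasitic_process", "Parasitic process (qualifier value)"),
    concept_row("organism", "Organism (organism)"),
    concept_row("toxoplasma_gondii", "Toxoplasma gondii (organism)"),
    concept_row("body_structure", "Body structure (body structure)"),
    concept_row("eye_proper", "Structure of eye proper (body structure)"),
    concept_row("choroidal_structure", "Choroidal structure (body structure)"))
  isa <- rbind(
    edge("pathological_process", "root"),
    edge("causative_agent", "root"),
    edge("finding_site", "root"),
    edge("qualifier_value", "root"),
    edge("parasitic_process", "qualifier_value"),
    edge("organism", "root"),
    edge("toxoplasma_gondii", "organism"),
    edge("body_structure", "root"),
    edge("eye_proper", "body_structure"),
    edge("choroidal_structure", "eye_proper"))
  ontology(cons, isa, root = "root")
}

#' @rdname make_eye_fixture
#' @param o The eye fixture ontology.
#' @param site `"choroidal_structure"` or `"eye_proper"`.
#' @export
toxoplasma_group <- function(o, site = c("choroidal_structure", "eye_proper")) {
  site <- match.arg(site)
  att_group(list(avp("pathological_process", "parasitic_process"),
                 avp("causative_agent", "toxoplasma_gondii"),
                 avp("finding_site", site)))
}

#' Property-chain fixture (edetate adverse reactions)
#'
#' Encodes the chelating-agent / edetate adverse-reaction hierarchy, the
#' substance "Sodium calcium edetate" carrying an is-modification-of pair
#' pointing at "Edetate", and the property chain
#' causative agent o is modification of -> causative agent, so that
#' (Causative agent, "Edetate") is more general than
#' (Causative agent, "Sodium calcium edetate") through the chain alone
#' (the two substances are deliberately not is-a related).
#'
#' @return An [ontology].
#' @export
make_edetate_fixture <- function() {
  cons <- rbind(
    concept_row("root", "SNOMED CT concept (SNOMED RT+CTV3)"),
    concept_row("causative_agent", "Causative agent (attribute)"),
    concept_row("is_modification_of", "Is modification of (attribute)"),
    concept_row("substance", "Substance (substance)"),
    concept_row("chelating_agent", "Chelating agent (substance)"),
    concept_row("edetate", "Edetate (substance)"),
    concept_row("sodium_calcium_edetate", "Sodium calcium edetate (substance)"),
    concept_row("clinical_finding", "Clinical finding (finding)"),
    concept_row("adverse_reaction", "Adverse reaction (disorder)"),
    concept_row("chelating_agent_adverse_reaction",
                "Chelating agent adverse reaction (disorder)", TRUE),
    concept_row("edetate_adverse_reaction", "Edetate adverse reaction (disorder)", TRUE))
  isa <- rbind(
    edge("causative_agent", "root"),
    edge("is_modification_of", "root"),
    edge("substance", "root"),
    edge("chelating_agent", "substance"),
    edge("edetate", "chelating_agent"),
    edge("sodium_calcium_edetate", "substance"),
    edge("clinical_finding", "root"),
    edge("adverse_reaction", "clinical_finding"),
    edge("chelating_agent_adverse_reaction", "adverse_reaction"),
    edge("edetate_adverse_reaction", "chelating_agent_adverse_reaction"))
  groups <- list(
    sodium_calcium_edetate = list(att_group(avp("is_modification_of", "edetate"))),
    chelating_agent_adverse_reaction = list(att_group(avp("causative_agent", "chelating_agent"))),
    edetate_adverse_reaction = list(att_group(avp("causative_agent", "edetate"))))
  chains <- data.frame(first = "causative_agent", second = "is_modification_of",
                       implied = "causative_agent", stringsAsFactors = FALSE)
  ontology(cons, isa, groups = groups, chains = chains, root = "root")
}

#' Serialization fixture (digoxin product)
#'
#' A medicinal product whose two-pair definition serializes to the sentence
#' "Is a Product containing glycoside (product), Has active ingredient
#' Digoxin (substance)."
#'
#' @return An [ontology].
#' @export
make_digoxin_fixture <- function() {
  cons <- rbind(
    concept_row("root", "SNOMED CT concept (SNOMED RT+CTV3)"),
    concept_row("has_active_ingredient", "Has active ingredient (attribute)"),
    concept_row("product", "Product (product)"),
    concept_row("product_glycoside", "Product containing glycoside (product)"),
    concept_row("product_digoxin", "Product containing digoxin (medicinal product)", TRUE),
    concept_row("substance", "Substance (substance)"),
    concept_row("glycoside", "Glycoside (substance)"),
    concept_row("digoxin", "Digoxin (substance)"))
  isa <- rbind(
    edge("has_active_ingredient", "root"),
    edge("product", "root"),
    edge("product_glycoside", "product"),
    edge("product_digoxin", "product_glycoside"),
    edge("substance", "root"),
    edge("glycoside", "substance"),
    edge("digoxin", "glycoside"))
  groups <- list(
    product_digoxin = list(att_group(avp("has_active_ingredient", "digoxin"))))
  ontology(cons, isa, groups = groups, root = "root")
}

#' Random ontology generator
#'
#' Deterministic (per seed) generator of an acyclic is-a DAG with a small
#' attribute hierarchy, grouped attribute relationships, a configurable
#' fully-defined fraction and optional property chains. Concepts are added
#' in index order with parents drawn from earlier concepts, so acyclicity
#' holds by construction; every ontology passes the construction-time
#' validation of [ontology()].
#'
#' @param n_concepts Number of ordinary concepts including the root (>= 5).
#' @param seed Integer seed.
#' @param params Optional list overriding: `n_attributes` (3),
#'   `p_extra_parent` (0.25), `p_group` (0.5), `max_groups` (2),
#'   `max_pairs` (2), `p_fully_defined` (0.6), `n_chains` (0), `max_level`
#'   (`Inf`; when finite, parents are only drawn from concepts above that
#'   depth, bounding the hierarchy depth and hence generalization-closure
#'   sizes).
#' @return An [ontology].
#' @export
random_ontology <- function(n_concepts, seed, params = list()) {
  if (n_concepts < 5L) stop("need at least 5 concepts")
  p <- utils::modifyList(list(n_attributes = 3L, p_extra_parent = 0.25,
                              p_group = 0.5, max_groups = 2L, max_pairs = 2L,
                              p_fully_defined = 0.6, n_chains = 0L,
                              max_level = Inf), params)
  if (p$n_attributes < 1L) stop("need at least one attribute concept")
  if (p$n_chains > 0L && p$n_attributes < 2L)
    stop("property chains need at least two attribute concepts")
  with_private_rng(seed, {
    ids <- c("root", paste0("c", seq_len(n_concepts - 1L)))
    atts <- paste0("a", seq_len(p$n_attributes))
    cons <- rbind(
      concept_row("root", "Root concept (root)"),
      do.call(rbind, lapply(seq_len(n_concepts - 1L), function(i)
        concept_row(paste0("c", i), sprintf("Test concept %d (test)", i),
                    stats::runif(1) < p$p_fully_defined))),
      do.call(rbind, lapply(seq_len(p$n_attributes), function(i)
        concept_row(paste0("a", i), sprintf("Test attribute %d (attribute)", i)))))
    edges <- list()
    lev <- c(root = 0L)
    for (i in seq_len(n_concepts - 1L)) {
      pool <- ids[seq_len(i)]  # root plus earlier concepts
      pool <- pool[lev[pool] < p$max_level]
      pa <- if (length(pool) == 1L) pool else sample(pool, 1L)
      edges[[length(edges) + 1L]] <- edge(ids[[i + 1L]], pa)
      lv <- lev[[pa]] + 1L
      if (length(pool) > 1L && stats::runif(1) < p$p_extra_parent) {
        pb <- sample(setdiff(pool, pa), 1L)
        edges[[length(edges) + 1L]] <- edge(ids[[i + 1L]], pb)
        lv <- max(lv, lev[[pb]] + 1L)
      }
      lev[[ids[[i + 1L]]]] <- lv
    }
    # shallow attribute hierarchy: a1 under root, later attributes under
    # root or an earlier attribute
    for (i in seq_len(p$n_attributes)) {
      pool <- c("root", if (i > 1L) atts[seq_len(i - 1L)])
      edges[[length(edges) + 1L]] <- edge(atts[[i]],
        if (length(pool) == 1L) pool else sample(pool, 1L))
    }
    isa <- do.call(rbind, edges)
    groups <- list()
    for (i in seq_len(n_concepts - 1L)) {
      if (stats::runif(1) >= p$p_group) next
      ng <- sample.int(p$max_groups, 1L)
      gl <- lapply(seq_len(ng), function(g) {
        np <- sample.int(p$max_pairs, 1L)
        att_group(lapply(seq_len(np), function(k)
          avp(sample(atts, 1L), sample(ids[-1L], 1L))))
      })
      groups[[paste0("c", i)]] <- gl
    }
    chains <- NULL
    if (p$n_chains > 0L) {
      chains <- unique(do.call(rbind, lapply(seq_len(p$n_chains), function(k) {
        data.frame(first = sample(atts, 1L), second = sample(atts, 1L),
                   implied = sample(atts, 1L), stringsAsFactors = FALSE)
      })))
    }
    ontology(cons, isa, groups = groups, chains = chains, root = "root")
  })
}

# Rebuild an ontology with extra concepts/edges/groups appended.
ontology_with <- function(o, add_concepts = NULL, add_edges = NULL,
                          add_groups = NULL) {
  cons <- o$concepts
  if (!is.null(add_concepts)) cons <- rbind(cons, add_concepts)
  isa <- o$isa_edges
  if (!is.null(add_edges)) isa <- rbind(isa, add_edges)
  groups <- o$attribute_rels
  for (nm in names(add_groups)) {
    groups[[nm]] <- c(groups[[nm]], add_groups[[nm]])
  }
  # the is-a attribute concept was auto-added by the original constructor;
  # keep it and its edge (already in the tables)
  ontology(cons, isa, groups = groups, chains = o$chains,
           synonyms = o$synonyms, root = o$root, isa_id = o$isa)
}

#' Plant recoverable missing concepts into an ontology
#'
#' Grafts, per plant, a padded branch holding an unrelated fully defined
#' concept pair (A, B) that (a) shares two common children, making (A, B) a
#' non-lattice pair with a size-4 subgraph, and (b) carries attribute groups
#' whose values meet at a fresh common ancestor, so that the intersection of
#' the pair's derived definitions is a unique definition no existing concept
#' has. The "pruned" ontology omits the missing concept M; the "unpruned"
#' ontology additionally contains M (children of M re-parented directly
#' under A and B in both), so proposing on it exercises suppression. The
#' truth records the pair and M's definition, computed at construction time
#' via [intersect_derived()].
#'
#' @param o Base [ontology] (e.g. from [random_ontology()]).
#' @param seed Integer seed (chooses the graft point).
#' @param n Number of independent plants (default 1).
#' @param min_level The candidate level threshold the plants must clear
#'   (default 10; the padding chain is sized from it).
#' @return A list: `pruned`, `unpruned` ([ontology] objects) and `truth`
#'   (list of `list(pair, definition)` records).
#' @export
plant_missing_concept <- function(o, seed, n = 1L, min_level = 10L) {
  stopifnot(n >= 1L)
  existing <- o$concepts$id
  graft <- with_private_rng(seed, {
    pool <- setdiff(existing, o$isa)
    if (length(pool) == 1L) pool else sample(pool, 1L)
  })
  pad_len <- min_level  # graft at level >= 0, chain of min_level puts A,B at >= min_level + 1
  pads <- paste0("plant_pad", seq_len(pad_len))
  cons <- do.call(rbind, lapply(seq_len(pad_len), function(i)
    concept_row(pads[[i]], sprintf("Planted padding %d (test)", i))))
  edges <- edge(pads[[1L]], graft)
  for (i in seq_len(pad_len - 1L))
    edges <- rbind(edges, edge(pads[[i + 1L]], pads[[i]]))
  # fresh value branch: root -> vstem -> vdeep -> v0_k -> {va_k, vb_k}
  cons <- rbind(cons,
                concept_row("plant_vstem", "Planted value stem (test)"),
                concept_row("plant_vdeep", "Planted value branch (test)"),
                concept_row("plant_attr", "Planted site (attribute)"))
  edges <- rbind(edges, edge("plant_vstem", "root"),
                 edge("plant_vdeep", "plant_vstem"),
                 edge("plant_attr", "root"))
  groups <- list()
  truth_specs <- list()
  top <- pads[[pad_len]]
  for (k in seq_len(n)) {
    v0 <- sprintf("plant_v0_%d", k)
    va <- sprintf("plant_va_%d", k); vb <- sprintf("plant_vb_%d", k)
    A <- sprintf("plant_A_%d", k); B <- sprintf("plant_B_%d", k)
    C1 <- sprintf("plant_C1_%d", k); C2 <- sprintf("plant_C2_%d", k)
    cons <- rbind(cons,
      concept_row(v0, sprintf("Planted common site %d (test)", k)),
      concept_row(va, sprintf("Planted site %da (test)", k)),
      concept_row(vb, sprintf("Planted site %db (test)", k)),
      concept_row(A, sprintf("Planted finding %dA (test)", k), TRUE),
      concept_row(B, sprintf("Planted finding %dB (test)", k), TRUE),
      concept_row(C1, sprintf("Planted finding %dC1 (test)", k)),
      concept_row(C2, sprintf("Planted finding %dC2 (test)", k)))
    edges <- rbind(edges,
      edge(v0, "plant_vdeep"), edge(va, v0), edge(vb, v0),
      edge(A, top), edge(B, top),
      edge(C1, A), edge(C1, B), edge(C2, A), edge(C2, B))
    groups[[A]] <- list(att_group(avp("plant_attr", va)))
    groups[[B]] <- list(att_group(avp("plant_attr", vb)))
    truth_specs[[k]] <- list(pair = sort(c(A, B)), M = sprintf("plant_M_%d", k))
  }
  base <- if (any(duplicated(c(existing, cons$id)))) stop("no plantable site: id clash") else o
  pruned <- ontology_with(base, cons, edges, groups)
  truth <- lapply(truth_specs, function(ts) {
    def <- intersect_derived(pruned, ts$pair[[1L]], ts$pair[[2L]])
    if (!length(def$groups)) stop("no plantable site: empty planted intersection")
    list(pair = ts$pair, definition = def)
  })
  keys <- vapply(truth, function(t) definition_key(t$definition), character(1L))
  if (any(keys %in% existing_definition_keys(pruned)) || anyDuplicated(keys))
    stop("no plantable site: planted definition not identifiable")
  # unpruned: insert each M with exactly its truth definition
  m_cons <- NULL; m_edges <- NULL; m_groups <- list()
  for (k in seq_len(n)) {
    M <- truth_specs[[k]]$M
    d <- truth[[k]]$definition
    m_cons <- rbind(m_cons, concept_row(M, sprintf("Planted missing finding %d (test)", k), TRUE))
    for (g in d$groups) {
      isa_pairs <- Filter(function(p) p$attribute == pruned$isa, g$pairs)
      rest <- Filter(function(p) p$attribute != pruned$isa, g$pairs)
      for (p in isa_pairs) m_edges <- rbind(m_edges, edge(M, p$value))
      if (length(rest)) m_groups[[M]] <- c(m_groups[[M]], list(att_group(rest)))
    }
  }
  unpruned <- ontology_with(pruned, m_cons, m_edges, m_groups)
  list(pruned = pruned, unpruned = unpruned, truth = truth)
}
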