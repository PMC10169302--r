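test_that("normalization lowercases, lemmatizes, replaces synonyms and drops stop words", {
  o <- make_synonym_fixture()
  n <- normalize_name("Dyspepsia  of stomach (finding)", o)
  expect_identical(n$tokens, c("indigestion", "stomach"))
  expect_identical(n$tag, "finding")
  # plural handling
  expect_identical(normalize_name("Cutaneous infections (disorder)")$tokens,
                   c("cutaneous", "infection"))
  # the semantic tag is split off and not matched as tokens
  expect_identical(normalize_name("Cutaneous infection (disorder)")$tokens,
                   normalize_name("Cutaneous infections")$tokens)
  # a documented miss: re-ordered noun compounds normalize differently
  a <- normalize_name("Closure of fistula of sclera (procedure)")
  b <- normalize_name("Closure of scleral fistula (procedure)")
  expect_identical(a$tokens, c("closure", "fistula", "sclera"))
  expect_identical(b$tokens, c("closure", "scleral", "fistula"))
  expect_false(identical(a$tokens, b$tokens))
})

test_that("normalization is idempotent on arbitrary printable strings", {
  o <- make_synonym_fixture()
  set.seed(123)
  alphabet <- c(letters, LETTERS, 0:9, " ", " ", " ", "-", "'", "(", ")", ",",
                ".", "/", ";")
  for (i in 1:40) {
    s <- paste(sample(alphabet, sample(5:40, 1L), replace = TRUE), collapse = "")
    if (!nzchar(trimws(s))) next
    n1 <- normalize_name(s, o)
    if (!length(n1$tokens)) next
    n2 <- normalize_name(paste(n1$tokens, collapse = " "), o)
    expect_identical(n2$tokens, n1$tokens)
  }
  for (tok in c("infections", "studies", "classes", "viruses", "boxes",
                "feet", "lens", "status", "myringitis", "glasses")) {
    l1 <- default_lemmatizer(tok)
    expect_identical(default_lemmatizer(l1), l1)
  }
})

test_that("lexicon matching finds lemmatized atoms and rejects near misses", {
  lex <- read_lexicon_tsv(system.file("extdata", "lexicon_demo.tsv",
                                      package = "ontoaudit"))
  hit <- match_lexicon("Cutaneous infection (disorder)", lex)
  expect_identical(hit$aui, "A24682086")
  expect_identical(hit$cui, "C1853193")
  # the same pipeline on both sides: swapping the inflected form still matches
  hit2 <- match_lexicon("Cutaneous infections", lex)
  expect_identical(hit2$aui, "A24682086")
  # an atom with an extra token does not match
  expect_identical(nrow(match_lexicon("Severe cutaneous infection of arm (disorder)", lex)), 0L)
  expect_identical(nrow(match_lexicon("Anything", lex[0, ])), 0L)
  # irregular plural through lemmatization
  expect_identical(match_lexicon("Lesion of foot (disorder)", lex)$aui, "A13728295")
})

test_that("MRCONSO-style files are parsed with an English filter", {
  path <- withr::local_tempfile(fileext = ".RRF")
  writeLines(c(
    "C1853193|ENG|P|L123|PF|S123|Y|A24682086||||HPO|PT|HP:1|Cutaneous infections|0|N||",
    "C1853193|SPA|P|L124|PF|S124|Y|A999|||||PT|X|Infecciones cutaneas|0|N||"),
    path)
  lex <- read_mrconso(path)
  expect_identical(nrow(lex), 1L)
  expect_identical(lex$aui, "A24682086")
  expect_identical(lex$cui, "C1853193")
  expect_identical(lex$source, "HPO")
  expect_identical(lex$name, "Cutaneous infections")
})

test_that("noun-phrase indexing matches whole phrases only", {
  docs <- read_corpus_jsonl(system.file("extdata", "corpus_demo.jsonl",
                                        package = "ontoaudit"))
  idx <- build_np_index(docs)
  # the title phrase "pulmonary artery operations" validates the operation concept
  expect_identical(search_np(idx, "Pulmonary artery operation (procedure)"),
                   "20072857")
  # "thoracic artery" only occurs inside "fetal thoracic artery": no match
  expect_length(search_np(idx, "Thoracic artery (body structure)"), 0L)
  expect_identical(search_np(idx, "Fetal thoracic artery (body structure)"),
                   "30000001")
  expect_length(search_np(build_np_index(docs[0, ]), "Lung cyst (disorder)"), 0L)
  # whole-phrase property: indexed phrases match themselves, never extensions
  some <- c("lung cysts", "pulmonary artery operations")
  for (ph in some) {
    expect_true("20072857" %in% search_np(idx, ph))
    expect_length(search_np(idx, paste("massive", ph)), 0L)
  }
})

test_that("PubMed-style XML corpora are read into the same document shape", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<PubmedArticleSet>",
    " <PubmedArticle><MedlineCitation><PMID>20072857</PMID><Article>",
    "  <ArticleTitle>Lung cysts following pulmonary artery operations</ArticleTitle>",
    "  <Abstract><AbstractText>Part one.</AbstractText><AbstractText>Part two.</AbstractText></Abstract>",
    " </Article></MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"), path)
  docs <- read_corpus_pubmed_xml(path)
  expect_identical(docs$id, "20072857")
  expect_identical(docs$abstract, "Part one. Part two.")
  idx <- build_np_index(docs)
  expect_identical(search_np(idx, "Pulmonary artery operation (procedure)"),
                   "20072857")
})

test_that("a failing chunker skips the document with a warning", {
  docs <- data.frame(id = c("1", "2"), title = c("Alpha beta", "Gamma delta"),
                     abstract = c("", ""), stringsAsFactors = FALSE)
  chunker <- function(text) {
    if (grepl("Gamma", text)) stop("parse failure")
    default_chunker(text)
  }
  expect_warning(idx <- build_np_index(docs, chunker), "chunker failed on document 2")
  expect_identical(search_np(idx, "Alpha beta"), "1")
  expect_length(search_np(idx, "Gamma delta"), 0L)
})

test_that("newer-release matching distinguishes the four match kinds", {
  o <- make_nonlattice_fixture()
  props <- propose_all(o)
  expect_length(props, 1L)
  p <- props[[1L]]  # definition: {is-a Disorder of vulva} {Finding site Vulval structure}
  p$predicted_fsn <- "Neoplasm of Bartholin's gland (disorder)"

  newer_with <- function(fsn, with_def = TRUE) {
    cons <- ontoaudit:::concept_row("new1", fsn, TRUE)
    groups <- if (with_def)
      list(new1 = list(att_group(avp("finding_site", "vulval_structure"))))
    edges <- if (with_def) ontoaudit:::edge("new1", "disorder_vulva")
      else ontoaudit:::edge("new1", "disease")
    ontoaudit:::ontology_with(o, cons, edges, groups)
  }
  # same FSN and same definition
  r1 <- match_release(p, newer_with("Neoplasm of Bartholin's gland (disorder)"))
  expect_identical(r1$match_kind, "fsn+definition")
  expect_identical(r1$concept_id, "new1")
  # same FSN, different definition
  r2 <- match_release(p, newer_with("Neoplasm of Bartholin's gland (disorder)", FALSE))
  expect_identical(r2$match_kind, "fsn_only")
  # same definition, different FSN
  r3 <- match_release(p, newer_with("Bartholin neoplasia (disorder)"))
  expect_identical(r3$match_kind, "definition_only")
  # name matches up to the semantic tag only: recorded but not validated
  p2 <- p; p2$definition <- logical_definition(att_group(avp("assoc_morph", "neoplasm_morph")))
  r4 <- match_release(p2, newer_with("Neoplasm of Bartholin's gland (finding)", FALSE))
  expect_identical(r4$match_kind, "tag_differs")
  v4 <- validate_proposal(p2, o, newer = newer_with("Neoplasm of Bartholin's gland (finding)", FALSE))
  expect_false(v4$validated)
  # no counterpart at all
  expect_null(match_release(p2, o))
})

test_that("proposal validation aggregates the three matchers", {
  o <- make_nonlattice_fixture()
  props <- propose_all(o)
  p <- props[[1L]]
  p$predicted_fsn <- "Benign neoplasm of vulva (disorder)"
  lex <- read_lexicon_tsv(system.file("extdata", "lexicon_demo.tsv",
                                      package = "ontoaudit"))
  idx <- build_np_index(read_corpus_jsonl(system.file("extdata", "corpus_demo.jsonl",
                                                      package = "ontoaudit")))
  v <- validate_proposal(p, o, lexicon = lex, np_index = idx)
  expect_true(v$validated)
  expect_identical(v$by_lexicon$aui, "A9999002")
  # the corpus only carries the phrase "benign vulval neoplasms"
  expect_length(v$by_corpus, 0L)
  p2 <- p; p2$predicted_fsn <- "Benign vulval neoplasm (disorder)"
  v2 <- validate_proposal(p2, o, lexicon = lex, np_index = idx)
  expect_true(v2$validated)
  expect_identical(v2$by_corpus, "30000002")
  expect_identical(nrow(v2$by_lexicon), 0L)
  # nothing supplied, nothing validated
  v0 <- validate_proposal(p, o)
  expect_false(v0$validated)
})
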