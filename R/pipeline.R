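# Stage runners tying the pipeline together: audit (non-lattice subgraphs),
# propose (candidate pairs -> missing-concept proposals), name-data (naming
# datasets + splits) and validate (lexicon / corpus / newer-release
# matching). Each stage is deterministic given (config, seed) and writes
# plain-text outputs with stage counts.

#' Pipeline configuration
#'
#' Collects every tunable the pipeline stages use. Thresholds default to
#' the values used in the underlying auditing methodology: subgraph size
#' cap 10 (inclusive), candidate level threshold 10, chain rewrite depth 3,
#' generality ceiling 2, 80/10/10 split ratios.
#'
#' @param ontology An [ontology] object, or a path to a fixture directory
#'   (`format = "fixture"`) or RF2 snapshot (`format = "rf2"`).
#' @param format Input format when `ontology` is a path.
#' @param out_dir Output directory for stage artifacts.
#' @param max_subgraph_size,inclusive Subgraph size threshold, see
#'   [enumerate_subgraphs()].
#' @param min_level Candidate level threshold, see [generate_candidates()].
#' @param chain_depth,ceiling_level See [intersect_derived()].
#' @param ratios Train/valid/test ratios, see [split_dataset()].
#' @param seed Integer seed for every randomized step.
#' @param lexicon Optional path to a lexicon table (TSV dialect; `.RRF`
#'   files are read as MRCONSO).
#' @param corpus Optional path to a JSON-lines corpus.
#' @param newer Optional path to a newer-release fixture directory.
#' @return A list of class `audit_config`.
#' @export
audit_config <- function(ontology, format = c("fixture", "rf2"),
                         out_dir = tempfile("ontoaudit"),
                         max_subgraph_size = 10L, inclusive = TRUE,
                         min_level = 10L, chain_depth = 3L, ceiling_level = 2L,
                         ratios = c(0.8, 0.1, 0.1), seed = 1L,
                         lexicon = NULL, corpus = NULL, newer = NULL) {
  format <- match.arg(format)
  if (!inherits(ontology, "ontology") && !is.character(ontology))
    stop("config field 'ontology' must be an ontology object or a path")
  if (!is.numeric(max_subgraph_size) || max_subgraph_size < 2L)
    stop("config field 'max_subgraph_size' must be at least 2")
  if (!is.numeric(min_level) || min_level < 0L)
    stop("config field 'min_level' must be non-negative")
  structure(list(ontology = ontology, format = format, out_dir = out_dir,
                 max_subgraph_size = as.integer(max_subgraph_size),
                 inclusive = isTRUE(inclusive),
                 min_level = as.integer(min_level),
                 chain_depth = as.integer(chain_depth),
                 ceiling_level = as.integer(ceiling_level),
                 ratios = ratios, seed = as.integer(seed),
                 lexicon = lexicon, corpus = corpus, newer = newer),
            class = "audit_config")
}

config_ontology <- function(config) {
  if (inherits(config$ontology, "ontology")) return(config$ontology)
  if (config$format == "rf2") load_rf2(config$ontology)
  else load_fixture(config$ontology)
}

stage_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config$out_dir
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the audit stage: non-lattice subgraph report
#'
#' Enumerates non-lattice subgraphs within the size threshold and writes
#' `subgraphs.json` plus a count log to the configured output directory.
#'
#' @param config An [audit_config()].
#' @return Invisibly, a list with `ontology`, `subgraphs` and `counts`.
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  o <- config_ontology(config)
  sgs <- enumerate_subgraphs(o, config$max_subgraph_size, config$inclusive)
  out <- stage_dir(config)
  payload <- lapply(sgs, function(sg) list(
    seed_pair = sg$seed_pair, mcas = sg$mcas, mcds = sg$mcds,
    concepts = sg$concepts, size = sg$size,
    edges = lapply(seq_len(nrow(sg$edges)), function(i)
      list(child = sg$edges$child[[i]], parent = sg$edges$parent[[i]]))))
  write_stage_json(payload, file.path(out, "subgraphs.json"))
  counts <- list(concepts = nrow(o$concepts), subgraphs = length(sgs))
  write_stage_json(counts, file.path(out, "audit_counts.json"))
  message(sprintf("audit: %d non-lattice subgraphs (size <= %d) in %d concepts",
                  length(sgs), config$max_subgraph_size, nrow(o$concepts)))
  invisible(list(ontology = o, subgraphs = sgs, counts = counts))
}

#' Run the propose stage: missing-concept proposals
#'
#' Audits, filters candidate pairs, intersects their derived definitions and
#' writes `candidates.tsv`, `proposals.jsonl`, a readable `proposals.txt`
#' report and a count log.
#'
#' @param config An [audit_config()].
#' @return Invisibly, a list with `ontology`, `subgraphs`, `candidates`,
#'   `proposals` and `counts`.
#' @export
run_propose <- function(config) {
  audit <- run_audit(config)
  o <- audit$ontology
  cands <- generate_candidates(o, audit$subgraphs, config$min_level)
  props <- propose(o, cands, chain_depth = config$chain_depth,
                   ceiling_level = config$ceiling_level)
  out <- stage_dir(config)
  candidates_to_tsv(o, cands, file.path(out, "candidates.tsv"))
  proposals_to_jsonl(props, file.path(out, "proposals.jsonl"))
  writeLines(proposals_report(o, props), file.path(out, "proposals.txt"),
             useBytes = TRUE)
  counts <- c(audit$counts, list(
    candidates = length(cands), proposals = length(props),
    empty_intersections = attr(props, "n_empty"),
    suppressed_existing = attr(props, "n_suppressed")))
  write_stage_json(counts, file.path(out, "propose_counts.json"))
  message(sprintf("propose: %d candidates -> %d proposals (%d empty, %d already defined)",
                  length(cands), length(props), attr(props, "n_empty"),
                  attr(props, "n_suppressed")))
  invisible(list(ontology = o, subgraphs = audit$subgraphs, candidates = cands,
                 proposals = props, counts = counts))
}

#' Run the name-data stage: naming datasets and splits
#'
#' Serializes every definable concept and writes train/valid/test TSVs and
#' split manifests under the configured output directory.
#'
#' @param config An [audit_config()].
#' @return Invisibly, the per-split instance data frames.
#' @export
run_name_data <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  o <- config_ontology(config)
  out <- stage_dir(config)
  res <- write_naming_data(o, file.path(out, "naming"), config$ratios, config$seed)
  message(sprintf("name-data: %d/%d/%d train/valid/test instances",
                  nrow(res$train), nrow(res$valid), nrow(res$test)))
  invisible(res)
}

#' Run the validate stage: match proposals against external resources
#'
#' Runs the propose stage, names each proposal with the supplied namer, then
#' matches against whichever of lexicon, corpus and newer release the config
#' provides (stages without inputs are skipped with a warning). Writes
#' `validation.json`.
#'
#' @param config An [audit_config()].
#' @param namer A naming function (default: [make_template_namer()] on the
#'   source ontology).
#' @return Invisibly, a list with `proposals` (validation attached) and
#'   `counts`.
#' @export
run_validate <- function(config, namer = NULL) {
  pro <- run_propose(config)
  o <- pro$ontology
  if (is.null(namer)) namer <- make_template_namer(o)
  lexicon <- NULL
  if (!is.null(config$lexicon)) {
    lexicon <- if (grepl("\\.rrf$", config$lexicon, ignore.case = TRUE))
      read_mrconso(config$lexicon) else read_lexicon_tsv(config$lexicon)
  } else warning("no lexicon configured; lexicon validation skipped", call. = FALSE)
  np_index <- NULL
  if (!is.null(config$corpus)) {
    docs <- if (grepl("\\.xml$", config$corpus, ignore.case = TRUE))
      read_corpus_pubmed_xml(config$corpus) else read_corpus_jsonl(config$corpus)
    np_index <- build_np_index(docs, o = o)
  } else warning("no corpus configured; corpus validation skipped", call. = FALSE)
  newer <- NULL
  if (!is.null(config$newer)) {
    newer <- load_fixture(config$newer)
  } else warning("no newer release configured; release validation skipped",
                 call. = FALSE)
  props <- lapply(pro$proposals, function(p) {
    p$predicted_fsn <- tryCatch(
      as.character(namer(serialize_definition(o, p$definition)))[[1L]],
      error = function(e) NULL)
    p$validation <- validate_proposal(p, o, lexicon, np_index, newer)
    p
  })
  out <- stage_dir(config)
  payload <- lapply(props, function(p) list(
    predicted_fsn = if (is.null(p$predicted_fsn)) NA else p$predicted_fsn,
    definition = lapply(p$definition$groups, function(g)
      lapply(g$pairs, function(pr) list(attribute = pr$attribute, value = pr$value))),
    by_lexicon = p$validation$by_lexicon,
    by_corpus = p$validation$by_corpus,
    by_release = if (is.null(p$validation$by_release)) NULL else p$validation$by_release,
    validated = p$validation$validated))
  write_stage_json(payload, file.path(out, "validation.json"))
  n_valid <- sum(vapply(props, function(p) isTRUE(p$validation$validated), logical(1L)))
  counts <- c(pro$counts, list(validated = n_valid))
  write_stage_json(counts, file.path(out, "validate_counts.json"))
  message(sprintf("validate: %d of %d proposals validated", n_valid, length(props)))
  invisible(list(proposals = props, counts = counts))
}
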