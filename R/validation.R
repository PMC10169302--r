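# Name normalization and the three validation matchers: lexicon atom tables
# (UMLS MRCONSO-style), base-noun-phrase corpus indexes, and a newer
# terminology release. Normalization pipeline, in order: semantic tag split
# off -> whitespace collapse -> lowercase -> lemmatization -> synonym-to-
# preferred-term replacement against the ontology -> stop-word removal.

#' Default English stop-word list
#'
#' Small, fixed, overridable list used by [normalize_name()]. Deliberately
#' includes prepositions so that e.g. "Closure of fistula of sclera"
#' normalizes to the token sequence closure/fistula/sclera.
#'
#' @return Character vector of stop words.
#' @export
ontoaudit_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "by", "due", "for", "from",
    "has", "in", "into", "is", "it", "of", "on", "or", "that", "the", "to",
    "was", "were", "will", "with")
}

# irregular plurals handled before the suffix rules
.IRREGULAR_LEMMA <- c(feet = "foot", teeth = "tooth", children = "child",
                      men = "man", women = "woman", mice = "mouse")

#' Rule-based default lemmatizer
#'
#' Token-to-lemma function behind the pluggable lemmatizer contract: a few
#' irregular plurals plus idempotent English suffix rules (ies -> y;
#' -sses/-xes/-zes/-ches/-shes/-ses drop es; a final s drops unless the
#' token ends in ss/us/is). Any other `function(token) -> lemma` can be
#' supplied to [normalize_name()] instead.
#'
#' @param token A single lowercase token.
#' @return The lemma.
#' @export
default_lemmatizer <- function(token) {
  hit <- .IRREGULAR_LEMMA[token]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(token)
  if (n <= 3L) return(token)
  if (grepl("ies$", token) && n > 4L) return(sub("ies$", "y", token))
  if (grepl("(sses|xes|zes|ches|shes|ses)$", token)) return(sub("es$", "", token))
  if (grepl("[^su]s$", token) && !grepl("is$", token)) return(sub("s$", "", token))
  token
}

#' Normalize a concept name for cross-source matching
#'
#' Splits off a trailing parenthesized semantic tag (held separately and
#' excluded from token matching), collapses whitespace, lowercases,
#' lemmatizes each token, replaces synonyms with the preferred term of the
#' corresponding concept (longest-first, left-to-right, single pass over the
#' token sequence), and removes stop words. Idempotent: normalizing the
#' joined tokens of a normalized name changes nothing.
#'
#' @param name A non-empty string.
#' @param o Optional [ontology] supplying the synonym-to-preferred-term
#'   table; `NULL` skips replacement.
#' @param stopwords Stop-word list (default [ontoaudit_stopwords()]).
#' @param lemmatizer Token-to-lemma function (default [default_lemmatizer()]).
#' @return An object of class `normalized_name`: `tokens` (character),
#'   `original`, `tag` (string or `NA`).
#' @examples
#' n <- normalize_name("Cutaneous infections (disorder)")
#' n$tokens  # "cutaneous" "infection"
#' n$tag     # "disorder"
#' @export
normalize_name <- function(name, o = NULL, stopwords = ontoaudit_stopwords(),
                           lemmatizer = default_lemmatizer) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  tag <- semantic_tag(name)
  body <- if (is.na(tag)) name else strip_semantic_tag(name)
  body <- tolower(trimws(gsub("\\s+", " ", body)))
  body <- gsub("'", "", body, fixed = TRUE)  # possessives: bartholin's -> bartholins
  body <- gsub("[^a-z0-9 ]", " ", body)
  toks <- strsplit(body, "\\s+")[[1L]]
  toks <- toks[nzchar(toks)]
  toks <- vapply(toks, lemmatizer, character(1L), USE.NAMES = FALSE)
  if (!is.null(o)) toks <- replace_synonyms(toks, o, lemmatizer)
  toks <- toks[!toks %in% stopwords]
  structure(list(tokens = toks, original = name, tag = unname(tag)),
            class = "normalized_name")
}

#' @export
print.normalized_name <- function(x, ...) {
  cat(sprintf("<normalized name: \"%s\"%s>\n", paste(x$tokens, collapse = " "),
              if (is.na(x$tag)) "" else paste0(" (", x$tag, ")")))
  invisible(x)
}

name_key <- function(nn) paste(nn$tokens, collapse = " ")

# synonym-token-sequence -> preferred-term-token-sequence map, memoized.
# Entries whose replacement equals the key, or whose key tokens occur in a
# replacement (which would break idempotence), are dropped.
synonym_map <- function(o, lemmatizer) {
  if (!is.null(o$cache$syn_map)) return(o$cache$syn_map)
  map <- list()
  if (nrow(o$synonyms)) {
    lemtoks <- function(s) {
      s <- tolower(trimws(gsub("\\s+", " ", s)))
      s <- gsub("'", "", s, fixed = TRUE)
      s <- gsub("[^a-z0-9 ]", " ", s)
      t <- strsplit(s, "\\s+")[[1L]]
      t <- t[nzchar(t)]
      vapply(t, lemmatizer, character(1L), USE.NAMES = FALSE)
    }
    pref <- o$concepts$preferred_term[match(o$synonyms$concept, o$concepts$id)]
    for (i in seq_len(nrow(o$synonyms))) {
      from <- lemtoks(o$synonyms$term[[i]])
      to <- lemtoks(pref[[i]])
      if (!length(from) || !length(to)) next
      key <- paste(from, collapse = " ")
      if (key == paste(to, collapse = " ")) next
      if (is.null(map[[key]])) map[[key]] <- to
    }
    # idempotence guard: drop entries whose replacement contains another key
    keys <- names(map)
    if (length(keys)) {
      bad <- vapply(keys, function(k) {
        to <- map[[k]]
        any(vapply(keys, function(k2) {
          kt <- strsplit(k2, " ", fixed = TRUE)[[1L]]
          length(kt) <= length(to) &&
            any(vapply(seq_len(length(to) - length(kt) + 1L), function(s)
              identical(to[s:(s + length(kt) - 1L)], kt), logical(1L)))
        }, logical(1L)))
      }, logical(1L))
      map <- map[!bad]
    }
  }
  o$cache$syn_map <- map
  map
}

replace_synonyms <- function(toks, o, lemmatizer) {
  map <- synonym_map(o, lemmatizer)
  if (!length(map) || !length(toks)) return(toks)
  key_lens <- vapply(names(map), function(k)
    length(strsplit(k, " ", fixed = TRUE)[[1L]]), integer(1L))
  max_len <- max(key_lens)
  out <- character(0L)
  i <- 1L
  while (i <= length(toks)) {
    hit <- FALSE
    for (w in seq.int(min(max_len, length(toks) - i + 1L), 1L)) {
      key <- paste(toks[i:(i + w - 1L)], collapse = " ")
      if (!is.null(map[[key]])) {
        out <- c(out, map[[key]])
        i <- i + w
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      out <- c(out, toks[[i]])
      i <- i + 1L
    }
  }
  out
}

#' Match a name against a lexicon of atoms
#'
#' Exact match of normalized token sequences (semantic tags excluded on both
#' sides) between an FSN and the atom names of a lexicon table, e.g. UMLS
#' atoms where each row carries an atom identifier (AUI) and the concept
#' identifier (CUI) grouping synonymous atoms.
#'
#' @param fsn The name to look up.
#' @param lexicon `data.frame` with columns `aui`, `cui`, `source`, `name`
#'   (see [read_lexicon_tsv()] / [read_mrconso()]).
#' @param o Optional [ontology] for synonym replacement during
#'   normalization (the same pipeline is applied to both sides).
#' @return `data.frame` with columns `aui`, `cui` of matching atoms.
#' @export
match_lexicon <- function(fsn, lexicon, o = NULL) {
  empty <- data.frame(aui = character(), cui = character(), stringsAsFactors = FALSE)
  if (is.null(lexicon) || nrow(lexicon) == 0L) return(empty)
  key <- name_key(normalize_name(fsn, o))
  atom_keys <- vapply(lexicon$name, function(nm)
    name_key(normalize_name(nm, o)), character(1L), USE.NAMES = FALSE)
  hit <- atom_keys == key & nzchar(key)
  if (!any(hit)) return(empty)
  data.frame(aui = lexicon$aui[hit], cui = lexicon$cui[hit],
             stringsAsFactors = FALSE)
}

#' Read lexicon atom tables
#'
#' `read_lexicon_tsv` reads the minimal fixture dialect (tab-separated
#' columns aui, cui, source, name). `read_mrconso` reads a pipe-delimited
#' MRCONSO-style RRF file (CUI in column 1, language in column 2, AUI in
#' column 8, source vocabulary in column 12, string in column 15), keeping
#' English rows only.
#'
#' @param path Input file.
#' @return `data.frame` with columns `aui`, `cui`, `source`, `name`.
#' @export
read_lexicon_tsv <- function(path) {
  df <- read_tsv_file(path)
  need <- c("aui", "cui", "source", "name")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("lexicon table lacks column(s): ", paste(miss, collapse = ", "))
  df[, need]
}

#' @rdname read_lexicon_tsv
#' @export
read_mrconso <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "|", fixed = TRUE)
  keep <- vapply(parts, function(p) length(p) >= 15L && p[[2L]] == "ENG", logical(1L))
  parts <- parts[keep]
  data.frame(
    aui = vapply(parts, `[[`, character(1L), 8L),
    cui = vapply(parts, `[[`, character(1L), 1L),
    source = vapply(parts, `[[`, character(1L), 12L),
    name = vapply(parts, `[[`, character(1L), 15L),
    stringsAsFactors = FALSE)
}

#' Default base-noun-phrase chunker
#'
#' Splits text on sentence punctuation and extracts maximal runs of content
#' tokens between closed-class words (articles, prepositions, conjunctions,
#' pronouns, auxiliaries and common verbal connectives). An approximation of
#' a part-of-speech-based noun-phrase chunker adequate for title/abstract
#' matching; any `function(text) -> character vector of phrases` can replace
#' it in [build_np_index()].
#'
#' @param text A string.
#' @return Character vector of candidate base noun phrases.
#' @export
default_chunker <- function(text) {
  closed <- c("the", "a", "an", "this", "that", "these", "those", "some", "any",
              "each", "every", "no", "of", "in", "on", "at", "by", "for",
              "with", "without", "from", "to", "into", "onto", "over", "under",
              "between", "among", "during", "before", "after", "following",
              "and", "or", "but", "nor", "as", "than", "is", "are", "was",
              "were", "be", "been", "being", "has", "have", "had", "do",
              "does", "did", "can", "could", "may", "might", "will", "would",
              "shall", "should", "must", "not", "it", "its", "their", "his",
              "her", "we", "they", "he", "she", "i", "you", "who", "which",
              "whose", "when", "where", "while", "because", "if", "then",
              "also", "such", "via", "versus", "vs")
  segs <- strsplit(text, "[.;:!?()\\[\\]\"]+")[[1L]]
  out <- character(0L)
  for (seg in segs) {
    toks <- strsplit(tolower(seg), "[^a-z0-9'-]+")[[1L]]
    toks <- toks[nzchar(toks)]
    run <- character(0L)
    for (t in c(toks, "")) {
      if (!nzchar(t) || t %in% closed) {
        if (length(run)) out <- c(out, paste(run, collapse = " "))
        run <- character(0L)
      } else run <- c(run, t)
    }
  }
  unique(out)
}

#' Build and search a normalized noun-phrase index of a corpus
#'
#' `build_np_index` runs the chunker over every document's title and
#' abstract, normalizes each phrase and stores it in an inverted index keyed
#' by the joined token sequence. `search_np` normalizes the query name
#' (semantic tag excluded) and returns the documents containing it as a
#' whole base noun phrase — a name occurring only inside a longer phrase
#' does not match. A chunker failure skips that document with a warning.
#'
#' @param documents `data.frame` with columns `id`, `title`, `abstract`.
#' @param chunker Phrase extractor contract (default [default_chunker()]).
#' @param o Optional [ontology] for normalization.
#' @param index An index from `build_np_index`.
#' @param fsn Query name.
#' @return `build_np_index`: an object of class `np_index`; `search_np`: a
#'   character vector of document ids.
#' @export
build_np_index <- function(documents, chunker = default_chunker, o = NULL) {
  idx <- new.env(parent = emptyenv())
  n_phrases <- 0L
  for (i in seq_len(nrow(documents))) {
    did <- as.character(documents$id[[i]])
    phrases <- tryCatch(
      unique(c(chunker(documents$title[[i]]), chunker(documents$abstract[[i]]))),
      error = function(e) {
        warning("chunker failed on document ", did, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(phrases)) next
    for (ph in phrases) {
      key <- name_key(normalize_name(ph, o))
      if (!nzchar(key)) next
      n_phrases <- n_phrases + 1L
      idx[[key]] <- unique(c(idx[[key]], did))
    }
  }
  structure(list(index = idx, n_docs = nrow(documents), n_phrases = n_phrases),
            class = "np_index")
}

#' @rdname build_np_index
#' @export
search_np <- function(index, fsn, o = NULL) {
  stopifnot(inherits(index, "np_index"))
  key <- name_key(normalize_name(fsn, o))
  hits <- index$index[[key]]
  if (is.null(hits)) character(0L) else sort(hits, method = "radix")
}

#' Read a JSON-lines corpus
#'
#' One JSON object per line with fields `id`, `title`, `abstract`.
#'
#' @param path Input file.
#' @return `data.frame` with columns `id`, `title`, `abstract`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    data.frame(id = as.character(obj$id),
               title = if (is.null(obj$title)) "" else obj$title,
               abstract = if (is.null(obj$abstract)) "" else obj$abstract,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a PubMed-style XML corpus
#'
#' Extracts PMID, article title and abstract text from a PubMed XML file
#' (`PubmedArticle` records); multiple `AbstractText` sections are joined
#' with spaces. Only titles and abstracts are read.
#'
#' @param path Input XML file.
#' @return `data.frame` with columns `id`, `title`, `abstract`.
#' @export
read_corpus_pubmed_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  rows <- lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- paste(xml2::xml_text(xml2::xml_find_all(a, ".//Abstract/AbstractText")),
                  collapse = " ")
    data.frame(id = pmid, title = ifelse(is.na(title), "", title),
               abstract = abst, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(id = character(), title = character(),
                      abstract = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Match a proposal against a newer terminology release
#'
#' Compares a proposal's predicted FSN (normalized, semantic tag included)
#' and its logical definition against every concept of a newer release.
#' Match kinds: `"fsn+definition"`, `"fsn_only"`, `"definition_only"`, or
#' `"tag_differs"` (name tokens match but the semantic tag differs —
#' recorded, yet not counted as validated).
#'
#' @param pmc A `potential_missing_concept` (with `predicted_fsn` set for
#'   the name comparisons).
#' @param newer The newer-release [ontology].
#' @return `NULL` when nothing matches, else a list with `concept_id` and
#'   `match_kind`.
#' @export
match_release <- function(pmc, newer) {
  stopifnot(inherits(pmc, "potential_missing_concept"))
  fsn_ids <- character(0L); tag_ids <- character(0L)
  if (!is.null(pmc$predicted_fsn)) {
    q <- normalize_name(pmc$predicted_fsn, newer)
    for (i in seq_len(nrow(newer$concepts))) {
      cand <- normalize_name(newer$concepts$fsn[[i]], newer)
      if (!identical(q$tokens, cand$tokens)) next
      same_tag <- (is.na(q$tag) && is.na(cand$tag)) ||
        (!is.na(q$tag) && !is.na(cand$tag) && q$tag == cand$tag)
      if (same_tag) fsn_ids <- c(fsn_ids, newer$concepts$id[[i]])
      else tag_ids <- c(tag_ids, newer$concepts$id[[i]])
    }
  }
  def_keys <- existing_definition_keys(newer)
  def_ids <- names(def_keys)[def_keys == definition_key(pmc$definition)]
  both <- intersect(fsn_ids, def_ids)
  if (length(both)) return(list(concept_id = both[[1L]], match_kind = "fsn+definition"))
  if (length(fsn_ids)) return(list(concept_id = fsn_ids[[1L]], match_kind = "fsn_only"))
  if (length(def_ids)) return(list(concept_id = def_ids[[1L]], match_kind = "definition_only"))
  if (length(tag_ids)) return(list(concept_id = tag_ids[[1L]], match_kind = "tag_differs"))
  NULL
}

#' Validate a proposal against all available resources
#'
#' Runs the lexicon, corpus and newer-release matchers that were supplied
#' and assembles a validation result. A proposal is `validated` when the
#' lexicon or corpus matches, or the release matches with any kind other
#' than `"tag_differs"`.
#'
#' @param pmc A `potential_missing_concept`.
#' @param o The source [ontology] (used for normalization).
#' @param lexicon Optional lexicon `data.frame`.
#' @param np_index Optional `np_index`.
#' @param newer Optional newer-release [ontology].
#' @return An object of class `validation_result`: `by_lexicon`,
#'   `by_corpus`, `by_release`, `validated`.
#' @export
validate_proposal <- function(pmc, o, lexicon = NULL, np_index = NULL,
                              newer = NULL) {
  by_lex <- data.frame(aui = character(), cui = character(), stringsAsFactors = FALSE)
  by_corpus <- character(0L)
  by_release <- NULL
  if (!is.null(pmc$predicted_fsn)) {
    if (!is.null(lexicon)) by_lex <- match_lexicon(pmc$predicted_fsn, lexicon, o)
    if (!is.null(np_index)) by_corpus <- search_np(np_index, pmc$predicted_fsn, o)
  }
  if (!is.null(newer)) by_release <- match_release(pmc, newer)
  validated <- nrow(by_lex) > 0L || length(by_corpus) > 0L ||
    (!is.null(by_release) && by_release$match_kind != "tag_differs")
  structure(list(by_lexicon = by_lex, by_corpus = by_corpus,
                 by_release = by_release, validated = validated),
            class = "validation_result")
}
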