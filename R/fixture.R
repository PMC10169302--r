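# The fixture dialect: five small tab-separated tables that round-trip an
# ontology without any licensed release files. concepts.tsv and isa.tsv are
# mandatory; groups.tsv, chains.tsv and synonyms.tsv default to empty.

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8", check.names = TRUE)
}

#' Load an ontology from the fixture dialect
#'
#' Reads `concepts.tsv` (id, fsn, preferred_term, fully_defined, active),
#' `isa.tsv` (child, parent), and the optional `groups.tsv` (concept,
#' group_index, attribute, value), `chains.tsv` (first, second, implied) and
#' `synonyms.tsv` (concept, term) from a directory. All files are UTF-8 with
#' a header row. Validation (acyclicity, resolvable ids, parent coverage) is
#' performed by [ontology()].
#'
#' @param tables Directory containing the fixture tables.
#' @param isa_id Id to use for the is-a attribute concept.
#' @return An [ontology].
#' @seealso [write_fixture()] for the inverse.
#' @export
load_fixture <- function(tables, isa_id = ISA_DEFAULT) {
  if (!dir.exists(tables)) stop("fixture directory not found: ", tables)
  cpath <- file.path(tables, "concepts.tsv")
  ipath <- file.path(tables, "isa.tsv")
  for (p in c(cpath, ipath))
    if (!file.exists(p)) stop("missing mandatory fixture file: ", basename(p))
  concepts <- read_tsv_file(cpath)
  if (nrow(concepts) == 0L) stop("fixture concept table is empty")
  concepts$fully_defined <- tolower(concepts$fully_defined) %in% c("true", "t", "1")
  concepts$active <- tolower(concepts$active) %in% c("true", "t", "1")
  isa <- read_tsv_file(ipath)
  opt <- function(name) {
    p <- file.path(tables, name)
    if (file.exists(p)) read_tsv_file(p) else NULL
  }
  groups <- opt("groups.tsv")
  chains <- opt("chains.tsv")
  synonyms <- opt("synonyms.tsv")
  ontology(concepts, isa, groups = groups, chains = chains,
           synonyms = synonyms, isa_id = isa_id)
}

#' Write an ontology in the fixture dialect
#'
#' Emits the five fixture tables so that `load_fixture(write_fixture(o, d))`
#' reconstructs an equal ontology (same concepts, edges, groups, chains and
#' synonyms; ordering canonicalized).
#'
#' @param o An [ontology].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(o, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wf <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  cons <- o$concepts[order(o$concepts$id, method = "radix"), ]
  cons$fully_defined <- ifelse(cons$fully_defined, "true", "false")
  cons$active <- ifelse(cons$active, "true", "false")
  wf(cons, "concepts.tsv")
  isa <- o$isa_edges[order(o$isa_edges$child, o$isa_edges$parent, method = "radix"), ]
  wf(isa, "isa.tsv")
  rows <- list()
  for (cid in sort(names(o$attribute_rels), method = "radix")) {
    gl <- o$attribute_rels[[cid]]
    for (i in seq_along(gl)) {
      for (p in gl[[i]]$pairs) {
        rows[[length(rows) + 1L]] <- data.frame(
          concept = cid, group_index = i, attribute = p$attribute,
          value = p$value, stringsAsFactors = FALSE)
      }
    }
  }
  gdf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(concept = character(), group_index = integer(),
               attribute = character(), value = character())
  wf(gdf, "groups.tsv")
  wf(o$chains, "chains.tsv")
  syn <- o$synonyms[order(o$synonyms$concept, o$synonyms$term, method = "radix"), ,
                    drop = FALSE]
  wf(syn, "synonyms.tsv")
  invisible(dir)
}

#' Structural equality of two ontologies
#'
#' Compares concept tables, is-a edge sets, attribute groups, chains and
#' synonyms, all order-insensitively. Used to assert fixture round-trips.
#'
#' @param a,b [ontology] objects.
#' @return Logical.
#' @export
ontology_equal <- function(a, b) {
  norm_con <- function(o) {
    d <- o$concepts[order(o$concepts$id, method = "radix"),
                    c("id", "fsn", "preferred_term", "fully_defined", "active")]
    rownames(d) <- NULL
    d
  }
  edge_key <- function(o) sort(paste(o$isa_edges$child, o$isa_edges$parent, sep = "\x1f"))
  rel_key <- function(o) {
    ks <- vapply(sort(names(o$attribute_rels)), function(cid) {
      gl <- o$attribute_rels[[cid]]
      if (!length(gl)) return(NA_character_)
      paste(cid, paste(sort(vapply(gl, group_key, character(1L))), collapse = ";"))
    }, character(1L))
    sort(ks[!is.na(ks)])
  }
  chain_key <- function(o) sort(paste(o$chains$first, o$chains$second,
                                      o$chains$implied, sep = "\x1f"))
  syn_key <- function(o) sort(paste(o$synonyms$concept, o$synonyms$term, sep = "\x1f"))
  identical(norm_con(a), norm_con(b)) &&
    identical(edge_key(a), edge_key(b)) &&
    identical(rel_key(a), rel_key(b)) &&
    identical(chain_key(a), chain_key(b)) &&
    identical(syn_key(a), syn_key(b)) &&
    identical(a$root, b$root)
}
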