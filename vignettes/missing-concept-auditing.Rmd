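---
title: "Auditing terminologies for missing concepts via logical-definition intersection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing terminologies for missing concepts via logical-definition intersection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoaudit)
```

## The problem and the model

Large clinical terminologies such as SNOMED CT evolve continuously and
inevitably miss concepts. ontoaudit detects *candidate* missing concepts by
exploiting two ingredients the terminology already has: its is-a hierarchy
and its logical definitions.

**Hierarchy.** The is-a graph must be a DAG rooted in a single concept. In
lattice terms a healthy hierarchy gives any two concepts a unique maximal
shared lower bound and a unique minimal shared upper bound; a pair with
more than one of either is a *non-lattice pair*. Bounds here are reflexive
(a concept bounds itself), as in order theory — this matters: with strict
descendants, every parent/child pair under a branching child would be
flagged, which is not what the lattice criterion means. A non-lattice
subgraph is built from a pair's maximal common descendants (MCDs), the
minimal common ancestors (MCAs) of those MCDs, and everything on is-a paths
between them; its size is its concept count. For pairs that are non-lattice
only through multiple shared ancestors, the dual construction (MCAs of the
pair, the pair as bottom) is used.

**Definitions.** A logical definition is a set of attribute groups; a group
is a set of attribute–value pairs. We follow the grouping convention that
every is-a parent occupies its own singleton group, so `own_groups()`
always returns (number of parents) + (number of defining groups) groups.
The is-a relation is modeled as an ordinary attribute concept living in the
same hierarchy as everything else; that makes the four generality
conditions (value subsumption, attribute subsumption, both, property-chain
rewriting) one uniform relation, `pair_more_general()`.

**Derived definitions and intersection.** A concept's derived definition is
its own groups plus every strictly more general group. Because group
generality only requires each pair of the more general group to dominate
*some* pair of the other, more general groups may have fewer pairs: the
exact set of groups same-as-or-more-general than a group G is the set of
non-empty subsets of U(G), the upward closure of G's pairs under the four
conditions. `derived_groups()` materializes that closure for small inputs
and serves as the in-package oracle; `intersect_derived()` never
materializes it — for each own-group pair (G_a, G_b) it intersects the two
pair closures and keeps only the minimal (most specific) pairs, which is
exactly the group that survives reduction of the full subset families. The
equality of the two routes is a standing property test.

**Reduction.** Within a proposed definition, any group strictly more
general than a co-member is dropped (`reduce_definition()`). Groups are
first normalized by deleting pairs dominated by another pair of the same
group; this collapses the mutual-generality classes that arise because
{p} and {p, p'} (p' above p) dominate each other, making reduction
order-independent and idempotent. Should a mutual class survive
normalization (conceivable only through exotic property-chain cycles), its
lexicographically smallest member is kept, so reduction never empties a
definition.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_subgraph_size` | 10 (inclusive) | subgraphs larger than this are ignored; `inclusive = FALSE` gives a strict `<` cut for users who prefer it |
| `min_level` | 10 | candidate concepts must lie at least this many hops (longest path) below the root, excluding overly general concepts |
| `chain_depth` | 3 | cap on chained property-chain rewrites per pair; conditions 1–3 are exhausted in one step, only chains can cascade |
| `ceiling_level` | 2 | generality ceiling: intersection groups whose every value sits within this many levels of the root are discarded as vacuous (e.g. `{(is-a, root)}`) |
| `ratios` | 0.8/0.1/0.1 | naming-data split; validation and test take `floor(ratio * N)` each, training the remainder, so 361,461 concepts split 289,169/36,146/36,146 |

Levels are longest-path hop counts from the root (root = 0). The ceiling is
an extension in the spirit of the level threshold: without it, every
candidate pair "shares" content like `{(is-a, root)}`.

## Candidate filtering and proposal hygiene

A pair qualifies inside a subgraph when both members belong to it, neither
is an ancestor of the other, both are fully defined, and both meet
`min_level`. Pairs recur across overlapping subgraphs and are deduplicated
with provenance. After intersection, a proposal is dropped when its
definition is empty (nothing shared below the ceiling) or equals the
reduced definition of *any* existing concept — primitive concepts
included, a conservative reading of "already exists". Proposals with equal
definitions merge, concatenating provenance. Proposal output is sorted by a
canonical definition key, so results are independent of candidate order.
Inserting accepted proposals into the ontology and re-running proposes none
of them again (fixed-point suppression) — insertion itself is deliberately
out of scope; the tool reports for curator review.

## Naming and evaluation

Definitions serialize to one sentence per concept: pairs rendered
"AttributeName ValueFSN" (attribute tag stripped, value tag kept),
comma-separated, period-terminated. Group boundaries are flattened and the
order is canonicalized (is-a pairs first, then by attribute and value id) —
the serialization the naming task consumes shows no group delimiters, and
an unspecified order would make evaluation irreproducible. The naming model
itself is a plug-in `function(text) -> text`; fine-tuning a transformer
(summarization models of the PEGASUS/BART/T5 family are the natural choice,
typically run at learning rate 5e-5 with 1024 input tokens) happens outside
this package. Reference namers (`make_identity_namer()`,
`make_constant_namer()`, `make_template_namer()`) document the contract.

ROUGE-N is clipped n-gram recall: matching n-gram counts (clipped per
reference) over total reference n-grams. ROUGE-L is implemented as LCS
recall over the same tokenization for consistency with that recall
orientation. The tokenizer lowercases, strips parentheses and splits on
non-alphanumerics; ROUGE is sensitive to tokenization, so this is fixed and
documented rather than configurable. Exact-match counting compares names
after full normalization, tags included.

## Normalization and validation

Normalization runs, in order: semantic tag split off (kept separately,
excluded from matching) → whitespace collapse → lowercase → lemmatization →
synonym-to-preferred-term replacement against the ontology's synonym table
→ stop-word removal. The lemmatizer is a contract (`function(token) ->
lemma`); the default is rule-based (a few irregulars plus idempotent
suffix rules) so results do not depend on an external NLP stack. Synonym
replacement scans longest-first, left-to-right, in a single pass; map
entries that would break idempotence (a replacement containing another
key) are dropped up front. The pipeline is idempotent by construction and
by property test. It is deliberately not a semantic matcher: "Closure of
fistula of sclera" and "Closure of scleral fistula" normalize differently
— a known limitation, asserted as such in the tests.

Three matchers consume normalized names. The lexicon matcher compares
token sequences against atom tables (a minimal TSV dialect, or
MRCONSO-style RRF with an English filter). The corpus matcher indexes the
base noun phrases of titles/abstracts in an inverted index keyed by joined
tokens and requires whole-phrase equality, so a name occurring only inside
a longer phrase ("thoracic artery" inside "fetal thoracic artery") does not
validate. The chunker is pluggable; the default splits on closed-class
words — an approximation of a part-of-speech chunker that handles
title-style text, not a parser. The release matcher compares normalized FSN
(tag included) and definition keys against a newer release; a name hit
whose semantic tag differs is recorded as `tag_differs` but never counted
as validated.

## The synthetic generator

`random_ontology()` emulates the structural features the pipeline depends
on: a rooted is-a DAG with occasional multi-parent concepts, a small
attribute hierarchy, grouped attribute relationships, a fully-defined
fraction, and optional property chains — deterministically per seed. It
does not emulate SNOMED's scale, tag system, or lexical distribution, so
green tests certify algorithmic correctness, not real-release recall.
`plant_missing_concept()` grafts, per plant: a padding chain (sized from
`min_level`), an unrelated fully defined pair (A, B) sharing two children
(making (A, B) a size-4 non-lattice subgraph), and attribute values meeting
at a fresh common ancestor deep enough to clear the ceiling. The planted
definition is computed at construction by `intersect_derived()` itself and
checked to be unique, so recovery is guaranteed identifiable by
construction rather than by luck; the `unpruned` variant contains the
concept and exercises suppression. Value and concept branches are kept
disjoint so cross-group intersections reduce to root-level groups that the
ceiling removes.

## Numerical and degenerate-input choices

Everything is exact set algebra on strings — no floating-point tolerances
except trivial ones in test comparisons. Ties are broken by radix-sorted
canonical keys (pair, group, definition, subgraph identity), which is also
what makes stage outputs byte-identical across runs. Degenerate inputs:
the root's definition may be empty (flagged, never serialized); empty
intersections are legal results; unknown ids, cycles, orphans and dangling
references fail loudly at load with the offending items named. Splits
require at least 10 items. The RF2 reader defaults to inferred
relationships, treats relationship group 0 as ungrouped (each row its own
singleton group; `group0 = "merge"` available since the convention is not
universal), and lacking a language refset takes the first synonym as the
preferred term.

## Problem sizes used in the checks

Property tests run on generated ontologies of 20–100 concepts, 20 seeds
per property, with closure-oracle comparisons restricted to shallow
single-pair-group fixtures where the subset families stay materializable
(the direct intersection handles the deep cases those oracles cannot).
Planted-recovery runs use 30/50/100-concept bases. These sizes exercise
every code path — multi-parent diamonds, duplicate subgraphs, chain
rewrites — while keeping the whole suite in the minutes range; the
algorithms themselves are the ones a full release would use, with
`enumerate_subgraphs()` being the only stage whose all-pairs screening
would need the cited large-scale detection machinery on a real release.

## Known limitations

Property-chain generality is applied as stated (exact value match in the
modified concept's own definition); compositions emerge only through
repeated rewriting, and transitivity of the generality relation is neither
assumed nor exploited when chains are involved. The default chunker and
lemmatizer are deliberately simple contracts; for production validation,
plug in a POS-based chunker and a dictionary lemmatizer. The release
matcher assumes a shared identifier space between releases. No
description-logic reasoning is performed beyond the four conditions.
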