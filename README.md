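# ontoaudit

Quality-assurance tooling for SNOMED CT-style terminologies: it finds
*potential missing concepts* and proposes machine-readable logical
definitions for them, for ontology curators and terminology-QA researchers
who need candidate concepts with definitions rather than bare name strings.

## The method

In a well-formed concept hierarchy (a lattice), any two concepts have a
unique maximal shared descendant and a unique minimal shared ancestor. A
**non-lattice pair** violates that — e.g. *Neoplasm of vulva* and *Disorder
of Bartholin's gland* share two maximal common descendants (the benign and
the malignant Bartholin-gland neoplasm). Such structures often signal a
missing intermediate concept.

Every concept carries a logical definition: a set of **attribute groups**,
each a set of attribute–value pairs (r, v); every is-a parent counts as its
own singleton group. A pair (r₂, v₂) is *more general than* (r₁, v₁) when

1. r₁ = r₂ and v₁ *is-a* v₂; or
2. r₁ *is-a* r₂ and v₁ = v₂; or
3. r₁ *is-a* r₂ and v₁ *is-a* v₂; or
4. v₁'s own definition contains (r_b, v₂) and a property chain
   r_a ∘ r_b ⊑ r₂ exists with r₁ = r_a or r₁ *is-a* r_a
   (e.g. *Causative agent* ∘ *Is modification of* ⊑ *Causative agent*).

A group G₂ is more general than G₁ (G₂ ≠ G₁) when every pair of G₂ is the
same as or more general than some pair of G₁. A concept's **derived
definition** is its own groups plus all more-general groups.

The pipeline: enumerate non-lattice subgraphs (size ≤ 10); keep
**candidate pairs** — unrelated, fully defined, level ≥ 10 concepts inside
one subgraph; intersect each pair's derived definitions and reduce the
result (drop groups more general than a co-member); drop definitions an
existing concept already has; deduplicate. Each survivor is a *potential
missing concept* with a full logical definition. Definitions serialize to
sentences ("Is a Product containing glycoside (product), Has active
ingredient Digoxin (substance).") for any pluggable text→text naming model,
whose output is scored with ROUGE-1/2/L and validated against lexicon atom
tables (UMLS MRCONSO-style), base-noun-phrase indexes of document corpora,
and newer terminology releases.

## Worked example

```r
library(ontoaudit)
o <- make_nonlattice_fixture()          # the vulva/Bartholin non-lattice example
a <- concept_by_fsn(o, "Neoplasm of vulva (disorder)")
b <- concept_by_fsn(o, "Disorder of Bartholin's gland (disorder)")
build_subgraph(o, a, b)
#> <non-lattice subgraph of size 6>
#>   seed pair: disorder_bartholin, neoplasm_vulva
#>   MCAs: disorder_bartholin, neoplasm_vulva
#>   MCDs: benign_neoplasm_bartholin, malignant_neoplasm_bartholin
```

The pair shares **two** maximal common descendants and the subgraph has
**six** concepts (the pair, the two shared descendants, and the benign and
malignant vulval neoplasms in between) — a structural anomaly. Proposing:

```r
cands <- generate_candidates(o, enumerate_subgraphs(o, 10), min_level = 10)
props <- propose(o, cands)
cat(proposals_report(o, props), sep = "\n")
#> Proposal 1
#>   Group 0  {(Finding site (attribute), "Vulval structure (body structure)")}
#>   Group 1  {(Is a (attribute), "Disorder of vulva (disorder)")}
#>   from candidate pair(s): (Disorder of Bartholin's gland (disorder), Neoplasm of vulva (disorder))
```

The proposed concept — a disorder of the vulva localized to the vulval
structure, generalizing both members of the pair — is exactly the common
content of the pair's derived definitions after reduction. Serialized for a
naming model:

```r
serialize_definition(o, props[[1]]$definition)
#> [1] "Is a Disorder of vulva (disorder), Finding site Vulval structure (body structure)."
```

On synthetic ontologies the whole loop is verifiable: `random_ontology()`
plus `plant_missing_concept()` grafts a concept that is removable and
uniquely identifiable, and `propose()` recovers its definition exactly
(and never re-proposes it once the concept exists — suppression).

The stage runners `run_audit()`, `run_propose()`, `run_name_data()` and
`run_validate()` write JSON/TSV artifacts for a whole ontology given an
`audit_config()`; `inst/scripts/ontoaudit.R` wraps them for the shell.

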