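---
title: "Methods: building and validating the matrisome diseasome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating the matrisome diseasome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmdiseasome)
```

## The model

The matrisome diseasome is a bipartite network: gene nodes on one side,
disease nodes on the other, one edge per unique (gene, disease) association
gathered from heterogeneous sources (clinical-variant records, curated
causal-gene sets, PheWAS hits, rare-disease extracts). Everything the
package computes is a deterministic function of that edge set and of the
record tables feeding it: degree tables, matrisome composition fractions,
category counts, substitution matrices, repurposing triads. There is no
statistical model being fit — the scientific content is in the curation
rules, and the engineering burden is making every rule explicit, total, and
conservation-checked.

### Identity and normalization

Gene symbols are uppercased and trimmed; no alias resolution is attempted,
because none of the source dialects documents one and silent synonym
merging would change counts invisibly. Disease names are lowercased,
trimmed and whitespace-collapsed, and that normalized string *is* the
disease identity across sources. This is the weakest link of any
name-keyed merge — "Stickler syndrome" and "Stickler syndrome type 1" stay
distinct — and we deliberately surface it rather than hide it behind a
fuzzy matcher: ontology mapping is out of scope, and exact normalized-name
identity makes every downstream count auditable.

### Load accounting

Every reader returns a load report with the invariant
`rows_in = records_out + dropped + rejected`, where `dropped` splits into
blank-mandatory-field rows and exact-duplicate rows, and `rejected` covers
invalid values (p-values outside (0, 1], self-interacting PPI pairs).
Because a "polymorphism count" can mean table rows or unique variant ids,
the variant reader reports both rather than choosing.

## Variant analysis

The protein-change parser is a total function with three tagged outcomes:
`missense`, `not_missense` (with a subtype: synonymous, frameshift,
deletion, duplication, insertion, extension, stop gain, stop lost) and
`unparseable`. It accepts `p.`-prefixed, parenthesized and bare forms,
case-insensitive three-letter codes and strict uppercase one-letter codes;
ambiguity codes other than `X` are unparseable, since the inputs use
standard residues only. Parse → render → parse is the identity on missense
outcomes, which the property tests exercise on generated notation.

Substitution matrices count one increment per missense record over the
22-residue alphabet (20 standard + unknown + stop), so the grand total
equals the number of contributing records and the diagonal is structurally
zero. Stop gains are excluded by default — the matrix describes
residue-for-residue substitution — with `include_stop_gain = TRUE`
counting them in the `Ter` column for users who want the broader reading.
Rankings break ties alphabetically by three-letter code so that reports
are reproducible byte for byte.

For collagens, the triplet-slot helper maps a protein coordinate to its
position in the Gly-X-Y repeat. The glycine slot is configurable (default
slot 1, i.e. glycine written first in the motif) because the motif can
equally be framed with glycine third; the `offset` argument aligns helices
whose first residue is not triplet-initial. The substitution-matrix gene
filter defaults to the catalog's collagen category, matching the question
the matrix is usually asked of; `"all"` widens it to the whole matrisome.

## Disease categorization

Diseases are assigned to three replaceable term lists — A
(connective-tissue), B (common), C (age-related) — by case-insensitive
substring matching on the normalized name, with no word-boundary
requirement (so "cancerous" matches "cancer"; this is the documented cost
of plain substring semantics). A disease matching several lists receives
all of them, which is what produces the overlap labels `A_C`, `B_C`,
`A_B_C`; unmatched diseases are retained as `uncategorized` so that label
counts always partition the input. The shipped default lists cover
well-known exemplars of each group; term curation is a judgment call, so
the lists are plain data a user can replace wholesale via `load_terms()`.
Counting supports two weightings because both questions are natural: per
unique disease, or per gene–disease association.

## Network stage

The bipartite graph is igraph-backed with typed sides. Degree tables obey
the handshake identity (each side's degrees sum to the edge count), which
the pipeline re-asserts at report time along with the reader conservation
identities — cheap invariants that catch merge bugs where they happen.

Shared-disease clustering of genes uses average-linkage agglomerative
clustering on the Jaccard *distance* between disease neighbor sets, cut at
distance `1 − cut`. Average linkage was chosen over single linkage for
interpretability (single linkage chains through weak bridges) while
remaining deterministic; genes are processed in sorted order so the result
is invariant to input ordering. On well-separated instances — within-block
similarity at or above the cut, between-block similarity zero — the result
provably coincides with thresholding pairwise Jaccard similarity and
taking connected components, and the test suite checks that equivalence
against a brute-force oracle on small planted instances. On instances with
intermediate between-block similarity the two constructions can differ;
the cut (default 0.5) is an analysis choice, not an estimate.

## PheWAS and repurposing

All significance thresholds use strict `<`, stated once and applied
everywhere; this makes `filter_by_p` monotone in `alpha` and `top_hits`
nested in `n`, both property-tested. Display transforms use −log10(p);
p = 0 is impossible by reader contract, so no clipping policy exists. The
repurposing join keys on the gene symbol: one candidate per (drug, gene)
pair carrying the union of that gene's diseases. Association records carry
no SNP id, so the stricter SNP-mediated linkage is offered as an optional
`snp_universe` argument — drug links whose SNP id is absent from the
supplied universe (e.g. the SNPs seen in the variant or PheWAS tables) are
dropped and counted.

## The synthetic-data generator

The generator emulates the *statistical shape* of the seven input
dialects, with every stochastic choice drawn from one seeded stream and a
manifest recording the **realized** (not expected) value of every quantity
the pipeline computes. Counting stages are deterministic, so ground-truth
recovery is exact equality, not a statistical tolerance.

Defaults, fixed once as the package's study conditions:

| knob | default | rationale |
|---|---|---|
| gene universe | 2000 | desk-scale stand-in for the coding genome |
| matrisome fraction | 0.5 | a ~1000-gene catalog, the scale of the published 1027-gene matrisome |
| category proportions | 44/195/35/171/238/344 of 1027 | the published catalog composition |
| variants | 5000, 70% missense | enough mass in every substitution cell |
| substitution distribution | Gly ref mass 0.6, Gly→Arg 0.25 | the glycine-dominant collagen signature |
| diseases | 800; term insertion A .20 / B .25 / C .40 | age-related category predominant, as in real association mixes |
| PheWAS | 10000 hits, p log-uniform over (1e-12, 1) | spans genome-wide to null significance |
| associations / drugs / PPI / rare | 3000 / 150 / 600 (40% matrisome–matrisome) / 400 | keeps every branch non-trivially populated |

Disease names embed category terms by controlled insertion into otherwise
neutral base names, so category membership is known by construction; the
default term lists contain no term that is a substring of another list's
term, so insertion events and realized memberships coincide exactly.

What passing these tests shows: every counting, filtering, joining and
ranking stage is exact on data whose truth is known. What it does not
show: robustness to real-world messiness the generator does not emulate —
synonymous gene aliases, near-duplicate disease names, ontology drift
between sources, LD structure among SNPs, or biased ascertainment of
variants. Real headline counts are snapshots of living databases and are
version-dependent by nature; the package reproduces procedures, and its
fixed expectations come from small curated fixtures (the Stickler and
Ullrich collagen lists, the nine-drug PLG panel, the five-gene repurposing
set) whose counts are stable. In those fixtures the gene, drug and SNP
identifiers are the curated published ones, while the filler indication
names attached to the repurposing genes are labelled synthetic.

## Numerical and degenerate-input choices

Percentages are rounded half-up to one decimal (333/1027 → 32.4), not
banker's-rounded. Empty inputs are ordinary values: empty filters, all-zero
matrices and all-zero reports, never errors — with two exceptions that are
genuine configuration faults (an empty matrisome catalog, clustering an
empty graph). Errors carry classed conditions (`ecm_format_error`,
`ecm_conflict_error`, `ecm_config_error`, `ecm_domain_error`,
`ecm_stage_error`) and the pipeline wraps failures with the stage name.

Problem sizes in the test suite: module tests run on inputs of tens to
hundreds of rows; the end-to-end ground-truth test runs the full default
generator (2000/5000/10000/800), which the package treats as its reference
study size.

## Interface decision

The package is a library, not a shell tool: its users drive it from R, so
the orchestration surface is `run_pipeline()` plus the exported stage
functions, and no command-line wrapper is shipped. Export helpers
(`write_diseasome()`, `write_substitution_matrix()`,
`write_association_table()`, `write_load_report()`) cover the artifact
formats a downstream consumer needs.

## Known limitations

- Name-keyed disease identity (no ontology reconciliation) under-merges
  synonymous disease labels and over-splits subtype spellings.
- Substring categorization inherits every false positive of substring
  semantics; term lists are data, not a classifier.
- The clustering cut is a tunable with no internal model selection.
- DNA/cDNA-level variant notation is out of scope; only protein-level
  changes are parsed.
- The generator plants independent draws; it does not emulate correlated
  structure (LD, pleiotropy beyond shared names, database redundancy).
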