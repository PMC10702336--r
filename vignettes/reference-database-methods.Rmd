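---
title: "Building and benchmarking harmonized CO1 reference databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and benchmarking harmonized CO1 reference databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcoderef)
```

This vignette explains the models and procedures behind `barcoderef`: what
each stage assumes, which parameters matter, how the numerical edge cases
are resolved, and what the synthetic fixtures do and do not demonstrate
about real data.

## Why harmonize at all

A reference database maps barcode sequences to taxon names, and every
downstream taxa list inherits its naming decisions. Public sources are
internally inconsistent: the same species may appear under its accepted
name in one source and under a synonym in another; the same genus name may
denote an animal in one kingdom and a plant in another (a homonym); many
names carry open-nomenclature qualifiers that flag the identification as
uncertain. Hierarchical classifiers compare names rank by rank, so a
synonym and its accepted name look like two different taxa and depress
bootstrap support. Harmonization against a single backbone taxonomy (GBIF
Backbone or NCBI Taxonomy style) removes this artificial signal. It is a
trade-off, not a free lunch: a unitary backbone is an editorial decision,
and users who prefer the sources' own opinions can run the pipeline
unmapped (`taxonomy_none()` + `unmapped = TRUE`), accepting that Metazoa,
Animalia and a missing kingdom will then coexist.

## The backbone store

`import_backbone()` reads either dialect into one node table
(id, canonical name, rank, status, parent, accepted-id) with a hash index
on lower-cased names, so lookup cost does not depend on dump size or row
order. Design points:

* **Synonym chains.** Sources normally point a synonym directly at its
  accepted name, but chains do occur in merged dumps. `accepted_of()`
  follows `accepted_id` transitively with a depth bound of 10 and treats a
  cycle or a dangling reference as an error naming the offending node —
  silent truncation would mislabel records.
* **Homonyms.** `tax_lookup()` narrows equal-named candidates by rank
  hint, then by lineage context (a candidate whose ancestry contains the
  record's own higher taxon wins), then by a user-supplied homonym list
  (name, rank, resolving kingdom). Candidates that remain plural are
  returned flagged ambiguous rather than guessed at; during harmonization
  such a name is skipped and the record falls back to its next higher
  taxon, which is deterministic and conservative.
* **Rank projection.** Only the seven standard ranks (kingdom to species)
  are representable in the output; `lineage_of()` walks the parent chain
  and skips subfamilies, tribes and other intermediate ranks. This is what
  downstream classifier formats expect.

## Name cleaning

Digits are erased everywhere. The first open-nomenclature token
(`aff.`, `cf.`, `cff.`, `sp.`, `spp.`, `nr.`, `prope`, `gr.`, `s.l.`,
`s.s.`, `indet.`, `?` — extensible via a one-token-per-line file) and
*everything after it* are dropped: in "Apis cf. mellifera" the epithet is
exactly the part the identifier was unsure about, so the certain remainder
is "Apis". Matching is case-insensitive and tolerant of a missing trailing
period. Hybrid signs (×) and stray punctuation are stripped; the cleaned
name contains only letters, spaces and hyphens and may legitimately end up
empty. Cleaning is idempotent, which the test suite asserts by property.

A cleaned name that now resolves at genus rank (the "cf." case) is tagged
`action = "exact"` with genus resolution: cleaning happens *before*
harmonization, and `rank_fallback` is reserved for the separate mechanism
of walking a record's raw lineage upward when a name is missing from the
backbone. Names met during that upward walk are looked up as the source
printed them, without re-cleaning; source lineages are almost always bare
higher-taxon names, and re-cleaning them would only mask malformed source
data.

## Harmonization actions

For each record, in order: (1) exact/accepted match → `exact`; (2)
synonym match → replaced by the accepted name (`synonym_replaced`), unless
`allow_synonyms` is set, in which case the synonym remains the displayed
name at its own rank while the higher ranks still come from the accepted
node's ancestry — classifiers need consistent higher ranks even when the
user insists on the source's epithet; (3) no match → walk the raw lineage
upward, first backbone hit truncates the lineage there
(`rank_fallback`); (4) nothing matches → `unmatched`, kept with an empty
lineage so that the minimal-rank filter (not a silent drop) decides its
fate. Record count is conserved through the stage, and the comparison
table aggregates every (provided name, accepted name, action) triple with
its record count — a lightweight reconciliation report.

## Filters

`filter_config()` defaults: `max_N = 0` (only literal `N` counts; the
total of all IUPAC ambiguity codes has its own optional bound),
`min_length = 400`, `max_length = 2000` bp — brackets for a usable CO1
Folmer fragment; `min_rank` off by default. Rules are pure predicates
applied in a fixed order (N, length, ambiguity, rank) and the first
failing rule names the drop reason, so filter outcomes are order-free and
auditable.

The translation check translates the three forward frames under NCBI
genetic code 5 (invertebrate mitochondrial — the appropriate code for
animal CO1; configurable) and demands at least one stop-free frame,
ignoring a trailing partial codon; ambiguous codons translate to X, never
to a stop, so Ns cannot cause false failures. Reverse-complement frames
are not checked because barcodes are deposited in coding orientation. The
default is to warn and keep, since a stop may indicate either a NUMT or an
honest frameshift in an otherwise informative record; `drop` is one flag
away.

Geography: country text is looked up in a gazetteer
(country → continent → biogeographic realm); coordinates are tested
against polygons with a boundary-inclusive crossing-number test in
lon/lat WGS84 — the only coordinate reference system assumed, matching
field practice. Text and point labels are unioned. When a region filter is
active, records with no location information at all are dropped: their
provenance cannot be established, and keeping them would silently widen
the requested scope. Custom regions load from GeoJSON (Polygon /
MultiPolygon, outer rings).

## Dereplication

Identity means byte-identical sequence strings — no trimming, no
substring matching; similarity clustering is a downstream concern. Label
conflicts inside a cluster resolve by a three-step cascade:

1. If all distinct lineages are pairwise *consistent* (equal at every rank
   both have filled), they differ only in resolution and the deepest one
   wins. Consistency is checked over full lineages; any contradiction at
   any rank routes to step 2.
2. Otherwise the lineage carried by the most records wins, provided that
   maximum is unique. Majority is computed over whole lineages, never per
   rank — per-rank voting could assemble a chimera no record ever claimed.
   A more abundant but shallower lineage beats a rarer, deeper one here:
   step 1 is only about resolution, and abundance is the tie-breaker the
   cascade trusts once labels genuinely disagree.
3. A tied maximum falls back to the lowest common ancestor of the tied
   lineages — the deepest statement all of them support.

The representative record is the lexicographically smallest id within the
winning group, which (together with first-appearance cluster ordering)
makes output independent of input order. The suite checks the cascade
against a hand-coded decision-table oracle over every configuration of up
to six members from up to three distinct lineages.

## The THID benchmark

The top-hit identity distribution answers "how well does this reference
database cover these queries?". Each query is aligned globally against
*every* reference sequence — an exact scan; the pruning heuristics of
usearch-style tools (`maxaccepts`/`maxrejects`) are deliberately not
reproduced, since at package scale exactness is affordable and guarantees
the true best hit. The best hit at or above the identity threshold
(default 0.7) is kept; ties go to the lexicographically smallest reference
id.

Alignment is affine-gap global (Gotoh) in C++: match +2, mismatch −4, gap
open 20, gap extend 2 — the customary nucleotide settings of the
benchmark tools this mirrors; a gap of length L costs `open + extend·L`.
Identity is 100 × matching columns / alignment columns with terminal gap
columns excluded, so a short query inside a longer reference is not
penalized for the overhang. On score ties the traceback prefers the
diagonal, favouring matches. Identities are binned by half-up rounding to
integer percent (the convention had to be fixed somehow; half-up is the
least surprising for percentages). Histogram mass always equals the
number of queries with a hit.

`dense_ranks()` summarizes several databases at 100% identity: fewest
hits → rank 1, ties share their minimum rank. `subsample_cross_coverage()`
draws seeded subsamples from each database and queries them against every
*other* database, tallying hits at 100/99/98% — a symmetric measure of
how much of one database another already contains. The package seeds this
through an isolated RNG stream so benchmarks never disturb the caller's
random state.

## The fixture generator

`generate_fixtures()` is first-class, tested code, not a throwaway: it
emulates the study conditions end to end. Defaults: 60 species in a
two-kingdom backbone (~124 nodes), 10% of species with a synonym, 2
homonym genus names duplicated under Plantae, 30 records per source
dialect; per record, 10% open-nomenclature decoration, 5% unknown genus
(expected rank fallback), 2% fabricated lineage (expected unmatched), 30%
of GBOL rows with a missing order cell, 20% duplicate sequences
concentrated on few species so real clusters form, 5% with one ambiguous
base; 658 bp sequences built codon-wise without stops under code 5, so
translation-plausible like real barcodes. Queries are copies of reference
sequences with k planted substitutions at distinct positions, so their
true identity is exactly (L−k)/L and the expected histogram bin is known
in advance; 50 queries cycling k ∈ {0, 1, 3, 5, 10, 30} by default.
Everything derives from one seed and regenerates byte-identically.

What the fixtures do **not** emulate: phylogenetically realistic sequence
evolution (species are random coding sequences, far apart), indel-rich
queries (substitution-only by design, so truth is closed-form), real
GenBank lineage depth (fixtures use one clade line with the kingdom
first), BOLD's private records, or the sheer scale and annotation error
rate of live snapshots. Passing tests therefore demonstrate the
correctness of the machinery — parsing, cleaning, mapping, filtering,
clustering, searching — not the biological quality of any real source.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberate desk scale:
90-record snapshots, 124-node backbones, 100×100 and 60×60
query-by-reference scans at 100–150 bp, 50 small fixtures for the
conservation property suite. These sizes exercise every code path while
keeping a full run in the low minutes on one core; all of them are
parameters, and the same code runs unchanged on larger inputs.

Degenerate inputs are defined, not accidental: empty backbone files give
an empty store; records with empty cleaned names start their harmonization
at the lineage walk; an empty lineage has `NA` resolution and fails any
`min_rank`; histograms of hitless query sets are empty with zero mass;
boundary points count as inside polygons; `min_length` and the 0.7
identity threshold are inclusive bounds.

## Known limitations

* One marker (CO1) and one record grammar per source dialect; GBOL column
  layouts vary between releases, and only the layout the generator fixes
  is parsed out of the box.
* ESRI shapefiles are not read; custom regions must be GeoJSON.
* No taxon-concept (sensu) resolution — source databases do not carry the
  information; the comparison file is the practical approximation.
* The aligner is quadratic per pair; the benchmark is exact, not
  heuristic, and meant for curated query sets rather than million-read
  runs.
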