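---
title: "Proteoform-centric pathway matching: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteoform-centric pathway matching: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopath)
```

This vignette explains the models implemented in `proteopath`, the
parameters that govern them, and the design decisions taken where more than
one reasonable reading existed. It is the reference for *why* the package
behaves as it does; the README shows *how* to run it.

## The proteoform model

A proteoform is a protein accession, an optional isoform number (absent
means the canonical isoform), and a **multiset** of PTMs, each a 5-digit
PSI-MOD type plus a 1-based site on the UniProt sequence or an unknown
marker. Two choices deserve comment:

* **Multiset, not set.** Duplicate (type, site) pairs are preserved.
  Reference annotation may legitimately list one modification per subunit
  occurrence, and collapsing duplicates would silently change STRICT
  matching, which compares PTM counts.
* **Opaque accessions.** No UniProt checksum validation is performed, so
  synthetic knowledge bases can use arbitrary accession tokens.

The text notation is `ACC[-n];TYPE:SITE,...`. The first `;` always
terminates the accession; between PTM tokens both `,` and `;` are accepted
on input because both dialects occur in practice, while the serializer
always emits `,`. Serialization orders PTMs by (type, site, unknown last),
which makes string equality coincide with proteoform equality and gives
every "first PTM" reference below a deterministic meaning. Unknown sites
parse from `?` or `null` and serialize as `?`. Zero, negative and
fractional sites are rejected at construction — they are not valid sequence
coordinates — and a non-5-digit type is rejected likewise. Nothing forbids
an isoform suffix to combine with unknown sites; both are permitted.

## Site comparison and the matching stringencies

Two known sites match when `|input - ref| <= margin`. The margin is
**inclusive** and **zero is allowed**: the worked coordinate examples the
semantics derive from treat a distance exactly equal to the margin as a
match and use margin 0 throughout, so those two properties are adopted over
stricter prose readings ("below the margin", "positive margin"). Unknown
input sites match anything (the input is less specific than the reference);
known input sites match unknown reference sites (`NA` on load, or a legacy
`-1` sentinel which the knowledge-base reader normalizes to unknown).
Invalid raw input coordinates (≤ 0) never match, even inside the margin:
the comparison is a total function that returns `FALSE` rather than an
error, so corrupt coordinates in bulk input degrade to non-matches instead
of aborting a run.

The eight stringencies quantify over the two PTM multisets after requiring
accession + isoform identity. Points that were genuinely open:

* **STRICT is a bijection.** "Same number of PTMs and every PTM matches"
  is read as a one-to-one assignment. At exact-site semantics this reduces
  to comparing the site multisets and, per site, checking the type
  multisets with wildcard absorption — no backtracking search is needed in
  the implementation; the test oracle nevertheless enumerates permutations
  to stay independent.
* **Vacuous truth.** SUBSET with an unmodified input, SUPERSET with an
  unmodified reference, and STRICT with two empty PTM sets are all `TRUE`.
  ONE is the exception: it asserts the *existence* of a matching input PTM
  and is therefore `FALSE` for an input without PTMs.
* **ONE quantifies over the input only.** The symmetric reading (also
  counting reference→input hits) would make ONE equivalent to "not
  disjoint"; the implemented reading keeps ONE ≤ SUBSET on single-PTM
  inputs, the equivalence that makes single-phosphosite queries behave
  identically under both.
* **The `00000` wildcard is honored on the input side only.** It is a
  query device; a reference proteoform carrying `00000` is treated as a
  literal type.

These choices produce the containment lattice the tests verify
exhaustively against a brute-force oracle: STRICT ⟹ SUBSET ∧ SUPERSET,
SUBSET ⟹ ONE (given ≥ 1 input PTM), every typed result implies its
no-types counterpart, and ACCESSION contains everything.

## Input modelling

Gene names and variant identifiers resolve through exact lookup tables;
unmapped tokens are reported as unresolved, never guessed. Peptides map by
**exact substring** search over the knowledge base's FASTA — no I/L
equivalence, no missed-cleavage expansion — because approximate peptide
indexing is a solved problem elsewhere and exactness keeps the contract
testable. A modified peptide occurring at start `s` turns each
peptide-relative PTM position `q` into protein site `s + q - 1`; every
occurrence yields a candidate proteoform and the matching engine decides
which candidates correspond to annotated proteoforms. Ambiguity always
fans out: a variant or peptide mapping several accessions contributes all
of them.

## Overrepresentation analysis

Each scored pathway gets a right-tail binomial p-value with

* `p` — the pathway's distinct participants over the database total, both
  at the active granularity (proteoform-centric when the input kind carries
  PTM information, protein-centric otherwise);
* `k` — distinct matched input entities in the pathway (an entity in many
  reactions of one pathway counts once; the trial is per entity);
* `n` — the number of **distinct resolved input entities present in the
  knowledge-base universe**. Raw line counts would make p-values depend on
  unmapped junk lines; the alternative reading is still available as
  `analyse_pathways(..., n_definition = "raw")`.

Pathway totals and matches use the pathway's **reaction closure**: its own
reactions plus those of all descendant subpathways. Ancestors inherit the
matches found in their children (hierarchical search listing), so their
totals must cover the same reaction set or `k ≤ entities_total` would not
hold. All pathways with at least one match are scored, including top-level
ones. The tail probability is computed through the binomial survival
function, not `1 - pbinom(...)`, so small p-values keep full relative
precision; BH adjustment is the standard step-up procedure applied to the
emitted p-value vector.

## Networks

Edges are recorded **per reaction**: one row per unordered pair of distinct
projected identities, annotated with each endpoint's role and complex/set
context in that reaction (several roles of one participant in one reaction
join with `|`). Degree and internal/external membership collapse this
multiplicity to distinct neighbors. This multigraph-with-collapse
convention preserves per-reaction annotation while keeping degree
distributions comparable across granularities. All role pairs connect —
co-participation is the criterion — and complex/set membership is
annotation only, not an edge-generating mechanism. At gene granularity an
accession without a gene mapping keeps its accession as identity, with a
warning. A node is `canonical` when every proteoform projecting onto it is
an unmodified canonical isoform, `specific` otherwise; at proteoform
granularity this reduces to "no isoform and no PTMs".

## The synthetic knowledge-base generator

The generator emulates the structure the matcher needs: hierarchical
pathways (default 60, hierarchy depth ≤ 3) over reactions (default 400,
2–6 participants) whose participants are proteoforms with roles and
complex/set context. Every protein contributes its unmodified canonical
proteoform; a `ptm_fraction` (default 0.6) of proteins carries 1–3
modified forms of 1–3 PTMs each, types drawn from a small PSI-MOD
catalogue that includes the three phospho types, and an
`isoform_fraction` (default 0.1) contributes a second, unmodified isoform.
Sequences are random 120–400-residue strings; PTM sites are drawn within
`[1, length - 10]` so the +5 shifts of the sensitivity experiment never
leave the sequence. All sites are known: the experiment's contrast between
STRICT (exact sites) and margin-based types would be diluted by unknown
sites, which match everything.

What the generator does **not** emulate: realistic amino-acid composition
or homology (peptides map almost uniquely), correlated PTM patterns within
protein families, reuse of one reaction across pathways, small-molecule
participants, and the heavy-tailed pathway-size distribution of curated
databases. Passing tests therefore demonstrate correctness of the matching,
scoring and network semantics — not calibration of p-values or network
statistics on real annotation.

## The sensitivity experiment

Eligible references are modified proteoforms of proteins with **multiple**
modified proteoforms — the regime where stringency matters. Each sampled
proteoform is perturbed: the first PTM (canonical order) gets type
`00000` and site +5; a second PTM, if present, is also shifted +5. The
offset of the second shift is not independently specified anywhere; +5 is
used for symmetry with the first. A shift applied to an unknown site
leaves it unknown (the generator emits none, so the controlled experiment
is unaffected). With margin 5 the shifted sites sit exactly on the
inclusive margin, so ONE/SUBSET/SUPERSET recover the original with or
without types, while STRICT (no margin) recovers nothing — the extreme
ends of the stringency ordering the experiment is designed to exhibit.
Defaults are 10 samples of 300 proteoforms, sampled without replacement
within a sample, margin 5.

## Numerical and scale choices

Tolerances in the test suite: 1e-12 absolute for the binomial tail against
direct mass summation over a (k, n, p) grid up to n = 200; 1e-14 for BH
against the textbook procedure (pure arithmetic, so effectively exact).
Problem sizes — 1,000 random pairs for the matching-lattice check, 300
phosphosites for the One/Subset equivalence, the default generator and
experiment sizes for sensitivity — were chosen once as comfortably large
for the properties being demonstrated while keeping a full run in tens of
seconds.

## Known limitations

* Matching never crosses isoforms: `P31749-3` and `P31749` are different
  entities at every stringency, even ACCESSION.
* Peptide mapping is exact-substring only; bottom-up data with sequence
  variants or ambiguous residues will under-map.
* The variant map is a static table; no consequence prediction is
  performed.
* ORA inherits the independence assumptions of the binomial model; as with
  any first-generation method, correlated entities (complex members) can
  inflate significance. The search and network outputs are the primary
  product; the ORA is a convenience.
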