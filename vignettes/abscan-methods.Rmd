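---
title: "abscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{abscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the model behind `abscan`, the parameters that
matter, the numerical choices, and what the synthetic-data validation does
and does not establish about real repertoires.

## The canonical alignment

Antibody V domains admit a position-wise coordinate system (IMGT
numbering: positions 1–128 per chain, lettered insertion codes inside long
CDR3 loops), which makes alignment-free, position-indexed comparison
possible. `abscan` fixes a *canonical scheme*: an ordered catalogue of
(position, insertion) slots into which a numbered sequence is scattered,
producing an integer vector with 0 for every unoccupied slot.

The default scheme has 200 slots: the 128 plain positions plus 36
insertion slots at position 111 and 36 at position 112. Slot order follows
the IMGT CDR3 traversal — plain positions ascending, insertions at 111
ascending immediately after plain 111, insertions at 112 *descending*
immediately before plain 112 — so that a long CDR3 loop occupies a
contiguous run of slots and biological adjacency is preserved in the
vector. The set of canonical positions is an empirical choice (positions
common in large repertoires plus a few seen in therapeutics), and
curated position catalogues differ at the margins, so the scheme is fully
loadable from a TSV file (`load_scheme()`); the default is the mitigation
baseline, not dogma. Every scheme gets a content hash (`scheme_id`)
stamped into database manifests, and searching with a query encoded under
a different scheme is a hard error — a silent one-slot misalignment would
corrupt every identity downstream, so this is checked, never assumed.

Sequences with insertions outside the scheme (e.g. an eighth insertion at
position 81, almost certainly a sequencing or numbering artefact) cannot
be vectorized. They are *classified*, not dropped on the floor: `encode()`
returns an `unusual_sequence` marker carrying the offending keys, the
database build writes them to a FASTA sidecar, and the manifest counts
them, so `input = encoded + unusual + filtered + errors` holds exactly for
every build.

Insertion codes are stored as integer ordinals (A→1, B→2, …), not
letters, so the 111-ascending / 112-descending ordering is arithmetic in
exactly one place (the scheme constructor) rather than scattered through
the code.

## The identity model

For query `q`, target `t` and region mask `R` (a set of slots):

* **matches** — slots in `R` where both vectors carry the same non-gap
  code;
* **coverage** — slots in `R` where *at least one* vector carries a
  residue;
* **identity** = 100 · matches / coverage (0 when coverage is 0).

Counting coverage over the union of occupied slots means an indel present
in only one sequence counts as a mismatch. When both sequences have
one-sided gaps at *different* slots inside the region, a defensible
alternative would divide by the larger region length instead; the two
coincide otherwise. The union rule is what `pair_identity()` implements,
and it is isolated there and in the oracle, so changing the convention is
a two-line edit.

Modes, all orthogonal flags on `identity_options()`:

* `length_matched` (default for CDR/CDR3 region masks): the pair is only
  comparable when query and target carry the same number of residues
  within the (effective) mask. This counts *residues*, not slot spans, so
  a 15-residue CDR3 using insertion slots compares against any other
  15-residue CDR3. Non-comparable pairs report identity 0 and a
  `comparable = FALSE` flag, and never enter hit lists.
* `include_terminal_gaps` (default on): residues missing at the ends of a
  truncated sequence count as mismatches. Turning it off first removes
  masked slots outside the joint span of the two sequences
  (`trim_terminal()`), so 5′/3′ truncation is not penalised.
* `ambiguous_matches_nothing` (default on): `X` matches nothing, not even
  `X`. Ambiguity can then lower identity but never raise it.

Matches and coverage are exact integers; the percentage is formed once at
the end. Two pairs with equal rational identity therefore produce
bit-identical doubles, and ranking (identity descending, ties broken by
ascending global database row in manifest order) is exactly reproducible.
A threshold, when given, is inclusive (a hit at exactly the threshold
qualifies — "90 % or better"), and is applied inside the accumulator, so
sub-threshold rows never occupy top-N capacity.

## Search engine

`search()` is deliberately exhaustive: every row of every selected
partition is scored for every query and region, with no candidate
prefiltering of any kind. This is what buys the guarantee that the exact
closest match under the identity definition is always found — heuristic
k-mer screens (the usual approach in general-purpose protein search) can
and do miss the nearest antibody when the difference is concentrated in a
short loop. The cost model is a linear scan, which the storage layout
serves: shards are uint8 row-major matrices read in chunks
(`chunk_rows`), all queries and all regions are scored against a chunk
while it is in memory (loading data, not arithmetic, is the practical
bottleneck, so batching queries amortizes it), and per-(query, region)
accumulators hold at most `n_best` candidates so memory is bounded at any
database size.

Parallelism is by shard (`workers` forked processes), and partial results
are merged in manifest order with the same tie rule, so the output is
identical for every `chunk_rows` and `workers` setting — the test suite
asserts equality, not approximate agreement, across
`chunk_rows ∈ {1, 7, 1024}` and `workers ∈ {1, 4}`.

## Regions and the paratope

`default_regions()` returns the standard suite: the whole domain
(variable length), the three CDRs combined, and the CDR3, the latter two
length-matched. CDR boundaries are the IMGT delimitations (CDR1 27–38,
CDR2 56–65, CDR3 105–117 plus all CDR3 insertion slots); they are
arguments, not hard-coded, since numbering-scheme conventions differ.

`extract_paratope()` derives a region from a solved antibody–antigen
complex: all antibody residues with any atom within a distance cutoff
(default 4.5 Å, the conventional contact criterion) of any antigen atom.
By default only heavy (non-hydrogen) atoms are considered — deposited
structures rarely include hydrogens, so an all-atom criterion would
behave inconsistently across structures; `atoms = "all"` and
`atoms = "sidechain"` are available. Chain residues are mapped to IMGT
keys by numbering the chain sequence (through the numbering backend) and
pairing residues in order; structure residues beyond the numbered domain
(tags, constant-domain overhang) are ignored with a warning. Output is
monotone in the cutoff by construction and is validated against an
independent all-pairs distance computation in the tests.

## Numbering backends

Numbering itself (an HMM alignment against germline profiles) is a
solved problem with dedicated external tools and is out of scope. The
package defines the backend *contract* and ships a file-based fixture
backend (`fixture_backend()`): exact lookup of the amino-acid string in a
pre-numbered table. This keeps the entire pipeline — including structure
paratope mapping — runnable and testable with no external tool. An
adapter to an ANARCI-compatible command-line tool fits the same contract
(sequence string in, numbered residues out) but is intentionally not
required anywhere.

## The database store

A database directory holds: uint8 shard matrices (`.bin`, row-major,
dimensions in the manifest), int32 index-pair files (`.idx`, one
(metadata file, row) pair per shard row, 0-based), the original metadata
CSVs, the unusual-sequence FASTA, a per-rule filter report, the scheme
definition, and a plain-text manifest with md5 content hashes. Plain text
plus raw fixed-width binary keeps the format language-neutral and
memory-mappable and makes integrity checking trivial; `load_database()`
verifies existence, sizes and hashes before anything is read.

Reduction filters (for building smaller database variants) apply in a
fixed order — ambiguous residues, minimum redundancy (default 5 when
enabled), residue required at position 1, exact deduplication — and
every input is accounted to exactly one outcome, so conservation is
checkable per build. Redundancy comes from the metadata `redundancy`
column when present (the usual case: repertoire pipelines annotate it),
else from exact-duplicate counting within the build input. Duplicates
across independent input files are treated as distinct records unless
`deduplicate` is enabled.

The default `shard_size` is 2^20 rows (~200 MB per shard under the
default scheme): large enough that scan overhead is negligible, small
enough to bound per-chunk memory; it is configurable and has no effect on
results.

## Synthetic repertoires and what validation shows

`generate_repertoire()` emulates an IMGT-numbered repertoire: a framework
template over positions 1–104/118–128 (with a few germline-style gaps),
per-position residue frequency profiles (strongly concentrated at
framework positions, flat-ish in the CDRs) from which mutations are
drawn, a uniformly sampled CDR3 length occupying the canonical insertion
slots, independent per-position mutation (default 2 % framework, 5× that
in the CDR3), optional ambiguous residues, and AIRR-style metadata
(species, disease state, V/J calls, geometric redundancy). Profile-based
backgrounds matter for validation: they produce realistic identity
distributions — high framework identity, variable CDR identity, frequent
exact ties — which is precisely what stresses the tie-breaking and
accumulator-merge logic.

What it does *not* emulate: real V(D)J recombination, somatic
hypermutation lineage structure, germline gene usage biases, sequencing
error profiles, or chain pairing. Consequently, passing validation shows
the engine is *exact with respect to its definition* on data with the
right combinatorial structure (variable-length CDR3s, indels, ties,
ambiguity, unusual insertions); it says nothing about biological
interpretation of hits on real data, and nothing about wall-clock
performance at repertoire scale.

`plant_neighbors()` plants variants at an exact masked edit distance, so
their identity to the query is known in closed form
(100·(m−e)/m for e edits among m masked residues) — an analytic anchor
that requires no oracle. `oracle_search()` is the independent reference:
a pair-at-a-time transliteration of the identity definition with its own
counting and sorting code, sharing nothing with the vectorized path;
engine-vs-oracle equality (values *and* ranked index lists) over
randomized databases of 10³–10⁴ sequences is the core validation, run
100 times in the acceptance suite (problem sizes chosen so the whole
suite stays in the minutes range on a single CPU; agreement is required
in 100/100 trials, not on average).

## Numerical and degenerate-input choices

* Gap code 0 and a 1..21 alphabet make "both non-gap" a comparison, not a
  lookup; codes fit uint8 with headroom.
* Zero coverage (e.g. an empty region after terminal trimming, or two
  sequences occupying disjoint scheme regions) yields identity 0 with
  `comparable = TRUE` — "nothing in common" is a valid, orderable result,
  distinct from the length-matched rejection.
* Empty databases, empty hit lists and header-only joins are all legal
  and tested; `top_n` with fewer than `n` qualifying rows returns what
  qualifies.
* Slot indices are 1-based throughout the R API (idiomatic R); the
  on-disk index pairs are 0-based (language-neutral format). The boundary
  is `read_shard()`/`resolve_metadata()`.
* R's `sample()` length-1 surprise is avoided with `sample.int` wherever
  the pool can shrink to one element.

## Known limitations

* Only V domains: the scheme has no constant-domain positions.
* Identity only: no substitution-matrix similarity, so very distant
  relatives (same fold, low identity) are not ranked meaningfully; the
  engine is for the few-mutations regime.
* The default 200-slot scheme is a convention; repertoires of species
  with unusual insertion patterns (e.g. very long camelid CDR3s beyond
  the 72 insertion slots) route those sequences to the unusual sidecar
  rather than searching them.
* The fixture numbering backend cannot number previously unseen
  sequences; production use of raw FASTA queries requires an external
  numbering tool behind the backend contract.
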