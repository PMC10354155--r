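# abscan — exhaustive region-aware antibody sequence-identity search

`abscan` is an R toolkit for mining antibody repertoires: given an antibody
variable (V) domain of interest, it finds the most identical sequences in a
repertoire database over the whole domain, the CDRs, the CDR3, a
structurally derived paratope, or any user-defined set of alignment
positions. It is aimed at antibody engineers and immunoinformaticians who
want to ask "has a loop like this been seen before, in whom, and on which
germline frameworks?"

## The method

Pairwise alignment does not scale to repertoire-sized databases, but
antibody V domains have a standardized residue coordinate system: IMGT
numbering assigns every residue a position 1–128, with lettered insertion
codes for long CDR3 loops. `abscan` exploits this by pre-aligning every
sequence once into a fixed-length **canonical alignment** of 200 unique
positions (IMGT 1–128 plus 36 insertion slots each at positions 111 and
112, traversed in the IMGT CDR3 order 111, 111A, 111B, …, 112B, 112A, 112),
so each sequence becomes an integer vector `v` with `v[s] = 0` for a gap at
slot `s`. The rare sequences (~0.2 % in large repertoires) whose insertions
fall outside the canonical positions are set aside in an "unusual" sidecar
rather than silently misaligned.

Sequence identity between query `q` and target `t` over a region mask `R`
is then a pure counting operation:

```
matches(q,t,R)  = |{ s ∈ R : q[s] = t[s] ≠ gap }|
coverage(q,t,R) = |{ s ∈ R : q[s] ≠ gap or t[s] ≠ gap }|
identity        = 100 · matches / coverage
```

so an indel present in only one of the two sequences counts against
identity. Optional modes: *length-matched* (a pair is only comparable when
both carry the same number of residues in the region — the default for CDR
searches), *terminal-gap exclusion* (truncated ends are trimmed from the
region before counting), and ambiguity handling (`X` never matches
anything, so ambiguous reads cannot inflate identity). Because whole
matrices of targets can be scored with elementwise operations, the search
is **exhaustive** — every database row is scored, there is no k-mer
prefilter — which guarantees the exact closest match under this identity is
always found. Counting is exact integer arithmetic; ties are broken by
database order, so results are fully reproducible and independent of chunk
size or worker count.

The database is stored as sharded binary matrices (uint8, row-major) with a
plain-text manifest and content hashes, partitioned by chain type and
species. Each row carries a two-value index (metadata file, row) resolving
to an AIRR-style metadata record, so hits come back with species, disease
state, V/J gene calls, and redundancy, with the identity as the final
column.

## Worked example

```r
library(abscan)

scheme <- default_scheme()                       # the 200-slot canonical alignment
rep <- generate_repertoire(                      # synthetic human heavy-chain repertoire
  repertoire_spec(2000, seed = 42, mutation_rate = 0.05), scheme)
db  <- build_database(rep$sequences, rep$metadata, scheme,
                      "demo_db", shard_size = 1024)
db
#> <sharded_database> 2000 sequences in 2 shard(s), 0 unusual, scheme b13dd444a6b1...

# a query two substitutions away from database member 1
query <- encode(plant_neighbors(rep$sequences[[1]], 1,
                                default_regions(scheme)$whole,
                                edits = 2, scheme = scheme)[[1]], scheme)

hits    <- search(list(covid_ab = query), db,
                  search_config(default_regions(scheme), n_best = 3))
results <- join_metadata(hits, db)
results[, c("query", "region", "rank", "sequence_id", "v_call",
            "disease_state", "Identity")]
#>      query region rank  sequence_id      v_call disease_state  Identity
#> 1 covid_ab  whole    1 synth_000001  IGHV5-7*01       healthy  98.31933
#> 2 covid_ab  whole    2 synth_001356  IGHV4-6*02       healthy  94.95798
#> 3 covid_ab  whole    3 synth_001545 IGHV6-56*02       healthy  94.95798
#> 4 covid_ab   cdrs    1 synth_000001  IGHV5-7*01       healthy  96.42857
#> 5 covid_ab   cdrs    2 synth_000215 IGHV5-42*01    SARS-CoV-2  85.71429
#> 6 covid_ab   cdrs    3 synth_000127 IGHV5-42*01           HIV  82.14286
#> 7 covid_ab   cdr3    1 synth_000001  IGHV5-7*01       healthy 100.00000
#> 8 covid_ab   cdr3    2 synth_000215 IGHV5-42*01    SARS-CoV-2  75.00000
#> 9 covid_ab   cdr3    3 synth_000072 IGHV6-34*02    SARS-CoV-2  62.50000

summarize_hits(results, "disease_state")
#>   disease_state n_hits
#> 1       healthy      5
#> 2    SARS-CoV-2      3
#> 3           HIV      1
```

Reading the output: the planted 2-substitution relative of the query is
rank 1 in every region — at 98.3 % over the whole domain (2 mismatches in
119 covered slots), 96.4 % over the 28 CDR residues, and 100 % over the
CDR3 (both edits fell outside it). The metadata columns then tell you which
donors and germlines carry the closest sequences, exactly the grouping a
repertoire-mining study reports.

Region masks can also come from a structure: `extract_paratope()` reads an
antibody–antigen complex in PDB format and returns the IMGT positions of
all antibody residues with any heavy atom within 4.5 Å of the antigen,
ready for `mask_from_positions()`.

## Command line

A thin launcher over the same functions is installed at
`inst/cli/abscan.R`:

```sh
Rscript inst/cli/abscan.R make-synthetic --n 1000 --seed 7 --output synth/
Rscript inst/cli/abscan.R build-db --numbering synth/numbering.tsv \
        --metadata synth/metadata.csv --output db/
Rscript inst/cli/abscan.R search --db db/ --queries query.tsv \
        --regions whole,cdrs,cdr3 --n-best 1000 --threshold 90 --output out/
Rscript inst/cli/abscan.R summarize --results out/query_1_whole.csv \
        --group-by disease_state,v_call
```

Every run writes a `run_log.txt` capturing all effective parameters, the
scheme id and the seed, so any run is reproducible from its log.

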