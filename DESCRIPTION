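Package: abscan
Title: Exhaustive Region-Aware Antibody Sequence-Identity Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pre-aligns antibody variable-domain (V-domain) amino-acid
    sequences to a fixed-length canonical vector via IMGT numbering, stores
    them in a sharded binary database with metadata indices, and searches the
    database exhaustively (no prefiltering) for the top-N most identical
    sequences over the whole domain, the CDRs, the CDR3, a structurally
    derived paratope, or any user-defined set of alignment positions.
    Includes a synthetic repertoire generator and an independent brute-force
    oracle for validating the search engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
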