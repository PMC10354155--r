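# Fixture builders shared across the suite. Everything is generated in
# code; no binary files on disk.

# A small scheme over plain positions 1..n (no insertions).
tiny_scheme <- function(n = 8) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("imgt_position\tinsertion_code",
               sprintf("%d\t", seq_len(n))), f)
  on.exit(unlink(f))
  load_scheme(f)
}

# Numbering-table text for a list of records; each record is
# list(id, chain, species, pos, ins, res) with ins as insertion-code text.
numbering_text <- function(records) {
  rows <- unlist(lapply(records, function(r) {
    sprintf("%s\t%s\t%s\t%d\t%s\t%s", r$id, r$chain, r$species,
            r$pos, r$ins, r$res)
  }))
  c("sequence_id\tchain_type\tspecies\timgt_position\tinsertion_code\tresidue",
    rows)
}

write_numbering_text <- function(records) {
  f <- tempfile(fileext = ".tsv")
  writeLines(numbering_text(records), f)
  f
}

# Build a numbered_sequence directly from parallel vectors.
nseq <- function(id, pos, res, ins = integer(length(pos)), chain = "H",
                 species = "human") {
  numbered_sequence(id, data.frame(position = pos, insertion = ins,
                                   residue = res), chain, species)
}

# Minimal AIRR-style metadata for a list of numbered sequences.
meta_for <- function(seqs, redundancy = NULL) {
  n <- length(seqs)
  data.frame(
    sequence_id = vapply(seqs, `[[`, character(1), "id"),
    species = vapply(seqs, `[[`, character(1), "species"),
    chain = vapply(seqs, `[[`, character(1), "chain_type"),
    disease_state = rep_len(c("healthy", "SARS-CoV-2"), n),
    v_call = rep_len("IGHV1-58*01", n),
    j_call = rep_len("IGHJ3*02", n),
    redundancy = if (is.null(redundancy)) rep(1L, n) else redundancy
  )
}

# Random aligned vector over a scheme: occupies a contiguous-ish block.
random_vector <- function(scheme, n_res = 30) {
  L <- length(scheme$key)
  v <- integer(L)
  at <- sort(sample.int(L, n_res))
  v[at] <- sample.int(20L, n_res, replace = TRUE)
  attr(v, "scheme_id") <- scheme$scheme_id
  v
}

# Write a toy PDB file. `atoms` is a data frame with columns:
# serial, name, resn, chain, resno, x, y, z, elem.
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- sprintf(
    "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial, sprintf(" %-3s", atoms$name), atoms$resn, atoms$chain,
    atoms$resno, atoms$x, atoms$y, atoms$z, 1.00, 0.00, atoms$elem)
  writeLines(c(lines, "END"), path)
  path
}

# Independent all-pairs atomic distance check used against extract_paratope.
brute_force_contacts <- function(atoms, ab_chain, ag_chain, cutoff) {
  ab <- atoms[atoms$chain == ab_chain & atoms$elem != "H", ]
  ag <- atoms[atoms$chain == ag_chain & atoms$elem != "H", ]
  contact <- logical(0)
  for (rn in unique(ab$resno)) {
    a <- ab[ab$resno == rn, ]
    hit <- FALSE
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(ag))) {
      d <- sqrt((a$x[i] - ag$x[j])^2 + (a$y[i] - ag$y[j])^2 +
                  (a$z[i] - ag$z[j])^2)
      if (d <= cutoff) hit <- TRUE
    }
    contact[as.character(rn)] <- hit
  }
  as.integer(names(contact)[contact])
}
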