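# IMGT numbering contract: a numbered sequence is an ordered list of
# (imgt_position, insertion ordinal, residue) triples plus chain/species
# labels. Numbering itself (the HMM alignment an external tool performs) is
# out of scope; sequences enter either from a numbering table on disk or
# through a pluggable backend.

#' Construct a numbered sequence
#'
#' @param id Sequence identifier.
#' @param residues Data frame with columns `position` (integer 1..128),
#'   `insertion` (integer ordinal, 0 = none) and `residue` (one-letter code
#'   from the 20 standard amino acids plus `X`).
#' @param chain_type One of `"H"`, `"K"`, `"L"`.
#' @param species Free-text species label (e.g. `"human"`).
#' @return A `numbered_sequence` object.
#' @export
numbered_sequence <- function(id, residues, chain_type, species = "unknown") {
  stopifnot(is.data.frame(residues),
            all(c("position", "insertion", "residue") %in% names(residues)))
  residues$position <- as.integer(residues$position)
  residues$insertion <- as.integer(residues$insertion)
  residues$residue <- toupper(as.character(residues$residue))
  if (nrow(residues) > 0) {
    if (any(residues$position < 1L | residues$position > 128L))
      stop("imgt position out of range 1..128 in sequence '", id, "'")
    bad <- !(residues$residue %in% names(default_alphabet()))
    if (any(bad))
      stop("unknown residue symbol(s) in sequence '", id, "': ",
           paste(unique(residues$residue[bad]), collapse = ", "))
    k <- residues$position * 1000L + residues$insertion
    if (anyDuplicated(k))
      stop("duplicate (position, insertion) keys in sequence '", id, "'")
  }
  if (!chain_type %in% c("H", "K", "L"))
    stop("chain_type must be one of H, K, L (got '", chain_type, "')")
  structure(list(id = id, residues = residues, chain_type = chain_type,
                 species = species),
            class = "numbered_sequence")
}

#' @export
print.numbered_sequence <- function(x, ...) {
  cat("<numbered_sequence> '", x$id, "' chain ", x$chain_type, " (",
      x$species, "), ", nrow(x$residues), " residues\n", sep = "")
  invisible(x)
}

#' Raw amino-acid string of a numbered sequence
#' @param seq A `numbered_sequence`.
#' @return Single string of one-letter residues in numbering order.
#' @export
sequence_string <- function(seq) paste(seq$residues$residue, collapse = "")

#' Parse a numbering table into numbered sequences
#'
#' The fixture numbering format is tab-separated text with a header and
#' columns `sequence_id`, `chain_type`, `species`, `imgt_position`,
#' `insertion_code`, `residue` — one residue per row, rows of one record
#' contiguous and in numbering order. Lines starting with `#` are ignored.
#' Rows whose residue is the gap symbol `-` are dropped. Records appear in
#' the output in their order of first appearance.
#'
#' @param path Path to the table (or a connection).
#' @return Named list of `numbered_sequence` objects.
#' @export
parse_numbering_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          colClasses = "character", strip.white = TRUE)
  req <- c("sequence_id", "chain_type", "species", "imgt_position",
           "insertion_code", "residue")
  if (!all(req %in% names(df)))
    stop("numbering table must have columns: ", paste(req, collapse = ", "))
  pos <- suppressWarnings(as.integer(df$imgt_position))
  bad <- which(is.na(pos) & df$residue != "")
  if (length(bad) > 0)
    stop("malformed imgt_position at row ", bad[1], " (record '",
         df$sequence_id[bad[1]], "')")
  df$residue <- toupper(df$residue)
  known <- c(names(default_alphabet()), "-")
  bad <- which(!(df$residue %in% known))
  if (length(bad) > 0)
    stop("unknown residue symbol '", df$residue[bad[1]], "' at row ", bad[1],
         " (record '", df$sequence_id[bad[1]], "')")
  ins <- insertion_to_ordinal(df$insertion_code)
  ids <- unique(df$sequence_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    rows <- df$sequence_id == ids[i]
    keep <- rows & df$residue != "-"
    if (!any(keep)) {
      warning("record '", ids[i], "' has no residues; empty sequence kept")
      res <- data.frame(position = integer(0), insertion = integer(0),
                        residue = character(0))
    } else {
      res <- data.frame(position = pos[keep], insertion = ins[keep],
                        residue = df$residue[keep])
    }
    out[[i]] <- numbered_sequence(
      id = ids[i], residues = res,
      chain_type = df$chain_type[rows][1],
      species = df$species[rows][1]
    )
  }
  out
}

#' Write numbered sequences to a numbering table
#'
#' Inverse of [parse_numbering_table()]; emits the same tab-separated format.
#'
#' @param seqs List of `numbered_sequence` objects.
#' @param path Output path.
#' @export
write_numbering_table <- function(seqs, path) {
  blocks <- lapply(seqs, function(s) {
    if (nrow(s$residues) == 0) return(NULL)
    data.frame(
      sequence_id = s$id, chain_type = s$chain_type, species = s$species,
      imgt_position = s$residues$position,
      insertion_code = ordinal_to_insertion(s$residues$insertion),
      residue = s$residues$residue
    )
  })
  df <- do.call(rbind, blocks)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fixture numbering backend
#'
#' A numbering backend that answers queries by exact lookup of the raw
#' amino-acid string in a pre-numbered table, so the whole pipeline runs
#' with no external numbering tool. An adapter to an ANARCI-compatible
#' command-line tool can be written against the same backend contract
#' (a function taking a sequence string and returning a
#' `numbered_sequence` or `NULL`), but is not required anywhere.
#'
#' @param source Path to a fixture numbering table, or a list of
#'   `numbered_sequence` objects (e.g. from [parse_numbering_table()] or
#'   [generate_repertoire()]).
#' @return A `numbering_backend` object.
#' @export
fixture_backend <- function(source) {
  seqs <- if (is.character(source)) parse_numbering_table(source) else source
  stopifnot(all(vapply(seqs, inherits, logical(1), "numbered_sequence")))
  tab <- new.env(parent = emptyenv())
  for (s in seqs) assign(sequence_string(s), s, envir = tab)
  structure(list(kind = "fixture", table = tab, n = length(seqs)),
            class = "numbering_backend")
}

#' Number an amino-acid sequence with a backend
#'
#' Delegates numbering to the configured backend. With the fixture backend
#' this is an exact lookup; a miss returns a `numbering_failure` marker (the
#' sequence could not be numbered), never an error.
#'
#' @param sequence Amino-acid string (20 standard residues plus `X`).
#' @param backend A `numbering_backend` (see [fixture_backend()]).
#' @return A `numbered_sequence`, or a `numbering_failure` object.
#' @export
number_with_backend <- function(sequence, backend) {
  if (missing(backend) || !inherits(backend, "numbering_backend"))
    stop("no numbering backend configured; pass a 'numbering_backend' ",
         "(see fixture_backend())")
  sequence <- toupper(sequence)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", sequence))
    stop("input contains non-amino-acid characters")
  hit <- if (exists(sequence, envir = backend$table, inherits = FALSE))
    get(sequence, envir = backend$table) else NULL
  if (is.null(hit))
    return(structure(list(sequence = sequence,
                          reason = "sequence not found in fixture backend"),
                     class = "numbering_failure"))
  hit
}

#' Test whether numbering failed
#' @param x Object returned by [number_with_backend()].
#' @return Logical.
#' @export
is_numbering_failure <- function(x) inherits(x, "numbering_failure")
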