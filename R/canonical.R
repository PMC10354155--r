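# Residue alphabet: the 20 standard amino acids plus 'X' (ambiguous).
# Codes are 1..21; 0 is reserved for the alignment gap.
ABSCAN_ALPHABET <- {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  stats::setNames(seq_along(aa), aa)
}

#' Residue alphabet used by the canonical encoding
#'
#' Named integer vector mapping one-letter residue symbols (20 standard amino
#' acids plus `X` for an ambiguous residue) to the integer codes used inside
#' aligned vectors. Code 0 is reserved for the alignment gap and is not part
#' of the alphabet.
#'
#' @return Named integer vector of length 21.
#' @export
default_alphabet <- function() ABSCAN_ALPHABET

# Integer key for a (position, insertion) pair; insertions never exceed 36
# so a factor of 1000 keeps keys unique.
.slot_key <- function(position, insertion) position * 1000L + insertion

# Stable content hash of a character vector (md5 of its serialized text).
.content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

.new_scheme <- function(slots, alphabet = default_alphabet()) {
  key <- .slot_key(slots$position, slots$insertion)
  if (anyDuplicated(key))
    stop("duplicate position keys in scheme definition: ",
         paste(format_position_key(slots[duplicated(key), , drop = FALSE]),
               collapse = ", "))
  scheme_id <- .content_hash(c(
    sprintf("%d.%d", slots$position, slots$insertion),
    sprintf("%s=%d", names(alphabet), alphabet)
  ))
  structure(
    list(slots = slots, key = key, alphabet = alphabet, scheme_id = scheme_id),
    class = "canonical_scheme"
  )
}

#' Default canonical alignment scheme (200 slots)
#'
#' The canonical alignment places every IMGT position 1..128 (no insertion)
#' in one slot and adds 36 insertion slots at position 111 and 36 at position
#' 112, giving 200 slots in total. Slot order follows the IMGT traversal
#' rule: plain positions ascending, insertions at 111 ascending directly
#' after plain 111, insertions at 112 descending directly before plain 112,
#' so a long CDR3 loop stays contiguous in the vector.
#'
#' @return A `canonical_scheme` object with 200 slots.
#' @export
#' @examples
#' sc <- default_scheme()
#' nrow(sc$slots)  # 200
default_scheme <- function() {
  pos <- integer(0)
  ins <- integer(0)
  for (p in 1:128) {
    if (p == 112L) {
      pos <- c(pos, rep(112L, 36L)); ins <- c(ins, 36:1)
    }
    pos <- c(pos, p); ins <- c(ins, 0L)
    if (p == 111L) {
      pos <- c(pos, rep(111L, 36L)); ins <- c(ins, 1:36)
    }
  }
  .new_scheme(data.frame(position = pos, insertion = ins))
}

#' Load a canonical scheme from a definition file
#'
#' The definition is tab-separated with a header line and columns
#' `imgt_position` and `insertion_code` (empty for no insertion, or a letter
#' `A`, `B`, ... mapped to insertion ordinals 1, 2, ...; a plain integer
#' ordinal is also accepted). Rows are taken in file order as the slot
#' order. Lines starting with `#` are ignored.
#'
#' @param path Path to the definition file (or a connection).
#' @param alphabet Residue alphabet; defaults to [default_alphabet()].
#' @return A `canonical_scheme`.
#' @export
load_scheme <- function(path, alphabet = default_alphabet()) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          colClasses = "character", strip.white = TRUE)
  req <- c("imgt_position", "insertion_code")
  if (!all(req %in% names(df)))
    stop("scheme definition must have columns: ", paste(req, collapse = ", "))
  if (nrow(df) == 0) stop("scheme definition is empty")
  pos <- suppressWarnings(as.integer(df$imgt_position))
  if (anyNA(pos)) stop("non-integer imgt_position in scheme definition")
  ins <- insertion_to_ordinal(df$insertion_code)
  .new_scheme(data.frame(position = pos, insertion = ins), alphabet)
}

#' Write a scheme definition file
#'
#' @param scheme A `canonical_scheme`.
#' @param path Output path.
#' @export
write_scheme <- function(scheme, path) {
  df <- data.frame(
    imgt_position = scheme$slots$position,
    insertion_code = ordinal_to_insertion(scheme$slots$insertion)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert insertion codes (letters) to ordinals and back
#'
#' IMGT insertion codes are letters (`A` = first insertion, `B` = second,
#' ...). Internally insertions are ordinals so that the CDR3 traversal order
#' (ascending at 111, descending at 112) can be computed numerically. Codes
#' beyond `Z` use double letters `AA`, `AB`, ... (ordinals 27..52).
#'
#' @param code Character vector of insertion codes ("" for none). Numeric
#'   strings are taken as ordinals directly.
#' @return Integer vector of ordinals (0 = no insertion).
#' @export
insertion_to_ordinal <- function(code) {
  code <- toupper(trimws(ifelse(is.na(code), "", code)))
  out <- integer(length(code))
  numeric_like <- grepl("^[0-9]+$", code)
  out[numeric_like] <- as.integer(code[numeric_like])
  letters_like <- grepl("^[A-Z]+$", code)
  conv <- function(s) {
    v <- utf8ToInt(s) - utf8ToInt("A") + 1L
    as.integer(sum(v * 26^(rev(seq_along(v)) - 1)))
  }
  out[letters_like] <- vapply(code[letters_like], conv, integer(1))
  bad <- !numeric_like & !letters_like & code != ""
  if (any(bad)) stop("malformed insertion code(s): ",
                     paste(unique(code[bad]), collapse = ", "))
  out
}

#' @rdname insertion_to_ordinal
#' @param ordinal Integer vector of insertion ordinals.
#' @export
ordinal_to_insertion <- function(ordinal) {
  conv <- function(k) {
    if (k == 0L) return("")
    s <- ""
    while (k > 0L) {
      r <- (k - 1L) %% 26L
      s <- paste0(intToUtf8(utf8ToInt("A") + r), s)
      k <- (k - 1L) %/% 26L
    }
    s
  }
  vapply(as.integer(ordinal), conv, character(1))
}

#' Format position keys for messages
#' @param keys Data frame with columns `position`, `insertion`.
#' @return Character vector like `"111A"` or `"42"`.
#' @export
format_position_key <- function(keys) {
  paste0(keys$position, ordinal_to_insertion(keys$insertion))
}

#' Encode a numbered sequence into a fixed-length aligned vector
#'
#' Each residue is placed at the slot of its (position, insertion) key; all
#' other slots are the gap code 0. A sequence with any key absent from the
#' scheme (a rare insertion, e.g. `81I`) cannot be represented: no vector is
#' produced and an `unusual_sequence` marker carrying the offending keys is
#' returned instead. A residue symbol outside the alphabet is an error,
#' distinct from the unusual case.
#'
#' @param seq A `numbered_sequence`.
#' @param scheme A `canonical_scheme`.
#' @return An integer vector of length `nrow(scheme$slots)` with attribute
#'   `scheme_id`, or an `unusual_sequence` object.
#' @export
encode <- function(seq, scheme) {
  stopifnot(inherits(seq, "numbered_sequence"),
            inherits(scheme, "canonical_scheme"))
  res <- seq$residues
  vec <- integer(length(scheme$key))
  if (nrow(res) > 0) {
    slot <- match(.slot_key(res$position, res$insertion), scheme$key)
    if (anyNA(slot)) {
      off <- res[is.na(slot), c("position", "insertion"), drop = FALSE]
      return(structure(
        list(id = seq$id, sequence = paste(res$residue, collapse = ""),
             offending = off, chain_type = seq$chain_type,
             species = seq$species),
        class = "unusual_sequence"
      ))
    }
    code <- scheme$alphabet[res$residue]
    if (anyNA(code))
      stop("residue(s) not in alphabet for sequence '", seq$id, "': ",
           paste(unique(res$residue[is.na(code)]), collapse = ", "))
    vec[slot] <- unname(code)
  }
  attr(vec, "scheme_id") <- scheme$scheme_id
  vec
}

#' Decode an aligned vector back to its residue list
#'
#' Returns the (position, insertion, residue) rows for all non-gap slots, in
#' slot order. `decode(encode(s), scheme)` reproduces `s$residues` for any
#' sequence encodable under the scheme.
#'
#' @param vec Integer aligned vector.
#' @param scheme A `canonical_scheme`.
#' @return Data frame with columns `position`, `insertion`, `residue`.
#' @export
decode <- function(vec, scheme) {
  if (length(vec) != length(scheme$key))
    stop("vector length ", length(vec), " does not match scheme length ",
         length(scheme$key))
  nz <- which(vec != 0L)
  data.frame(
    position = scheme$slots$position[nz],
    insertion = scheme$slots$insertion[nz],
    residue = names(scheme$alphabet)[vec[nz]]
  )
}

#' Find the slot indices of position keys in a scheme
#'
#' @param keys Data frame with columns `position` and `insertion`, or an
#'   integer vector of plain positions (insertion 0).
#' @param scheme A `canonical_scheme`.
#' @return Integer vector of 1-based slot indices; `NA` where absent.
#' @export
slot_of <- function(keys, scheme) {
  if (!is.data.frame(keys))
    keys <- data.frame(position = as.integer(keys), insertion = 0L)
  if (is.null(keys$insertion)) keys$insertion <- 0L
  match(.slot_key(as.integer(keys$position), as.integer(keys$insertion)),
        scheme$key)
}

#' @export
print.canonical_scheme <- function(x, ...) {
  cat("<canonical_scheme> ", length(x$key), " slots, alphabet |",
      length(x$alphabet), "|, id ", substr(x$scheme_id, 1, 12), "...\n",
      sep = "")
  invisible(x)
}

#' @export
print.unusual_sequence <- function(x, ...) {
  cat("<unusual_sequence> '", x$id, "': off-scheme key(s) ",
      paste(format_position_key(x$offending), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Test whether an object is an unusual-sequence marker
#' @param x Object.
#' @return Logical.
#' @export
is_unusual <- function(x) inherits(x, "unusual_sequence")
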