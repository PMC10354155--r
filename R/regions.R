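# Named region masks over a canonical scheme: the whole V domain, the CDRs,
# the CDR3, a structurally derived paratope, or any user-defined set of
# alignment positions.

# IMGT CDR delimitations (positions, both ends inclusive). Configurable
# constants; insertion slots at a position inside a range belong to it.
ABSCAN_CDR_BOUNDS <- list(cdr1 = c(27L, 38L), cdr2 = c(56L, 65L),
                          cdr3 = c(105L, 117L))

#' Construct a region mask
#'
#' @param name Region name (unique within a suite).
#' @param slots Integer vector of 1-based slot indices into the scheme.
#' @param length_matched Logical; whether identity over this region requires
#'   equal residue counts in query and target (see [identity_options()]).
#' @param scheme Optional `canonical_scheme` used to validate slot range.
#' @return A `region_mask`.
#' @export
region_mask <- function(name, slots, length_matched = FALSE, scheme = NULL) {
  slots <- sort(unique(as.integer(slots)))
  if (length(slots) == 0) stop("region mask '", name, "' is empty")
  if (any(slots < 1L)) stop("slot indices must be >= 1")
  if (!is.null(scheme) && any(slots > length(scheme$key)))
    stop("slot index exceeds scheme length ", length(scheme$key))
  structure(list(name = name, slots = slots,
                 length_matched = isTRUE(length_matched)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask> '", x$name, "': ", length(x$slots), " slots",
      if (x$length_matched) ", length-matched" else "", "\n", sep = "")
  invisible(x)
}

#' Default region suite: whole domain, CDRs, CDR3
#'
#' The default search regions are the whole V domain (all slots, variable
#' length), the three CDRs combined and the CDR3 alone, both with exact
#' length match. CDR boundaries follow the IMGT delimitations: CDR1 27-38,
#' CDR2 56-65, CDR3 105-117, with all CDR3 insertion slots included.
#'
#' @param scheme A `canonical_scheme`.
#' @param bounds CDR boundary list (named `cdr1`, `cdr2`, `cdr3`, each
#'   `c(first, last)` IMGT position).
#' @return A named list of `region_mask` objects (`whole`, `cdrs`, `cdr3`),
#'   class `region_suite`.
#' @export
default_regions <- function(scheme, bounds = ABSCAN_CDR_BOUNDS) {
  pos <- scheme$slots$position
  in_range <- function(b) which(pos >= b[1] & pos <= b[2])
  cdr_slots <- sort(unique(unlist(lapply(bounds, in_range))))
  suite <- list(
    whole = region_mask("whole", seq_along(scheme$key), FALSE, scheme),
    cdrs = region_mask("cdrs", cdr_slots, TRUE, scheme),
    cdr3 = region_mask("cdr3", in_range(bounds$cdr3), TRUE, scheme)
  )
  region_suite(suite)
}

#' Assemble a region suite
#'
#' @param masks Named or unnamed list of `region_mask` objects; names unique.
#' @return A `region_suite`.
#' @export
region_suite <- function(masks) {
  if (inherits(masks, "region_mask")) masks <- list(masks)
  stopifnot(length(masks) > 0,
            all(vapply(masks, inherits, logical(1), "region_mask")))
  nm <- vapply(masks, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate region names in suite: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(masks) <- nm
  structure(masks, class = "region_suite")
}

#' @export
`[.region_suite` <- function(x, i) {
  region_suite(unclass(x)[i])
}

#' Build a region mask from a list of alignment positions
#'
#' Positions must be among the scheme's slots; any unknown key is rejected
#' with a message listing the offenders. The resulting mask is independent
#' of the input list order.
#'
#' @param positions Integer vector of plain IMGT positions, or a data frame
#'   with columns `position` and `insertion` (ordinals).
#' @param scheme A `canonical_scheme`.
#' @param length_matched Logical flag stored on the mask.
#' @param name Region name (default `"custom"`).
#' @return A `region_mask`.
#' @export
mask_from_positions <- function(positions, scheme, length_matched = FALSE,
                                name = "custom") {
  if (length(positions) == 0 ||
      (is.data.frame(positions) && nrow(positions) == 0))
    stop("position list is empty")
  if (!is.data.frame(positions))
    positions <- data.frame(position = as.integer(positions), insertion = 0L)
  if (is.null(positions$insertion)) positions$insertion <- 0L
  slots <- slot_of(positions, scheme)
  if (anyNA(slots))
    stop("position(s) not in scheme: ",
         paste(format_position_key(positions[is.na(slots), , drop = FALSE]),
               collapse = ", "))
  region_mask(name, slots, length_matched, scheme)
}

#' Serialize / read a region mask
#'
#' The on-disk form is the scheme-definition position-list format
#' (tab-separated `imgt_position`, `insertion_code`) with header comments
#' recording the region name and the length-match flag.
#'
#' @param mask A `region_mask`.
#' @param scheme The scheme the mask indexes into.
#' @param path File path.
#' @return `write_region_mask` returns `path` invisibly; `read_region_mask`
#'   returns a `region_mask`.
#' @export
write_region_mask <- function(mask, scheme, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# region_name: ", mask$name),
               paste0("# length_matched: ",
                      if (mask$length_matched) "true" else "false"),
               "imgt_position\tinsertion_code"), con)
  sl <- scheme$slots[mask$slots, , drop = FALSE]
  writeLines(sprintf("%d\t%s", sl$position, ordinal_to_insertion(sl$insertion)),
             con)
  invisible(path)
}

#' @rdname write_region_mask
#' @export
read_region_mask <- function(path, scheme) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) default else trimws(sub(".*:", "", m[1]))
  }
  nm <- get_hdr("region_name", "custom")
  lm <- tolower(get_hdr("length_matched", "false")) %in% c("true", "1", "yes")
  df <- utils::read.delim(textConnection(lines), header = TRUE,
                          comment.char = "#", colClasses = "character")
  keys <- data.frame(position = as.integer(df$imgt_position),
                     insertion = insertion_to_ordinal(df$insertion_code))
  mask_from_positions(keys, scheme, length_matched = lm, name = nm)
}

#' Extract paratope positions from an antibody-antigen complex
#'
#' Reads a PDB-format structure, finds the antibody residues having any
#' atom within `cutoff` of any antigen atom (default 4.5 angstrom, the
#' conventional contact distance), numbers each antibody chain's sequence
#' with the supplied backend, and returns the IMGT position keys of the
#' contact residues per antibody chain. By default only heavy (non-hydrogen)
#' atoms are considered; `atoms = "sidechain"` restricts to side-chain
#' atoms, `atoms = "all"` uses every atom present.
#'
#' Structure residues that cannot be mapped to a numbered position (for
#' example expression tags when the deposited chain is longer than the
#' numbered domain) are ignored with a warning.
#'
#' @param pdb_file Path to a PDB-format file.
#' @param antibody_chains Character vector of antibody chain identifiers.
#' @param antigen_chains Character vector of antigen chain identifiers.
#' @param cutoff Contact distance in angstrom (default 4.5).
#' @param backend A `numbering_backend` able to number the antibody chains.
#' @param atoms Atom subset: `"heavy"` (default), `"all"`, or `"sidechain"`.
#' @return Named list (one element per antibody chain) of data frames with
#'   columns `position` and `insertion`, in numbering order.
#' @export
extract_paratope <- function(pdb_file, antibody_chains, antigen_chains,
                             cutoff = 4.5, backend,
                             atoms = c("heavy", "all", "sidechain")) {
  atoms <- match.arg(atoms)
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (atoms != "all") {
    elt <- at$elesy
    if (is.null(elt) || all(is.na(elt)) || all(elt == ""))
      elt <- substr(trimws(at$elety), 1, 1)
    at <- at[toupper(trimws(elt)) != "H", , drop = FALSE]
  }
  if (atoms == "sidechain")
    at <- at[!(at$elety %in% c("N", "CA", "C", "O")) | at$resid == "GLY", ,
             drop = FALSE]
  missing_ch <- setdiff(c(antibody_chains, antigen_chains), unique(at$chain))
  if (length(missing_ch) > 0)
    stop("chain(s) not found in structure: ",
         paste(missing_ch, collapse = ", "))
  ag <- at[at$chain %in% antigen_chains, , drop = FALSE]
  ag_xyz <- as.matrix(ag[, c("x", "y", "z")])
  out <- list()
  for (ch in antibody_chains) {
    ab <- at[at$chain == ch & at$type == "ATOM", , drop = FALSE]
    res_key <- paste(ab$resno, ab$insert)
    res_order <- unique(res_key)
    # per-residue minimum atom-atom distance to the antigen
    ab_xyz <- as.matrix(ab[, c("x", "y", "z")])
    if (nrow(ag_xyz) == 0) {
      min_d <- rep(Inf, nrow(ab_xyz))
    } else {
      d2 <- outer(rowSums(ab_xyz^2), rowSums(ag_xyz^2), `+`) -
        2 * ab_xyz %*% t(ag_xyz)
      d2[d2 < 0] <- 0
      min_d <- sqrt(apply(d2, 1, min))
    }
    contact_res <- unique(res_key[min_d <= cutoff])
    # one-letter sequence of the chain, residues in order of appearance
    first_atom <- match(res_order, res_key)
    seq1 <- bio3d::aa321(ab$resid[first_atom])
    numbered <- number_with_backend(paste(seq1, collapse = ""), backend)
    if (is_numbering_failure(numbered))
      stop("could not number chain '", ch, "': ", numbered$reason)
    n_map <- nrow(numbered$residues)
    if (n_map != length(res_order))
      warning("chain '", ch, "': ", length(res_order), " structure residues ",
              "but ", n_map, " numbered residues; unmapped residues ignored")
    contact_i <- match(contact_res, res_order)
    contact_i <- sort(contact_i[contact_i <= n_map])
    out[[ch]] <- numbered$residues[contact_i, c("position", "insertion"),
                                   drop = FALSE]
    rownames(out[[ch]]) <- NULL
  }
  out
}
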