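# Region-masked sequence identity over canonically aligned vectors.
#
# Identity between two aligned vectors over a region is the percentage of
# identical residues across the region's slots, with indels present in only
# one of the sequences counted as mismatches: the denominator is the number
# of masked slots where at least one sequence has a residue, and matches are
# slots where both carry the same non-gap code. Counting is exact integer
# arithmetic; the percentage is formed only at reporting, so equal
# (matches, denominator) ratios compare exactly equal and ordering is
# reproducible.

#' Identity calculation options
#'
#' @param length_matched If `TRUE`, a pair is only comparable when the query
#'   and target have the same number of residues within the (effective)
#'   mask; otherwise the result is marked not comparable with identity 0.
#' @param include_terminal_gaps If `TRUE` (default), residues missing at the
#'   ends of either sequence count as mismatches like any one-sided indel.
#'   If `FALSE`, masked slots outside the region jointly covered by both
#'   sequences (before the later first residue, or after the earlier last
#'   residue, in slot order) are excluded first — see [trim_terminal()].
#' @param ambiguous_matches_nothing If `TRUE` (default), the ambiguous
#'   residue `X` never counts as a match, not even against another `X`, so
#'   ambiguity cannot inflate identity.
#' @param ambiguous_code Integer code of the ambiguous residue under the
#'   scheme's alphabet (21 for the default alphabet).
#' @return An `identity_options` object.
#' @export
identity_options <- function(length_matched = FALSE,
                             include_terminal_gaps = TRUE,
                             ambiguous_matches_nothing = TRUE,
                             ambiguous_code = unname(default_alphabet()["X"])) {
  structure(list(length_matched = isTRUE(length_matched),
                 include_terminal_gaps = isTRUE(include_terminal_gaps),
                 ambiguous_matches_nothing = isTRUE(ambiguous_matches_nothing),
                 ambiguous_code = as.integer(ambiguous_code)),
            class = "identity_options")
}

.as_opts <- function(opts) {
  if (is.null(opts)) identity_options()
  else if (inherits(opts, "identity_options")) opts
  else do.call(identity_options, opts)
}

# First and last non-gap slot of a vector; c(Inf, -Inf) when all gap, so an
# all-gap sequence yields an empty effective mask.
.span <- function(v) {
  nz <- which(v != 0L)
  if (length(nz) == 0) c(Inf, -Inf) else c(nz[1], nz[length(nz)])
}

#' Effective mask after excluding terminal missing residues
#'
#' Removes masked slots lying before the later of the two sequences' first
#' non-gap slots, or after the earlier of their last non-gap slots (slot
#' order = scheme order). Used when `include_terminal_gaps` is off, so that
#' a truncated sequence is not penalised for residues missing at its ends.
#'
#' @param a,b Aligned integer vectors under the same scheme.
#' @param mask A `region_mask` (or integer vector of slot indices).
#' @return Integer vector of retained slot indices (possibly empty).
#' @export
trim_terminal <- function(a, b, mask) {
  slots <- if (inherits(mask, "region_mask")) mask$slots else as.integer(mask)
  sa <- .span(a); sb <- .span(b)
  lo <- max(sa[1], sb[1]); hi <- min(sa[2], sb[2])
  slots[slots >= lo & slots <= hi]
}

.check_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("aligned vectors have different lengths (", length(a), " vs ",
         length(b), ")")
  ia <- attr(a, "scheme_id"); ib <- attr(b, "scheme_id")
  if (!is.null(ia) && !is.null(ib) && !identical(ia, ib))
    stop("aligned vectors were encoded under different schemes")
}

#' Sequence identity of one query/target pair over a region
#'
#' Over the masked slots (after optional terminal trimming): matches are
#' slots where both codes are equal and non-gap (and not ambiguous, under
#' the default options); the denominator is the number of slots where at
#' least one code is non-gap, so one-sided indels count as mismatches.
#' A zero denominator gives identity 0 with `comparable = TRUE`. In
#' length-matched mode, unequal residue counts within the effective mask
#' give `comparable = FALSE` and identity 0.
#'
#' @param a,b Aligned integer vectors under the same scheme.
#' @param mask A `region_mask` (or integer slot indices).
#' @param opts An `identity_options` object (defaults used when `NULL`).
#' @return List with `identity` (percentage in \[0, 100\]), `comparable`
#'   (logical), `matches` and `denominator` (integers).
#' @export
pair_identity <- function(a, b, mask, opts = NULL) {
  opts <- .as_opts(opts)
  .check_pair(a, b)
  slots <- if (inherits(mask, "region_mask")) mask$slots else as.integer(mask)
  if (any(slots < 1L | slots > length(a)))
    stop("mask slot index out of range for vector length ", length(a))
  if (!opts$include_terminal_gaps) slots <- trim_terminal(a, b, slots)
  am <- a[slots]; bm <- b[slots]
  na_ <- sum(am > 0L); nb_ <- sum(bm > 0L)
  if (opts$length_matched && na_ != nb_)
    return(list(identity = 0, comparable = FALSE, matches = 0L,
                denominator = 0L))
  denom <- sum(am > 0L | bm > 0L)
  eq <- am == bm & am > 0L
  if (opts$ambiguous_matches_nothing) eq <- eq & am != opts$ambiguous_code
  m <- sum(eq)
  list(identity = if (denom == 0L) 0 else 100 * m / denom,
       comparable = TRUE, matches = as.integer(m),
       denominator = as.integer(denom))
}

#' Identity of one query against a matrix of targets
#'
#' Matrix-operation equivalent of [pair_identity()] applied to every row of
#' `targets`; results are exactly equal (not approximately) to the pairwise
#' computation row by row.
#'
#' @param query Aligned integer vector.
#' @param targets N x L integer matrix of aligned vectors (rows).
#' @param mask A `region_mask` (or integer slot indices).
#' @param opts An `identity_options` object.
#' @return List with `identity` (numeric, length N) and `comparable`
#'   (logical, length N).
#' @export
batch_identity <- function(query, targets, mask, opts = NULL) {
  opts <- .as_opts(opts)
  if (!is.matrix(targets)) targets <- matrix(targets, nrow = 1)
  if (ncol(targets) != length(query))
    stop("target matrix has ", ncol(targets), " columns but query length is ",
         length(query))
  n <- nrow(targets)
  if (n == 0)
    return(list(identity = numeric(0), comparable = logical(0)))
  slots <- if (inherits(mask, "region_mask")) mask$slots else as.integer(mask)
  if (any(slots < 1L | slots > length(query)))
    stop("mask slot index out of range for vector length ", length(query))
  k <- length(slots)
  Tm <- targets[, slots, drop = FALSE]
  Qm <- matrix(query[slots], n, k, byrow = TRUE)
  nzT <- Tm != 0L
  nzQ <- Qm != 0L
  eq <- Tm == Qm & nzT
  if (opts$ambiguous_matches_nothing) eq <- eq & Tm != opts$ambiguous_code

  if (!opts$include_terminal_gaps) {
    qs <- .span(query)
    nzfull <- targets != 0L
    anynz <- rowSums(nzfull) > 0L
    ft <- max.col(nzfull, ties.method = "first")
    lt <- ncol(targets) + 1L - max.col(nzfull[, ncol(targets):1, drop = FALSE],
                                       ties.method = "first")
    lo <- pmax(qs[1], ifelse(anynz, ft, Inf))
    hi <- pmin(qs[2], ifelse(anynz, lt, -Inf))
    eff <- outer(lo, slots, `<=`) & outer(hi, slots, `>=`)
    denom <- rowSums((nzT | nzQ) & eff)
    m <- rowSums(eq & eff)
    cntT <- rowSums(nzT & eff)
    cntQ <- rowSums(nzQ & eff)
  } else {
    denom <- rowSums(nzT | nzQ)
    m <- rowSums(eq)
    cntT <- rowSums(nzT)
    cntQ <- rowSums(nzQ)
  }
  comparable <- rep(TRUE, n)
  if (opts$length_matched) comparable <- cntT == cntQ
  identity <- ifelse(denom == 0L, 0, 100 * m / denom)
  identity[!comparable] <- 0
  list(identity = as.numeric(identity), comparable = comparable)
}

#' Select the top-N hits from a vector of identities
#'
#' Returns the `n` largest comparable identities (at or above `threshold`
#' when one is given), sorted descending with ties broken by ascending row
#' index; fewer than `n` rows are returned when fewer qualify.
#'
#' @param identities Numeric identity values.
#' @param comparable Logical vector (same length); non-comparable rows never
#'   qualify. Defaults to all `TRUE`.
#' @param n Number of hits to keep (>= 1).
#' @param threshold Optional minimum identity (inclusive: a hit exactly at
#'   the threshold qualifies).
#' @return Data frame with columns `index` and `identity`, in rank order.
#' @export
top_n <- function(identities, comparable = NULL, n, threshold = NULL) {
  stopifnot(n >= 1)
  if (is.null(comparable)) comparable <- rep(TRUE, length(identities))
  keep <- comparable
  if (!is.null(threshold)) keep <- keep & identities >= threshold
  idx <- which(keep)
  if (length(idx) == 0)
    return(data.frame(index = integer(0), identity = numeric(0)))
  ord <- idx[order(-identities[idx], idx)]
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(index = ord, identity = identities[ord])
}
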