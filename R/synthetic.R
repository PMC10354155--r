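# Synthetic IMGT-numbered antibody repertoires with controlled mutation
# structure, plus the independent brute-force search oracle used to
# validate the engine. The generator emits the same numbering-table and
# metadata formats the database builder consumes, so the whole pipeline can
# be exercised end to end with no external data.

# Framework occupancy of the synthetic V-domain template: IMGT positions
# 1..104 and 118..128, with a few positions left empty as real germlines
# leave gaps in the IMGT frame (short CDR1/CDR2 loops and framework gaps).
SYNTH_TEMPLATE_GAPS <- c(10L, 33L, 61L, 73L)

.synth_env <- new.env(parent = emptyenv())

# Per-position residue frequency profiles: framework positions are highly
# conserved (one dominant residue), CDR positions much less so. Built once
# under a private RNG stream so generation is unaffected by it.
.synth_profiles <- function() {
  if (!is.null(.synth_env$profiles)) return(.synth_env$profiles)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(902700L)
  aa <- setdiff(names(default_alphabet()), "X")
  cdr_pos <- c(27:38, 56:65, 105:117)
  make_prof <- function(pos) {
    conc <- if (pos %in% cdr_pos) 2 else 15
    w <- stats::rexp(length(aa))
    w[sample.int(length(aa), 1)] <- conc
    w / sum(w)
  }
  prof <- lapply(1:128, make_prof)
  .synth_env$profiles <- prof
  prof
}

#' CDR3 position keys for a given loop length
#'
#' Returns the IMGT position keys occupied by a CDR3 of `len` residues,
#' following the canonical convention: the 13 plain positions 105..117 are
#' filled from both ends inward (gaps in the middle for short loops), and
#' longer loops use insertion slots 111.1, 111.2, ... and ..., 112.2, 112.1
#' between positions 111 and 112.
#'
#' @param len CDR3 residue count (1 to 85 under the default scheme).
#' @return Data frame with columns `position` and `insertion`, in canonical
#'   traversal order.
#' @export
cdr3_position_keys <- function(len) {
  stopifnot(len >= 1)
  left <- data.frame(position = c(105:111, rep(111L, 36)),
                     insertion = c(rep(0L, 7), 1:36))
  right <- data.frame(position = c(117:112, rep(112L, 36)),
                      insertion = c(rep(0L, 6), 1:36))
  n_left <- ceiling(len / 2)
  n_right <- floor(len / 2)
  if (n_left > nrow(left) || n_right > nrow(right))
    stop("CDR3 length ", len, " exceeds the scheme's CDR3 capacity")
  keys <- rbind(left[seq_len(n_left), ],
                right[rev(seq_len(n_right)), ])
  rownames(keys) <- NULL
  keys
}

# fast internal constructor; inputs already validated by construction
.numbered_fast <- function(id, position, insertion, residue, chain, species) {
  structure(list(
    id = id,
    residues = structure(list(position = position, insertion = insertion,
                              residue = residue),
                         class = "data.frame",
                         row.names = seq_along(position)),
    chain_type = chain, species = species), class = "numbered_sequence")
}

#' Specification of a synthetic repertoire
#'
#' @param n_sequences Number of sequences to generate.
#' @param chain_type `"H"`, `"K"` or `"L"` (one chain type per repertoire).
#' @param species_mix Named numeric vector of species proportions (e.g.
#'   `c(human = 0.8, mouse = 0.2)`).
#' @param cdr3_length_range Integer `c(min, max)` of CDR3 residue counts;
#'   lengths are sampled uniformly from the range.
#' @param mutation_rate Per-position probability that a framework residue
#'   deviates from the template consensus (resampled from the position's
#'   residue profile).
#' @param cdr3_mutation_rate Per-position deviation probability inside the
#'   CDR3; defaults to `min(1, 5 * mutation_rate)`, reflecting the much
#'   higher diversity of the loop.
#' @param ambiguous_rate Per-residue probability of replacement by `X`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `repertoire_spec`.
#' @export
repertoire_spec <- function(n_sequences, chain_type = "H",
                            species_mix = c(human = 1),
                            cdr3_length_range = c(8L, 20L),
                            mutation_rate = 0.02,
                            cdr3_mutation_rate = NULL,
                            ambiguous_rate = 0, seed = 1L) {
  if (is.null(cdr3_mutation_rate))
    cdr3_mutation_rate <- min(1, 5 * mutation_rate)
  rates <- c(mutation_rate, cdr3_mutation_rate, ambiguous_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(n_sequences >= 1, chain_type %in% c("H", "K", "L"),
            length(cdr3_length_range) == 2,
            cdr3_length_range[1] >= 1,
            cdr3_length_range[1] <= cdr3_length_range[2],
            all(species_mix > 0))
  structure(list(n_sequences = as.integer(n_sequences),
                 chain_type = chain_type,
                 species_mix = species_mix / sum(species_mix),
                 cdr3_length_range = as.integer(cdr3_length_range),
                 mutation_rate = mutation_rate,
                 cdr3_mutation_rate = cdr3_mutation_rate,
                 ambiguous_rate = ambiguous_rate,
                 seed = as.integer(seed)),
            class = "repertoire_spec")
}

#' Generate a synthetic IMGT-numbered repertoire
#'
#' Sequences occupy the framework template positions with residues drawn
#' from conserved per-position frequency profiles (consensus residue unless
#' mutated at `mutation_rate`), and a CDR3 of sampled length occupying the
#' canonical insertion slots, mutated at `cdr3_mutation_rate`. Metadata
#' rows carry AIRR-style columns: `sequence_id`, `species`, `chain`,
#' `disease_state`, `v_call`, `j_call`, `redundancy`.
#'
#' @param spec A `repertoire_spec`.
#' @param scheme A `canonical_scheme`; lengths are validated against its
#'   CDR3 capacity.
#' @return List with `sequences` (list of `numbered_sequence`) and
#'   `metadata` (data frame, one row per sequence).
#' @export
generate_repertoire <- function(spec, scheme = default_scheme()) {
  stopifnot(inherits(spec, "repertoire_spec"))
  cdr3_cap <- sum(scheme$slots$position %in% 105:117)
  if (spec$cdr3_length_range[2] > cdr3_cap)
    stop("cdr3 length ", spec$cdr3_length_range[2],
         " exceeds the scheme's CDR3 capacity of ", cdr3_cap)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  prof <- .synth_profiles()
  aa <- setdiff(names(default_alphabet()), "X")
  consensus <- vapply(prof, function(p) aa[which.max(p)], character(1))
  fw_pos <- setdiff(c(1:104, 118:128), SYNTH_TEMPLATE_GAPS)

  n <- spec$n_sequences
  len_pool <- seq(spec$cdr3_length_range[1], spec$cdr3_length_range[2])
  lens <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
  species <- sample(names(spec$species_mix), n, replace = TRUE,
                    prob = spec$species_mix)
  diseases <- sample(c("healthy", "SARS-CoV-2", "influenza", "HIV"),
                     n, replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  v_call <- sample(sprintf("IG%sV%d-%d*0%d", spec$chain_type,
                           sample(1:7, 40, TRUE), sample(1:70, 40, TRUE),
                           sample(1:2, 40, TRUE)), n, replace = TRUE)
  j_call <- sample(sprintf("IG%sJ%d*0%d", spec$chain_type, 1:6,
                           rep(1:2, 3)), n, replace = TRUE)
  redundancy <- 1L + stats::rgeom(n, 0.25)

  # per-length layout cache: ordered positions/insertions and mutation rates
  layout <- lapply(stats::setNames(nm = unique(lens)), function(l) {
    ck <- cdr3_position_keys(as.integer(l))
    pos <- c(fw_pos, ck$position)
    ins <- c(integer(length(fw_pos)), ck$insertion)
    ord <- order(match(pos * 1000L + ins, scheme$key))
    pos <- pos[ord]; ins <- ins[ord]
    list(pos = pos, ins = ins,
         rate = ifelse(pos >= 105L & pos <= 117L, spec$cdr3_mutation_rate,
                       spec$mutation_rate))
  })
  ids <- sprintf("synth_%06d", seq_len(n))
  seqs <- vector("list", n)
  for (i in seq_len(n)) {
    lay <- layout[[as.character(lens[i])]]
    res <- consensus[lay$pos]
    mut <- which(stats::runif(length(lay$pos)) < lay$rate)
    for (j in mut) res[j] <- sample(aa, 1, prob = prof[[lay$pos[j]]])
    if (spec$ambiguous_rate > 0)
      res[stats::runif(length(lay$pos)) < spec$ambiguous_rate] <- "X"
    seqs[[i]] <- .numbered_fast(ids[i], lay$pos, lay$ins, unname(res),
                                spec$chain_type, species[i])
  }
  metadata <- data.frame(
    sequence_id = sprintf("synth_%06d", seq_len(n)),
    species = species, chain = spec$chain_type, disease_state = diseases,
    v_call = v_call, j_call = j_call, redundancy = redundancy
  )
  list(sequences = seqs, metadata = metadata)
}

#' Plant near neighbours of a query at a known edit distance
#'
#' Produces `k` variants of `query` differing from it at exactly `edits`
#' residue positions inside the mask (substitutions only, never to `X` and
#' never back to the original residue), so each variant's region identity
#' to the query is analytically `100 * (m - edits) / m` where `m` is the
#' query's masked residue count.
#'
#' @param query A `numbered_sequence` encodable under `scheme`.
#' @param k Number of variants.
#' @param mask A `region_mask`.
#' @param edits Number of substitutions per variant (0 to the masked
#'   residue count).
#' @param scheme A `canonical_scheme`.
#' @return List of `k` `numbered_sequence` variants.
#' @export
plant_neighbors <- function(query, k, mask, edits, scheme = default_scheme()) {
  vec <- encode(query, scheme)
  if (is_unusual(vec)) stop("query is not encodable under the scheme")
  occupied <- intersect(mask$slots, which(vec > 0L))
  if (edits > length(occupied))
    stop("edits (", edits, ") exceeds the query's masked residue count (",
         length(occupied), ")")
  aa <- setdiff(names(default_alphabet()), "X")
  alpha <- scheme$alphabet
  out <- vector("list", k)
  for (v in seq_len(k)) {
    w <- vec
    at <- if (edits > 0) occupied[sample.int(length(occupied), edits)]
          else integer(0)
    for (s in at) {
      choices <- alpha[setdiff(aa, names(alpha)[w[s]])]
      w[s] <- unname(sample(choices, 1))
    }
    res <- decode(w, scheme)
    out[[v]] <- .numbered_fast(paste0(query$id, ".var", v), res$position,
                               res$insertion, res$residue,
                               query$chain_type, query$species)
  }
  out
}

#' Brute-force reference search (oracle)
#'
#' A deliberately simple, pair-at-a-time reference implementation of the
#' identity definition and ranking rule, sharing no code with the
#' vectorized engine ([batch_identity()], [search()]). Intended for small
#' inputs as the equality reference in validation.
#'
#' @param queries A single aligned vector or list of aligned vectors.
#' @param targets N x L integer matrix of aligned rows.
#' @param mask A `region_mask` (or integer slot indices).
#' @param opts An `identity_options` object (or `NULL` for defaults).
#' @param n Number of hits per query.
#' @param threshold Optional minimum identity (inclusive).
#' @return List (one element per query) of data frames with columns `index`
#'   and `identity`, rank-ordered.
#' @export
oracle_search <- function(queries, targets, mask, opts = NULL, n,
                          threshold = NULL) {
  if (!is.list(queries)) queries <- list(queries)
  opts <- .as_opts(opts)
  slots_in <- if (inherits(mask, "region_mask")) mask$slots
              else as.integer(mask)
  lm <- opts$length_matched
  itg <- opts$include_terminal_gaps
  ambn <- opts$ambiguous_matches_nothing
  ambc <- opts$ambiguous_code

  one_pair <- function(q, t) {
    slots <- slots_in
    if (!itg) {
      qi <- which(q != 0L); ti <- which(t != 0L)
      if (length(qi) == 0L || length(ti) == 0L) {
        slots <- integer(0)
      } else {
        lo <- max(qi[1], ti[1])
        hi <- min(qi[length(qi)], ti[length(ti)])
        slots <- slots[slots >= lo & slots <= hi]
      }
    }
    qq <- q[slots]; tt <- t[slots]
    if (lm && sum(qq != 0L) != sum(tt != 0L))
      return(list(identity = 0, comparable = FALSE))
    covered <- sum(qq != 0L | tt != 0L)
    same <- qq != 0L & qq == tt
    if (ambn) same[qq == ambc] <- FALSE
    list(identity = if (covered == 0L) 0 else 100 * sum(same) / covered,
         comparable = TRUE)
  }

  lapply(queries, function(q) {
    ids <- numeric(nrow(targets))
    cmp <- logical(nrow(targets))
    for (r in seq_len(nrow(targets))) {
      pr <- one_pair(q, targets[r, ])
      ids[r] <- pr$identity
      cmp[r] <- pr$comparable
    }
    ok <- which(cmp & (if (is.null(threshold)) TRUE else ids >= threshold))
    ord <- ok[order(-ids[ok], ok)]
    ord <- ord[seq_len(min(n, length(ord)))]
    data.frame(index = ord, identity = ids[ord])
  })
}
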