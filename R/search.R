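# Exhaustive multi-query, multi-region search over database shards, with
# streamed top-N accumulation. No prefiltering of any kind: every database
# row in the selected partitions is scored against every query and region,
# so the exact closest match under the identity definition is always found.
# Rows are ranked by identity descending with ties broken by ascending
# global database row (manifest order), which makes results independent of
# chunk size and worker count.

#' Search configuration
#'
#' @param regions A `region_suite` (see [default_regions()],
#'   [region_suite()]). Each mask carries its own length-match flag.
#' @param n_best Number of hits to keep per (query, region) (default 1000).
#' @param threshold Optional minimum identity percentage; hits below it
#'   never enter the accumulator (inclusive boundary: a hit exactly at the
#'   threshold qualifies).
#' @param chunk_rows Rows scored per chunk (default 16384). Any value gives
#'   identical results; it only bounds working memory.
#' @param workers Number of parallel workers over shards (forked processes;
#'   default 1). Any value gives identical results.
#' @param chains Optional chain-type selector (e.g. `"H"`); default all
#'   partitions.
#' @param species Optional species selector; default all partitions.
#' @param include_terminal_gaps,ambiguous_matches_nothing Passed to
#'   [identity_options()] for every region.
#' @return A `search_config`.
#' @export
search_config <- function(regions, n_best = 1000, threshold = NULL,
                          chunk_rows = 16384, workers = 1,
                          chains = NULL, species = NULL,
                          include_terminal_gaps = TRUE,
                          ambiguous_matches_nothing = TRUE) {
  if (inherits(regions, "region_mask")) regions <- region_suite(list(regions))
  stopifnot(inherits(regions, "region_suite"), n_best >= 1, chunk_rows >= 1,
            workers >= 1)
  structure(list(regions = regions, n_best = as.integer(n_best),
                 threshold = threshold, chunk_rows = as.integer(chunk_rows),
                 workers = as.integer(workers), chains = chains,
                 species = species,
                 include_terminal_gaps = isTRUE(include_terminal_gaps),
                 ambiguous_matches_nothing = isTRUE(ambiguous_matches_nothing)),
            class = "search_config")
}

.empty_hits <- function() {
  data.frame(query = character(0), region = character(0), rank = integer(0),
             identity = numeric(0), db_row = integer(0),
             file_id = integer(0), row_in_file = integer(0))
}

# Rank candidate rows of one (query, region) accumulator: identity
# descending, ties by ascending global database row; truncate to n_best.
.rank_hits <- function(cand, n_best) {
  if (nrow(cand) == 0) return(cand)
  ord <- order(-cand$identity, cand$db_row)
  cand <- cand[ord[seq_len(min(n_best, length(ord)))], , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}

# Score one shard: returns per (query, region) candidate data frames,
# already truncated to n_best (local top-N; merged later across shards).
.scan_shard <- function(shard, offset, queries, config) {
  opts_for <- function(mask) identity_options(
    length_matched = mask$length_matched,
    include_terminal_gaps = config$include_terminal_gaps,
    ambiguous_matches_nothing = config$ambiguous_matches_nothing)
  out <- list()
  nrows <- nrow(shard$matrix)
  starts <- if (nrows > 0) seq(1, nrows, by = config$chunk_rows) else integer(0)
  for (qi in seq_along(queries)) {
    for (rg in config$regions) {
      cand <- NULL
      for (st in starts) {
        en <- min(st + config$chunk_rows - 1L, nrows)
        block <- shard$matrix[st:en, , drop = FALSE]
        bi <- batch_identity(queries[[qi]], block, rg, opts_for(rg))
        tp <- top_n(bi$identity, bi$comparable, config$n_best,
                    config$threshold)
        if (nrow(tp) > 0) {
          rows <- as.integer(st) - 1L + tp$index
          cand <- rbind(cand, data.frame(
            identity = tp$identity,
            db_row = offset + rows,
            file_id = shard$index_pairs[rows, 1],
            row_in_file = shard$index_pairs[rows, 2]))
          cand <- cand[order(-cand$identity, cand$db_row), , drop = FALSE]
          cand <- cand[seq_len(min(config$n_best, nrow(cand))), ,
                       drop = FALSE]
        }
      }
      out[[paste(qi, rg$name, sep = "\r")]] <-
        if (is.null(cand)) data.frame(identity = numeric(0),
                                      db_row = integer(0),
                                      file_id = integer(0),
                                      row_in_file = integer(0)) else cand
    }
  }
  out
}

#' Exhaustive top-N identity search
#'
#' Scores every query against every database row in the selected partitions
#' for every region of the suite, and returns the `n_best` closest hits per
#' (query, region), sorted by identity. Queries must be encoded under the
#' database's scheme; a scheme mismatch is an error, never a silent
#' misalignment.
#'
#' @param queries A single aligned vector, a list of them (named names the
#'   queries), or an N x L matrix of query rows.
#' @param db A `sharded_database` from [load_database()] or
#'   [build_database()].
#' @param config A `search_config`.
#' @return A `search_hits` data frame with columns `query`, `region`,
#'   `rank`, `identity`, `db_row` (1-based global row in manifest order),
#'   `file_id`, `row_in_file` (0-based metadata index pair).
#' @export
search <- function(queries, db, config) {
  stopifnot(inherits(db, "sharded_database"),
            inherits(config, "search_config"))
  if (is.matrix(queries))
    queries <- lapply(seq_len(nrow(queries)), function(i) queries[i, ])
  if (!is.list(queries)) queries <- list(queries)
  if (length(queries) == 0) stop("no queries given")
  qnames <- names(queries)
  if (is.null(qnames)) qnames <- paste0("query_", seq_along(queries))
  for (q in queries) {
    if (length(q) != db$n_slots)
      stop("query length ", length(q), " does not match database slot count ",
           db$n_slots)
    sid <- attr(q, "scheme_id")
    if (!is.null(sid) && !identical(sid, db$scheme_id))
      stop("query was encoded under a different scheme than the database")
  }
  sel <- rep(TRUE, nrow(db$shards))
  if (!is.null(config$chains)) sel <- sel & db$shards$chain %in% config$chains
  if (!is.null(config$species))
    sel <- sel & db$shards$species %in% config$species
  shard_ids <- which(sel)
  offsets <- cumsum(c(0L, db$shards$rows))[seq_len(nrow(db$shards))]

  scan_one <- function(i) .scan_shard(read_shard(db, i), offsets[i],
                                      queries, config)
  per_shard <- if (config$workers > 1 && length(shard_ids) > 1 &&
                   .Platform$OS.type == "unix") {
    parallel::mclapply(shard_ids, scan_one, mc.cores = config$workers)
  } else {
    lapply(shard_ids, scan_one)
  }

  hits <- .empty_hits()
  for (qi in seq_along(queries)) {
    for (rg in config$regions) {
      key <- paste(qi, rg$name, sep = "\r")
      cand <- do.call(rbind, lapply(per_shard, `[[`, key))
      if (is.null(cand)) cand <- data.frame(identity = numeric(0),
                                            db_row = integer(0),
                                            file_id = integer(0),
                                            row_in_file = integer(0))
      cand <- .rank_hits(cand, config$n_best)
      if (nrow(cand) > 0)
        hits <- rbind(hits, data.frame(
          query = qnames[qi], region = rg$name, rank = cand$rank,
          identity = cand$identity, db_row = cand$db_row,
          file_id = cand$file_id, row_in_file = cand$row_in_file))
    }
  }
  class(hits) <- c("search_hits", class(hits))
  attr(hits, "queries") <- qnames
  attr(hits, "regions") <- vapply(config$regions, `[[`, character(1), "name")
  hits
}

#' Join hits with their metadata records
#'
#' Produces one output row per hit: the full metadata record columns
#' followed by the identity as the final column (`Identity`), preserving
#' the hit order (descending identity within each query and region).
#'
#' @param hits A `search_hits` data frame from [search()].
#' @param db The `sharded_database` the hits came from.
#' @return Data frame: `query`, `region`, `rank`, metadata columns,
#'   `Identity` last.
#' @export
join_metadata <- function(hits, db) {
  meta <- resolve_metadata(as.matrix(hits[, c("file_id", "row_in_file")]), db)
  if (nrow(hits) == 0) {
    # header-only table with the first metadata file's columns
    cols <- if (length(db$metadata_files) > 0)
      names(utils::read.csv(file.path(db$dir, db$metadata_files[1]),
                            nrows = 1)) else character(0)
    meta <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
  }
  out <- cbind(hits[, c("query", "region", "rank"), drop = FALSE], meta,
               Identity = hits$identity)
  rownames(out) <- NULL
  out
}

#' Summarize joined hits by metadata columns
#'
#' Counts hits per combination of the grouping column values, descending.
#'
#' @param results Data frame from [join_metadata()] (or any data frame).
#' @param group_by Character vector of column names to group by.
#' @return Data frame of the grouping columns plus `n_hits`, sorted by
#'   `n_hits` descending.
#' @export
summarize_hits <- function(results, group_by) {
  missing_cols <- setdiff(group_by, names(results))
  if (length(missing_cols) > 0)
    stop("grouping column(s) not in results: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(results) == 0) {
    out <- results[, group_by, drop = FALSE]
    out$n_hits <- integer(0)
    return(out)
  }
  agg <- stats::aggregate(list(n_hits = seq_len(nrow(results))),
                          by = results[, group_by, drop = FALSE], FUN = length)
  agg <- agg[order(-agg$n_hits), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write one CSV per (query, region) of joined results
#'
#' File names are `<query>_<region>.csv`; each file holds the metadata
#' columns with `Identity` as the final column, in rank order.
#'
#' @param results Data frame from [join_metadata()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (q in unique(results$query)) {
    for (rg in unique(results$region[results$query == q])) {
      sub <- results[results$query == q & results$region == rg, ,
                     drop = FALSE]
      sub <- sub[, setdiff(names(sub), c("query", "region", "rank")),
                 drop = FALSE]
      f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "-", q), "_",
                                 gsub("[^A-Za-z0-9_.-]", "-", rg), ".csv"))
      utils::write.csv(sub, f, row.names = FALSE)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}
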