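# Sharded aligned database: fixed-width uint8 shard matrices + per-row
# (metadata_file, row) index pairs + a plain-text manifest with content
# hashes + the original metadata CSVs. Partitioned by chain type and
# species. The binary layout is row-major bytes with dimensions recorded in
# the manifest, so shards are memory-mappable and language-neutral.

MANIFEST_NAME <- "manifest.txt"

#' Dataset-reduction filter configuration
#'
#' The reduction rules used to derive smaller database variants, applied in
#' this fixed order: drop sequences containing ambiguous residues; drop
#' sequences seen fewer than `min_redundancy` times; drop sequences with no
#' residue at IMGT position one; drop exact duplicates (first occurrence
#' kept). Redundancy is taken from a `redundancy` metadata column when
#' present, otherwise computed by exact-duplicate counting within the build
#' input.
#'
#' @param drop_ambiguous Drop sequences containing `X`.
#' @param min_redundancy Minimum times a sequence must have been seen
#'   (`NULL` disables the rule; the conventional value when enabled is 5).
#' @param require_position_one Require a residue at IMGT position 1.
#' @param deduplicate Drop exact duplicate sequences.
#' @return A `filter_config`.
#' @export
filter_config <- function(drop_ambiguous = FALSE, min_redundancy = NULL,
                          require_position_one = FALSE, deduplicate = FALSE) {
  if (!is.null(min_redundancy)) {
    min_redundancy <- as.integer(min_redundancy)
    stopifnot(min_redundancy >= 1)
  }
  structure(list(drop_ambiguous = isTRUE(drop_ambiguous),
                 min_redundancy = min_redundancy,
                 require_position_one = isTRUE(require_position_one),
                 deduplicate = isTRUE(deduplicate)),
            class = "filter_config")
}

#' Apply reduction filters to sequences and metadata
#'
#' Filters are total functions: every input is either retained or counted
#' against exactly one rule (the first, in rule order, that rejects it).
#'
#' @param seqs List of `numbered_sequence` objects.
#' @param metadata Data frame with one row per sequence (may be `NULL`).
#' @param filters A `filter_config`.
#' @return List with `keep` (logical vector over inputs) and `drop_counts`
#'   (named integer vector: ambiguous, low_redundancy, no_position_one,
#'   duplicate).
#' @export
apply_reduction_filters <- function(seqs, metadata = NULL, filters) {
  stopifnot(inherits(filters, "filter_config"))
  n <- length(seqs)
  if (!is.null(metadata) && nrow(metadata) != n)
    stop("metadata has ", nrow(metadata), " rows for ", n, " sequences")
  keep <- rep(TRUE, n)
  drops <- c(ambiguous = 0L, low_redundancy = 0L, no_position_one = 0L,
             duplicate = 0L)
  strings <- vapply(seqs, function(s)
    paste(s$residues$position, s$residues$insertion, s$residues$residue,
          sep = ".", collapse = "|"), character(1))

  if (filters$drop_ambiguous) {
    amb <- vapply(seqs, function(s) any(s$residues$residue == "X"), logical(1))
    drops["ambiguous"] <- sum(keep & amb)
    keep <- keep & !amb
  }
  if (!is.null(filters$min_redundancy)) {
    red <- if (!is.null(metadata) && "redundancy" %in% names(metadata)) {
      as.integer(metadata$redundancy)
    } else {
      cnt <- table(strings)
      as.integer(cnt[strings])
    }
    low <- red < filters$min_redundancy
    drops["low_redundancy"] <- sum(keep & low)
    keep <- keep & !low
  }
  if (filters$require_position_one) {
    has1 <- vapply(seqs, function(s)
      any(s$residues$position == 1L & s$residues$insertion == 0L), logical(1))
    drops["no_position_one"] <- sum(keep & !has1)
    keep <- keep & has1
  }
  if (filters$deduplicate) {
    dup <- rep(FALSE, n)
    dup[keep] <- duplicated(strings[keep])
    drops["duplicate"] <- sum(dup)
    keep <- keep & !dup
  }
  list(keep = keep, drop_counts = drops)
}

.write_fasta <- function(ids, seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) writeLines(c(paste0(">", ids[i]), seqs[i]), con)
  invisible(path)
}

#' Build a sharded aligned database
#'
#' Encodes the input sequences under the scheme, partitions the encodable
#' ones by (chain type, species), and writes shards of at most `shard_size`
#' rows plus an unusual-sequence FASTA sidecar, the metadata CSVs, a filter
#' report and a manifest. Every encoded row carries a two-value index
#' (metadata file, row within file, both 0-based) resolving to its metadata
#' record. Counts are conserved: input = dropped-by-filter + encoded +
#' unusual + encoding-errors.
#'
#' @param seqs List of `numbered_sequence` objects.
#' @param metadata Data frame with one row per sequence, or a list of data
#'   frames (multiple metadata files) whose row counts sum to the input
#'   count; sequences map to files in order.
#' @param scheme A `canonical_scheme`.
#' @param out_dir Output directory (created if needed).
#' @param shard_size Maximum rows per shard (default 2^20).
#' @param filters Optional `filter_config` applied before encoding.
#' @return The manifest, invisibly, as a `sharded_database` handle (see
#'   [load_database()]).
#' @export
build_database <- function(seqs, metadata, scheme, out_dir,
                           shard_size = 2^20, filters = NULL) {
  stopifnot(inherits(scheme, "canonical_scheme"), shard_size >= 1)
  if (is.data.frame(metadata)) metadata <- list(metadata)
  n <- length(seqs)
  if (sum(vapply(metadata, nrow, integer(1))) != n)
    stop("metadata row count (", sum(vapply(metadata, nrow, integer(1))),
         ") does not match sequence count (", n, ")")
  # global index -> (file_id, row) 0-based
  file_id <- rep(seq_along(metadata) - 1L, vapply(metadata, nrow, integer(1)))
  row_in_file <- unlist(lapply(metadata, function(m) seq_len(nrow(m)) - 1L),
                        use.names = FALSE)

  meta_all <- do.call(rbind, lapply(metadata, function(m)
    m[, intersect(names(metadata[[1]]), names(m)), drop = FALSE]))
  if (!is.null(filters)) {
    flt <- apply_reduction_filters(seqs, meta_all, filters)
  } else {
    flt <- list(keep = rep(TRUE, n),
                drop_counts = c(ambiguous = 0L, low_redundancy = 0L,
                                no_position_one = 0L, duplicate = 0L))
  }
  kept <- which(flt$keep)

  L <- length(scheme$key)
  enc <- vector("list", length(kept))
  status <- character(length(kept))
  unusual <- list()
  errors <- list()
  for (j in seq_along(kept)) {
    i <- kept[j]
    v <- tryCatch(encode(seqs[[i]], scheme), error = function(e) e)
    if (is_unusual(v)) {
      status[j] <- "unusual"; unusual[[length(unusual) + 1L]] <- v
    } else if (inherits(v, "error")) {
      status[j] <- "error"
      errors[[length(errors) + 1L]] <- list(id = seqs[[i]]$id,
                                            message = conditionMessage(v))
    } else {
      status[j] <- "encoded"; enc[[j]] <- v
    }
  }
  ok <- kept[status == "encoded"]
  mat <- if (length(ok) > 0)
    do.call(rbind, enc[status == "encoded"]) else matrix(0L, 0, L)
  pairs <- cbind(file_id[ok], row_in_file[ok])

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # partition by (chain, species)
  chain <- vapply(seqs[ok], `[[`, character(1), "chain_type")
  species <- vapply(seqs[ok], `[[`, character(1), "species")
  part <- if (length(ok) > 0) paste(chain, species, sep = "\r") else character(0)
  shard_tab <- NULL
  for (p in unique(part)) {
    rows <- which(part == p)
    pc <- strsplit(p, "\r", fixed = TRUE)[[1]]
    starts <- seq(1, length(rows), by = shard_size)
    for (si in seq_along(starts)) {
      idx <- rows[starts[si]:min(starts[si] + shard_size - 1, length(rows))]
      stem <- sprintf("shard_%s_%s_%03d", pc[1], gsub("[^A-Za-z0-9]", "-", pc[2]),
                      si - 1L)
      bin <- file.path(out_dir, paste0(stem, ".bin"))
      ipath <- file.path(out_dir, paste0(stem, ".idx"))
      writeBin(as.raw(t(mat[idx, , drop = FALSE])), bin)
      writeBin(as.integer(t(pairs[idx, , drop = FALSE])), ipath,
               size = 4, endian = "little")
      shard_tab <- rbind(shard_tab, data.frame(
        file = basename(bin), chain = pc[1], species = pc[2],
        rows = length(idx), cols = L,
        md5 = unname(tools::md5sum(bin)),
        idx_md5 = unname(tools::md5sum(ipath))))
    }
  }
  if (is.null(shard_tab))
    shard_tab <- data.frame(file = character(0), chain = character(0),
                            species = character(0), rows = integer(0),
                            cols = integer(0), md5 = character(0),
                            idx_md5 = character(0))

  meta_files <- sprintf("metadata_%03d.csv", seq_along(metadata) - 1L)
  for (i in seq_along(metadata))
    utils::write.csv(metadata[[i]], file.path(out_dir, meta_files[i]),
                     row.names = FALSE)
  .write_fasta(vapply(unusual, `[[`, character(1), "id"),
               vapply(unusual, `[[`, character(1), "sequence"),
               file.path(out_dir, "unusual.fasta"))
  utils::write.csv(
    data.frame(rule = names(flt$drop_counts), dropped = flt$drop_counts,
               row.names = NULL),
    file.path(out_dir, "filter_report.csv"), row.names = FALSE)
  write_scheme(scheme, file.path(out_dir, "scheme.tsv"))

  con <- file(file.path(out_dir, MANIFEST_NAME), "w")
  writeLines(c(
    "abscan_manifest: 1",
    paste0("scheme_id: ", scheme$scheme_id),
    paste0("n_slots: ", L),
    paste0("alphabet: ", paste(names(scheme$alphabet), collapse = "")),
    paste0("total_input: ", n),
    paste0("total_dropped: ", sum(flt$drop_counts)),
    paste0("total_encoded: ", length(ok)),
    paste0("total_unusual: ", length(unusual)),
    paste0("total_errors: ", length(errors)),
    paste0("metadata_files: ", paste(meta_files, collapse = ",")),
    "shards:",
    paste(c("file", "chain", "species", "rows", "cols", "md5", "idx_md5"),
          collapse = "\t"),
    if (nrow(shard_tab) > 0)
      do.call(paste, c(shard_tab, sep = "\t")) else character(0)
  ), con)
  close(con)
  invisible(load_database(file.path(out_dir, MANIFEST_NAME)))
}

#' Load a sharded database from its manifest
#'
#' Validates that every shard and metadata file referenced by the manifest
#' exists, that content hashes match, and that recorded row counts are
#' consistent with file sizes. Shard matrices are not read here; use
#' [read_shard()] to stream them one at a time.
#'
#' @param manifest_path Path to `manifest.txt` (or to the database
#'   directory containing it).
#' @return A `sharded_database` handle: manifest fields, shard table,
#'   metadata file list and a metadata cache.
#' @export
load_database <- function(manifest_path) {
  if (dir.exists(manifest_path))
    manifest_path <- file.path(manifest_path, MANIFEST_NAME)
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  dir <- dirname(manifest_path)
  lines <- readLines(manifest_path)
  kv_lines <- lines[seq_len(which(lines == "shards:") - 1)]
  kv <- stats::setNames(
    trimws(sub("^[^:]*:", "", kv_lines)),
    trimws(sub(":.*$", "", kv_lines)))
  tab_lines <- lines[(which(lines == "shards:") + 1):length(lines)]
  shards <- utils::read.delim(textConnection(tab_lines), header = TRUE,
                              colClasses = c(rows = "integer",
                                             cols = "integer"))
  for (i in seq_len(nrow(shards))) {
    bin <- file.path(dir, shards$file[i])
    ipath <- sub("\\.bin$", ".idx", bin)
    if (!file.exists(bin)) stop("missing shard file: ", bin)
    if (!file.exists(ipath)) stop("missing shard index file: ", ipath)
    if (file.info(bin)$size != shards$rows[i] * shards$cols[i])
      stop("shard ", shards$file[i], " size does not match its row count")
    if (unname(tools::md5sum(bin)) != shards$md5[i])
      stop("shard ", shards$file[i], " failed its content hash check")
    if (unname(tools::md5sum(ipath)) != shards$idx_md5[i])
      stop("shard index ", basename(ipath), " failed its content hash check")
  }
  if (sum(shards$rows) != as.integer(kv[["total_encoded"]]))
    stop("manifest row counts are inconsistent with total_encoded")
  meta_files <- if (nzchar(kv[["metadata_files"]]))
    strsplit(kv[["metadata_files"]], ",")[[1]] else character(0)
  for (f in meta_files)
    if (!file.exists(file.path(dir, f))) stop("missing metadata file: ", f)
  structure(list(
    dir = dir,
    scheme_id = kv[["scheme_id"]],
    n_slots = as.integer(kv[["n_slots"]]),
    alphabet = kv[["alphabet"]],
    total_input = as.integer(kv[["total_input"]]),
    total_dropped = as.integer(kv[["total_dropped"]]),
    total_encoded = as.integer(kv[["total_encoded"]]),
    total_unusual = as.integer(kv[["total_unusual"]]),
    total_errors = as.integer(kv[["total_errors"]]),
    metadata_files = meta_files,
    shards = shards,
    meta_cache = new.env(parent = emptyenv())
  ), class = "sharded_database")
}

#' @export
print.sharded_database <- function(x, ...) {
  cat("<sharded_database> ", x$total_encoded, " sequences in ",
      nrow(x$shards), " shard(s), ", x$total_unusual, " unusual, scheme ",
      substr(x$scheme_id, 1, 12), "...\n", sep = "")
  invisible(x)
}

#' Read one shard of a database into memory
#'
#' @param db A `sharded_database`.
#' @param i Shard number (1-based, manifest order).
#' @return List with `matrix` (rows x n_slots integer), `index_pairs`
#'   (rows x 2 integer, 0-based), `chain`, `species`.
#' @export
read_shard <- function(db, i) {
  stopifnot(i >= 1, i <= nrow(db$shards))
  s <- db$shards[i, ]
  bin <- file.path(db$dir, s$file)
  raw <- readBin(bin, "raw", n = s$rows * s$cols)
  mat <- matrix(as.integer(raw), nrow = s$rows, ncol = s$cols, byrow = TRUE)
  ipath <- sub("\\.bin$", ".idx", bin)
  ip <- readBin(ipath, "integer", n = s$rows * 2L, size = 4,
                endian = "little")
  list(matrix = mat,
       index_pairs = matrix(ip, nrow = s$rows, ncol = 2, byrow = TRUE),
       chain = s$chain, species = s$species)
}

#' Resolve an index pair to its metadata record
#'
#' @param pair Integer vector `c(file_id, row)` (both 0-based) or a
#'   two-column matrix of such pairs.
#' @param db A `sharded_database` (metadata files are cached after first
#'   read).
#' @return One-row data frame (or an n-row data frame for a matrix input).
#' @export
resolve_metadata <- function(pair, db) {
  if (is.matrix(pair)) {
    out <- lapply(seq_len(nrow(pair)), function(i)
      resolve_metadata(pair[i, ], db))
    return(do.call(rbind, out))
  }
  fid <- pair[1]; row <- pair[2]
  if (is.na(fid) || fid < 0 || fid >= length(db$metadata_files))
    stop("index pair (", fid, ", ", row, "): metadata file id out of range")
  key <- as.character(fid)
  if (!exists(key, envir = db$meta_cache, inherits = FALSE)) {
    assign(key,
           utils::read.csv(file.path(db$dir, db$metadata_files[fid + 1L])),
           envir = db$meta_cache)
  }
  tab <- get(key, envir = db$meta_cache)
  if (row < 0 || row >= nrow(tab))
    stop("index pair (", fid, ", ", row, "): row out of range for ",
         db$metadata_files[fid + 1L])
  tab[row + 1L, , drop = FALSE]
}
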