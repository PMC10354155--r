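make_seqs <- function(n, species = "human", prefix = "s") {
  lapply(seq_len(n), function(i) {
    nseq(sprintf("%s%02d", prefix, i), pos = 1:10,
         res = c("E", "V", "Q", "L", "V", "E", "S", "G", "G",
                 c("A", "C", "D", "E", "F")[(i - 1) %% 5 + 1]),
         species = species)
  })
}

test_that("shards split at shard_size and counts are conserved", {
  sc <- default_scheme()
  seqs <- make_seqs(10)
  db <- build_database(seqs, meta_for(seqs), sc, tempfile("db"),
                       shard_size = 4)
  expect_equal(db$shards$rows, c(4L, 4L, 2L))
  expect_equal(db$total_encoded, 10L)
  expect_equal(db$total_unusual, 0L)
  expect_equal(db$total_input,
               db$total_encoded + db$total_unusual + db$total_dropped +
                 db$total_errors)
})

test_that("off-scheme insertions go to the unusual sidecar", {
  sc <- default_scheme()
  seqs <- make_seqs(10)
  seqs[[3]] <- nseq("u1", pos = c(80L, 81L), res = c("A", "G"),
                    ins = c(0L, 9L))
  seqs[[7]] <- nseq("u2", pos = c(20L, 20L), res = c("A", "G"),
                    ins = c(0L, 5L))
  dir <- tempfile("db")
  db <- build_database(seqs, meta_for(seqs), sc, dir)
  expect_equal(db$total_encoded, 8L)
  expect_equal(db$total_unusual, 2L)
  fasta <- readLines(file.path(dir, "unusual.fasta"))
  expect_equal(fasta[c(1, 3)], c(">u1", ">u2"))
  # unusual rows never reach a shard matrix
  expect_equal(sum(db$shards$rows), 8L)
})

test_that("partitions are a disjoint cover by chain and species", {
  sc <- default_scheme()
  seqs <- c(make_seqs(4, "human", "h"), make_seqs(3, "mouse", "m"))
  db <- build_database(seqs, meta_for(seqs), sc, tempfile("db"))
  expect_setequal(db$shards$species, c("human", "mouse"))
  expect_equal(sum(db$shards$rows[db$shards$species == "human"]), 4L)
  expect_equal(sum(db$shards$rows[db$shards$species == "mouse"]), 3L)
  expect_equal(sum(db$shards$rows), length(seqs))
})

test_that("reduction filters drop by rule in order and report counts", {
  sc <- default_scheme()
  seqs <- make_seqs(10)
  seqs[[2]]$residues$residue[4] <- "X"
  seqs[[5]]$residues$residue[1] <- "X"
  flt <- apply_reduction_filters(seqs, NULL,
                                 filter_config(drop_ambiguous = TRUE))
  expect_equal(sum(flt$keep), 8)
  expect_equal(unname(flt$drop_counts["ambiguous"]), 2L)

  # redundancy from the metadata column: counts [1, 5, 7] keep 2 of 3
  seqs3 <- make_seqs(3)
  meta3 <- meta_for(seqs3, redundancy = c(1L, 5L, 7L))
  flt3 <- apply_reduction_filters(seqs3, meta3,
                                  filter_config(min_redundancy = 5))
  expect_equal(sum(flt3$keep), 2)
  expect_equal(which(flt3$keep), c(2L, 3L))

  # duplicates: two byte-identical sequences keep the first
  dup <- make_seqs(2)
  dup[[2]] <- nseq("copy", dup[[1]]$residues$position,
                   dup[[1]]$residues$residue)
  fltd <- apply_reduction_filters(dup, NULL,
                                  filter_config(deduplicate = TRUE))
  expect_equal(flt_keep <- which(fltd$keep), 1L)

  # position-one rule
  nohead <- list(nseq("a", pos = 2:4, res = c("A", "C", "D")),
                 nseq("b", pos = 1:3, res = c("A", "C", "D")))
  fltp <- apply_reduction_filters(nohead, NULL,
                                  filter_config(require_position_one = TRUE))
  expect_equal(which(fltp$keep), 2L)
})

test_that("conservation holds for every filter combination", {
  sc <- default_scheme()
  set.seed(99)
  rep <- generate_repertoire(repertoire_spec(40, seed = 99,
                                             mutation_rate = 0.1,
                                             ambiguous_rate = 0.05), sc)
  seqs <- rep$sequences
  # inject off-scheme insertions and duplicates
  seqs[[1]] <- nseq("odd1", pos = c(80L, 81L), res = c("A", "G"),
                    ins = c(0L, 9L))
  seqs[[2]] <- nseq(seqs[[2]]$id,
                    seqs[[3]]$residues$position, seqs[[3]]$residues$residue,
                    seqs[[3]]$residues$insertion)
  meta <- rep$metadata
  meta$redundancy <- sample(1:8, length(seqs), replace = TRUE)
  for (da in c(FALSE, TRUE)) for (mr in list(NULL, 5))
    for (p1 in c(FALSE, TRUE)) for (dd in c(FALSE, TRUE)) {
      db <- build_database(seqs, meta, sc, tempfile("db"),
                           filters = filter_config(da, mr, p1, dd))
      expect_equal(db$total_encoded + db$total_unusual + db$total_dropped +
                     db$total_errors,
                   length(seqs))
      expect_equal(sum(db$shards$rows), db$total_encoded)
    }
})

test_that("build/load round trip is bit-exact and integrity-checked", {
  sc <- default_scheme()
  rep <- generate_repertoire(repertoire_spec(30, seed = 4), sc)
  dir <- tempfile("db")
  built <- build_database(rep$sequences, rep$metadata, sc, dir,
                          shard_size = 12)
  loaded <- load_database(dir)
  expect_identical(loaded$scheme_id, sc$scheme_id)
  mats <- lapply(seq_len(nrow(loaded$shards)),
                 function(i) read_shard(loaded, i))
  all_rows <- do.call(rbind, lapply(mats, `[[`, "matrix"))
  want <- do.call(rbind, lapply(rep$sequences, function(s)
    as.integer(encode(s, sc))))
  expect_identical(all_rows, want)
  pairs <- do.call(rbind, lapply(mats, `[[`, "index_pairs"))
  expect_identical(pairs[, 1], rep(0L, 30))
  expect_identical(pairs[, 2], 0:29)
  # distinct sequences never share an index pair
  expect_false(anyDuplicated(paste(pairs[, 1], pairs[, 2])) > 0)

  # deleting a shard file is a load error naming the file
  victim <- file.path(dir, loaded$shards$file[2])
  content <- readBin(victim, "raw", file.info(victim)$size)
  unlink(victim)
  expect_error(load_database(dir), basename(victim))
  # corrupting it fails the content hash check
  writeBin(rev(content), victim)
  expect_error(load_database(dir), "hash")
})

test_that("an empty database is valid and searchable", {
  sc <- default_scheme()
  dir <- tempfile("db")
  db <- build_database(list(), list(meta_for(list())), sc, dir)
  expect_equal(db$total_encoded, 0L)
  expect_equal(nrow(db$shards), 0)
  h <- search(random_vector(sc), db,
              search_config(default_regions(sc), n_best = 5))
  expect_equal(nrow(h), 0)
})

test_that("index pairs resolve to the metadata supplied at build time", {
  sc <- default_scheme()
  rep1 <- generate_repertoire(repertoire_spec(6, seed = 21), sc)
  rep2 <- generate_repertoire(repertoire_spec(4, seed = 22), sc)
  rep2$metadata$sequence_id <- sub("synth", "other", rep2$metadata$sequence_id)
  for (i in seq_along(rep2$sequences))
    rep2$sequences[[i]]$id <- rep2$metadata$sequence_id[i]
  db <- build_database(c(rep1$sequences, rep2$sequences),
                       list(rep1$metadata, rep2$metadata), sc,
                       tempfile("db"))
  # bookkeeping oracle: the k-th input maps to its own metadata row
  sh <- read_shard(db, 1)
  ids_in <- c(rep1$metadata$sequence_id, rep2$metadata$sequence_id)
  for (k in seq_len(nrow(sh$matrix))) {
    rec <- resolve_metadata(sh$index_pairs[k, ], db)
    expect_equal(rec$sequence_id, ids_in[k])
  }
  expect_equal(resolve_metadata(c(0L, 0L), db)$sequence_id,
               rep1$metadata$sequence_id[1])
  expect_equal(resolve_metadata(c(1L, 2L), db)$sequence_id,
               rep2$metadata$sequence_id[3])
  expect_error(resolve_metadata(c(2L, 0L), db), "out of range")
  expect_error(resolve_metadata(c(0L, 99L), db), "out of range")
})

test_that("metadata/sequence count mismatches are build errors", {
  sc <- default_scheme()
  seqs <- make_seqs(3)
  expect_error(build_database(seqs, meta_for(make_seqs(2)), sc,
                              tempfile("db")), "does not match")
})
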