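build_synth_db <- function(n, seed, dir = tempfile("db"), shard_size = 400,
                           ...) {
  sc <- default_scheme()
  rep <- generate_repertoire(repertoire_spec(n, seed = seed,
                                             mutation_rate = 0.05, ...), sc)
  list(scheme = sc, rep = rep,
       db = build_database(rep$sequences, rep$metadata, sc, dir,
                           shard_size = shard_size))
}

db_matrix <- function(db) {
  do.call(rbind, lapply(seq_len(nrow(db$shards)),
                        function(i) read_shard(db, i)$matrix))
}

test_that("a query present in the database is its own rank-1 hit at 100", {
  x <- build_synth_db(120, seed = 31)
  q <- encode(x$rep$sequences[[17]], x$scheme)
  h <- search(q, x$db, search_config(default_regions(x$scheme), n_best = 3))
  for (rg in unique(h$region)) {
    top <- h[h$region == rg & h$rank == 1, ]
    expect_identical(top$identity, 100)
    expect_equal(top$db_row, 17)
  }
})

test_that("search equals the brute-force oracle for every query and region", {
  x <- build_synth_db(800, seed = 32, shard_size = 300)
  sc <- x$scheme
  regions <- default_regions(sc)
  set.seed(320)
  queries <- lapply(sample(800, 6), function(i)
    encode(x$rep$sequences[[i]], sc))
  h <- search(queries, x$db, search_config(regions, n_best = 50))
  mat <- db_matrix(x$db)
  for (qi in seq_along(queries)) {
    for (rg in regions) {
      o <- oracle_search(queries[[qi]], mat, rg,
                         identity_options(length_matched = rg$length_matched),
                         n = 50)[[1]]
      got <- h[h$query == paste0("query_", qi) & h$region == rg$name, ]
      expect_identical(got$db_row, o$index)
      expect_identical(got$identity, o$identity)
    }
  }
})

test_that("results are invariant to chunk size and worker count", {
  x <- build_synth_db(500, seed = 33, shard_size = 120)
  sc <- x$scheme
  q <- list(a = encode(x$rep$sequences[[5]], sc),
            b = encode(x$rep$sequences[[444]], sc))
  regions <- default_regions(sc)
  ref <- search(q, x$db, search_config(regions, n_best = 20,
                                       chunk_rows = 1024, workers = 1))
  for (cr in c(1, 7)) {
    alt <- search(q, x$db, search_config(regions, n_best = 20,
                                         chunk_rows = cr, workers = 1))
    expect_identical(alt, ref)
  }
  par <- search(q, x$db, search_config(regions, n_best = 20,
                                       chunk_rows = 64, workers = 4))
  expect_identical(par, ref)
})

test_that("multi-region output equals concatenated single-region searches", {
  x <- build_synth_db(300, seed = 34)
  sc <- x$scheme
  q <- encode(x$rep$sequences[[9]], sc)
  regions <- default_regions(sc)
  multi <- search(q, x$db, search_config(regions, n_best = 10))
  for (rg in regions) {
    single <- search(q, x$db, search_config(region_suite(list(rg)),
                                            n_best = 10))
    expect_equal(multi[multi$region == rg$name, ], single,
                 ignore_attr = TRUE)
  }
})

test_that("thresholding is inclusive, monotone, and can empty the hit list", {
  x <- build_synth_db(300, seed = 35)
  sc <- x$scheme
  # a query far from everything: all different residues at a few slots
  far <- nseq("far", pos = c(50:60), res = rep("W", 11))
  q <- encode(far, sc)
  h <- search(q, x$db, search_config(default_regions(sc)["whole"],
                                     n_best = 5, threshold = 90))
  expect_equal(nrow(h), 0)
  # monotone: hits at higher threshold are a subset of hits at lower
  q2 <- encode(x$rep$sequences[[2]], sc)
  h_all <- search(q2, x$db, search_config(default_regions(sc),
                                          n_best = 1000))
  for (t2 in c(80, 90, 99)) {
    ht <- search(q2, x$db, search_config(default_regions(sc), n_best = 1000,
                                         threshold = t2))
    expect_true(all(ht$identity >= t2))
    key <- paste(ht$region, ht$db_row)
    key_all <- paste(h_all$region, h_all$db_row)
    expect_true(all(key %in% key_all))
    # exactly the qualifying hits survive
    expect_equal(sort(key), sort(key_all[h_all$identity >= t2]))
  }
})

test_that("scheme mismatches between query and database are errors", {
  x <- build_synth_db(30, seed = 36)
  f <- tempfile()
  writeLines(c("imgt_position\tinsertion_code", sprintf("%d\t", 1:200)), f)
  other <- load_scheme(f)
  q <- encode(nseq("q", pos = 1:5, res = c("E", "V", "Q", "L", "S")), other)
  expect_error(search(q, x$db, search_config(default_regions(other))),
               "different scheme")
  expect_error(search(integer(10), x$db,
                      search_config(default_regions(x$scheme))), "length")
})

test_that("partition selectors restrict the scanned shards", {
  sc <- default_scheme()
  rep_h <- generate_repertoire(repertoire_spec(40, seed = 37,
                                               species_mix = c(human = 1)),
                               sc)
  rep_m <- generate_repertoire(repertoire_spec(40, seed = 38,
                                               species_mix = c(mouse = 1)),
                               sc)
  rep_m$metadata$sequence_id <- sub("synth", "mouse",
                                    rep_m$metadata$sequence_id)
  for (i in seq_along(rep_m$sequences))
    rep_m$sequences[[i]]$id <- rep_m$metadata$sequence_id[i]
  db <- build_database(c(rep_h$sequences, rep_m$sequences),
                       rbind(rep_h$metadata, rep_m$metadata), sc,
                       tempfile("db"))
  q <- encode(rep_h$sequences[[1]], sc)
  h_hum <- search(q, db, search_config(default_regions(sc)["whole"],
                                       n_best = 100, species = "human"))
  expect_equal(nrow(h_hum), 40)
  h_all <- search(q, db, search_config(default_regions(sc)["whole"],
                                       n_best = 100))
  expect_equal(nrow(h_all), 80)
})

test_that("metadata joins preserve order and put identity last", {
  x <- build_synth_db(60, seed = 39)
  sc <- x$scheme
  q <- encode(x$rep$sequences[[3]], sc)
  h <- search(q, x$db, search_config(default_regions(sc), n_best = 5))
  res <- join_metadata(h, x$db)
  expect_equal(nrow(res), nrow(h))
  expect_equal(names(res)[length(names(res))], "Identity")
  expect_identical(res$Identity, h$identity)
  expect_equal(res$sequence_id[res$region == "whole" & res$rank == 1],
               x$rep$metadata$sequence_id[3])
  # empty hits give a header-only table
  empty <- join_metadata(h[0, ], x$db)
  expect_equal(nrow(empty), 0)
  expect_true("Identity" %in% names(empty))
})

test_that("joins draw rows from the correct metadata file", {
  sc <- default_scheme()
  rep1 <- generate_repertoire(repertoire_spec(20, seed = 40), sc)
  rep2 <- generate_repertoire(repertoire_spec(20, seed = 41), sc)
  rep2$metadata$sequence_id <- sub("synth", "fileB",
                                   rep2$metadata$sequence_id)
  for (i in seq_along(rep2$sequences))
    rep2$sequences[[i]]$id <- rep2$metadata$sequence_id[i]
  db <- build_database(c(rep1$sequences, rep2$sequences),
                       list(rep1$metadata, rep2$metadata), sc,
                       tempfile("db"))
  q <- encode(rep2$sequences[[7]], sc)
  h <- search(q, db, search_config(default_regions(sc)["whole"], n_best = 1))
  res <- join_metadata(h, db)
  expect_equal(res$sequence_id, rep2$metadata$sequence_id[7])
})

test_that("hit summaries count group combinations descending", {
  res <- data.frame(disease_state = c("healthy", "healthy", "SARS-CoV-2"),
                    v_call = c("IGHV1-58*01", "IGHV1-58*01", "IGHV1-2*01"),
                    j_call = "IGHJ3*02")
  s1 <- summarize_hits(res, "disease_state")
  expect_equal(s1$disease_state, c("healthy", "SARS-CoV-2"))
  expect_equal(s1$n_hits, c(2L, 1L))
  s2 <- summarize_hits(res, c("v_call", "j_call"))
  expect_equal(nrow(s2), 2)
  expect_error(summarize_hits(res, "nope"), "nope")
  expect_equal(nrow(summarize_hits(res[0, ], "disease_state")), 0)
})

test_that("per-query-region CSVs are written with identity last", {
  x <- build_synth_db(40, seed = 42)
  sc <- x$scheme
  q <- list(myab = encode(x$rep$sequences[[1]], sc))
  h <- search(q, x$db, search_config(default_regions(sc), n_best = 3))
  res <- join_metadata(h, x$db)
  out <- tempfile("results")
  paths <- write_results(res, out)
  expect_length(paths, 3)
  tab <- utils::read.csv(file.path(out, "myab_whole.csv"))
  expect_equal(names(tab)[ncol(tab)], "Identity")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$Identity[1], 100)
})
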