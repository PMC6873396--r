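test_that("import persists indexes and fills descriptor counts", {
  ds <- random_dataset(n_probes = 10, n_samples = 4, seed = 11)
  store <- withr::local_tempdir()
  desc <- import_dataset(ds$matrix, ds$metadata, "GSE-TOY", store)
  expect_equal(desc$n_probes, 10L)
  expect_equal(desc$n_samples, 4L)
  si <- jsonlite::read_json(file.path(store, "GSE-TOY", "sample_index.json"),
                            simplifyVector = TRUE)
  expect_identical(names(si), sample_ids(ds$matrix))
  expect_identical(unname(unlist(si)), 0:3)
  mi <- jsonlite::read_json(file.path(store, "GSE-TOY",
                                      "metadata_index.json"),
                            simplifyVector = TRUE)
  expect_identical(mi, metadata_attributes(ds$metadata))

  # id mismatch names the symmetric difference
  md5 <- tx_metadata(c(ds$metadata$sample_id, "GSM9"),
                     rbind(ds$metadata[-1], ds$metadata[1, -1]))
  expect_error(import_dataset(ds$matrix, md5, "X", store), "GSM9")

  # existing accession refused without overwrite
  expect_error(import_dataset(ds$matrix, ds$metadata, "GSE-TOY", store),
               "already exists")
})

test_that("re-import with overwrite is byte-identical (determinism)", {
  ds <- random_dataset(n_probes = 12, n_samples = 5, seed = 12)
  store <- withr::local_tempdir()
  import_dataset(ds$matrix, ds$metadata, "ACC", store)
  files <- list.files(file.path(store, "ACC"), full.names = TRUE)
  md5_1 <- tools::md5sum(files)
  import_dataset(ds$matrix, ds$metadata, "ACC", store, overwrite = TRUE)
  md5_2 <- tools::md5sum(files)
  expect_identical(md5_1, md5_2)
})

test_that("search equals a brute-force metadata scan on random fixtures", {
  set.seed(13)
  store <- withr::local_tempdir()
  for (fixture in 1:4) {
    ds <- random_dataset(n_probes = 5, n_samples = 12, n_attrs = 4,
                         seed = 100 + fixture)
    acc <- paste0("A", fixture)
    import_dataset(ds$matrix, ds$metadata, acc, store)
    corpus <- unique(unlist(oracle_tokens(
      unlist(ds$metadata[metadata_attributes(ds$metadata)]))))
    for (q in 1:50) {
      token <- sample(corpus, 1)
      attribute <- if (runif(1) < 0.5) NULL else
        sample(metadata_attributes(ds$metadata), 1)
      got <- search_samples(store, acc, token, attribute)
      expect_setequal(got, oracle_search(ds$metadata, token, attribute))
    }
  }
})

test_that("multi-token search is the intersection of single-token results", {
  ds <- random_dataset(n_probes = 4, n_samples = 10, n_attrs = 3, seed = 14)
  store <- withr::local_tempdir()
  import_dataset(ds$matrix, ds$metadata, "A", store)
  got <- search_samples(store, "A", "non-small cell")
  parts <- lapply(c("non", "small", "cell"),
                  function(t) search_samples(store, "A", t))
  expect_setequal(got, Reduce(intersect, parts))
  expect_setequal(got, oracle_search(ds$metadata, "non-small cell"))

  expect_identical(search_samples(store, "A", "zzz_not_in_corpus"),
                   character(0))
  expect_error(search_samples(store, "A", "x", attribute = "nope"),
               "attr_1")
})

test_that("streaming selection equals in-memory column subsetting", {
  store <- withr::local_tempdir()
  set.seed(15)
  for (fixture in 1:8) {
    ds <- random_dataset(n_probes = sample(3:20, 1),
                         n_samples = sample(3:8, 1),
                         seed = 200 + fixture)
    acc <- paste0("F", fixture)
    import_dataset(ds$matrix, ds$metadata, acc, store)
    ids <- sample(sample_ids(ds$matrix),
                  sample(seq_len(ncol(ds$matrix)), 1))
    sel <- select_samples(store, acc, ids, "sel")
    got <- load_selection(sel)
    expect_identical(sample_ids(got$matrix), ids)
    expect_equal(vals(got$matrix), vals(ds$matrix)[, ids, drop = FALSE],
                 tolerance = 1e-9)
    expect_identical(got$metadata$sample_id, ids)
  }
})

test_that("selection handles identity, ordering and errors", {
  ds <- random_dataset(n_probes = 3, n_samples = 4, seed = 16)
  store <- withr::local_tempdir()
  import_dataset(ds$matrix, ds$metadata, "A", store)
  all_ids <- sample_ids(ds$matrix)

  sel <- select_samples(store, "A", all_ids, "all")
  expect_equal(vals(load_selection(sel)$matrix), vals(ds$matrix),
               tolerance = 1e-9)

  sel2 <- select_samples(store, "A", all_ids[c(2, 4)], "bd")
  expect_identical(readLines(sel2$matrix_path)[1L],
                   paste0("\t", all_ids[2], "\t", all_ids[4]))

  expect_error(select_samples(store, "A", c("GSM1", "NOPE"), "x"), "NOPE")
  expect_error(select_samples(store, "A", character(0), "x"), "empty")
})

test_that("the stored matrix is streamed strictly sequentially, one row at a time", {
  ds <- random_dataset(n_probes = 7, n_samples = 3, seed = 17)
  store <- withr::local_tempdir()
  import_dataset(ds$matrix, ds$metadata, "A", store)
  seen <- character(0)
  n <- stream_matrix_rows(store, "A", function(probe, vals) {
    seen <<- c(seen, probe)
    expect_length(vals, 3L)
  })
  expect_equal(n, 7L)
  expect_identical(seen, probe_ids(ds$matrix))
})
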